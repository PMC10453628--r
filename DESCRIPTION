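Package: lesionsemble
Title: Ensemble Thresholding for Dermoscopic Skin-Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Winner-takes-all ensemble segmentation of pigmented skin lesions
    in dermoscopic images. Five candidate segmenters (Otsu, Kapur maximum
    entropy, grey feature-histogram, Harris-hawks minimum cross-entropy
    thresholding, and the Chan-Vese active contour) are run on a
    preprocessed grayscale image; each candidate mask is scored by an
    objective function combining the normalized area of its largest
    connected component, the normalized distance of that component from the
    image centre, and a degeneracy penalty, and the best-scoring candidate
    is kept and morphologically postprocessed. Includes pixel-overlap
    evaluation (Dice, Jaccard, sensitivity, specificity, Welch t-tests) and
    a synthetic dermoscopy fixture generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
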