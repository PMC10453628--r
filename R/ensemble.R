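# Fixed method priority used to break score ties (column order of the
# per-image comparison the pipeline reproduces).
METHOD_PRIORITY <- c("otsu", "acm", "kapur", "hho", "gray")

#' 8-connected component labelling
#'
#' EBImage's labeller is 4-connected; blobs touching only diagonally must be
#' one object here, so its labels are merged across diagonal adjacencies
#' with a union-find pass.
#'
#' @param mask binary matrix of {0, 1}.
#' @return integer matrix of component labels (0 = background); labels are
#'   compacted to 1..n_components.
#' @export
label8 <- function(mask) {
  assert_binary_mask(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  # diagonal neighbour pairs with different nonzero labels
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # down-left
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                          pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) link(pairs[k, 1], pairs[k, 2])
  root <- vapply(seq_len(nlab), find, integer(1))
  compact <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- compact[lab[lab > 0L]]
  out
}

#' Largest connected foreground component and its geometry
#'
#' Labels the mask with 8-connectivity, keeps the component with the most
#' pixels (ties broken by the component containing the earliest pixel in
#' raster order), and summarizes its normalized geometry: area divided by
#' the image area, and the Euclidean distance from the component centroid to
#' the image centre divided by the half diagonal (centre-to-corner-pixel
#' distance), so both lie in [0, 1].
#'
#' @param mask binary matrix of {0, 1}.
#' @return list with `mask_C` (binary matrix of the largest component),
#'   `area_px`, `centroid` (row, col), `norm_area`, `norm_distance`, and
#'   `empty` (TRUE when the mask had no foreground; then `norm_distance` is
#'   defined as the maximal 1).
#' @export
largest_component <- function(mask) {
  assert_binary_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  empty_summary <- list(
    mask_C = matrix(0, H, W), area_px = 0L, centroid = c(NA_real_, NA_real_),
    norm_area = 0, norm_distance = 1, empty = TRUE)
  if (sum(mask) == 0) return(empty_summary)
  lab <- label8(mask)
  areas <- tabulate(lab[lab > 0L])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # raster order: row-major scan; pick the component seen first
    rows <- row(lab); cols <- col(lab)
    first_seen <- vapply(best, function(b) {
      sel <- lab == b
      min((rows[sel] - 1L) * W + cols[sel])
    }, numeric(1))
    best <- best[which.min(first_seen)]
  }
  C <- lab == best
  mode(C) <- "numeric"
  idx <- which(C == 1, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  centre <- c((H + 1) / 2, (W + 1) / 2)
  half_diag <- sqrt((H - 1)^2 + (W - 1)^2) / 2
  list(mask_C = C,
       area_px = as.integer(sum(C)),
       centroid = centroid,
       norm_area = sum(C) / (H * W),
       norm_distance = sqrt(sum((centroid - centre)^2)) / half_diag,
       empty = FALSE)
}

#' Degeneracy penalty of a candidate mask
#'
#' A thresholding that turns the whole image entirely white or entirely
#' black carries no lesion information and is excluded: such masks are
#' penalized with `Inf`, everything else with 0.
#'
#' @param mask binary matrix of {0, 1}.
#' @return 0 or `Inf`.
#' @export
mask_penalty <- function(mask) {
  assert_binary_mask(mask)
  s <- sum(mask)
  if (s == 0 || s == length(mask)) Inf else 0
}

#' Objective score of a candidate segmentation
#'
#' The selection objective: normalized area of the largest component minus
#' its normalized centre distance minus the degeneracy penalty. An infinite
#' penalty maps to `-Inf`, which excludes the candidate from winning. Finite
#' scores are bounded above by 1.
#'
#' @param summary output of [largest_component()].
#' @param pen output of [mask_penalty()] for the full candidate mask.
#' @return list with `value`, `area_term`, `distance_term`, `penalty`.
#' @export
objective_score <- function(summary, pen) {
  value <- if (is.infinite(pen)) -Inf else summary$norm_area - summary$norm_distance
  list(value = value,
       area_term = summary$norm_area,
       distance_term = summary$norm_distance,
       penalty = pen)
}

#' Winner-takes-all selection among candidate masks
#'
#' Scores every candidate with the objective function and keeps the single
#' best mask — selection, not fusion. Ties are broken by the fixed priority
#' order otsu > acm > kapur > hho > gray. If every candidate is degenerate
#' (all scores `-Inf`), the Otsu candidate's raw mask is returned as a
#' fallback with a warning (or the first candidate if Otsu is absent).
#'
#' @param candidates named list of binary masks, names in
#'   {"otsu", "acm", "kapur", "hho", "gray"} (other names are allowed and
#'   ranked last).
#' @return object of class `ensemble_decision`: list with `winner` (method
#'   name), `winning_mask_raw`, `scores` (data.frame with one row per
#'   method: value, area_term, distance_term, penalty), and `degenerate`
#'   (TRUE when the all-candidates-degenerate fallback fired).
#' @export
select_best <- function(candidates) {
  if (length(candidates) < 1L) stop("need at least one candidate", call. = FALSE)
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("`candidates` must be a named list", call. = FALSE)
  methods <- names(candidates)
  rows <- lapply(methods, function(m) {
    mask <- candidates[[m]]
    assert_binary_mask(mask)
    sc <- objective_score(largest_component(mask), mask_penalty(mask))
    data.frame(method = m, value = sc$value, area_term = sc$area_term,
               distance_term = sc$distance_term, penalty = sc$penalty,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  prio <- match(scores$method, METHOD_PRIORITY)
  prio[is.na(prio)] <- length(METHOD_PRIORITY) + 1L
  degenerate <- all(is.infinite(scores$value) & scores$value < 0)
  if (degenerate) {
    warning("all candidates degenerate; falling back to the Otsu mask")
    winner <- if ("otsu" %in% methods) "otsu" else methods[1]
  } else {
    ord <- order(-scores$value, prio)
    winner <- scores$method[ord[1]]
  }
  structure(list(winner = winner,
                 winning_mask_raw = candidates[[winner]],
                 scores = scores,
                 degenerate = degenerate),
            class = "ensemble_decision")
}

#' @export
print.ensemble_decision <- function(x, ...) {
  cat("Winner-takes-all ensemble decision\n")
  cat("  winner:", x$winner, if (x$degenerate) "(degenerate fallback)" else "", "\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

# Euclidean disc structuring element: offsets with dr^2 + dc^2 <= r^2.
# (EBImage's makeBrush "disc" of size 3 degenerates to a full box, which
# over-erodes diagonal boundaries.)
disc_kernel <- function(r) {
  d <- outer((-r:r)^2, (-r:r)^2, `+`) <= r^2
  mode(d) <- "numeric"
  d
}

#' Morphological postprocessing of a winning mask
#'
#' Shrinks the mask by a disc erosion (removing thin attachments such as
#' hair streaks), fills small holes and openings with a morphological
#' closing (dilation followed by erosion), and keeps the largest remaining
#' 8-connected component. If the result is empty the input mask is returned
#' unchanged with a warning.
#'
#' @param mask binary matrix of {0, 1}.
#' @param erode_r erosion disc radius, default 1.
#' @param close_r closing disc radius, default 2.
#' @return postprocessed binary mask, same shape.
#' @export
postprocess_mask <- function(mask, erode_r = 1L, close_r = 2L) {
  assert_binary_mask(mask)
  if (sum(mask) == 0) {
    warning("empty mask; postprocessing skipped")
    return(mask)
  }
  out <- mask
  if (erode_r > 0) {
    out <- EBImage::erode(out, disc_kernel(erode_r))
    out <- matrix(as.numeric(out > 0.5), nrow(mask), ncol(mask))
  }
  if (close_r > 0 && sum(out) > 0) {
    kern <- disc_kernel(close_r)
    out <- EBImage::erode(EBImage::dilate(out, kern), kern)
    out <- matrix(as.numeric(out > 0.5), nrow(mask), ncol(mask))
  }
  if (sum(out) == 0) {
    warning("postprocessing emptied the mask; returning the input mask")
    return(mask)
  }
  largest_component(out)$mask_C
}

#' Segment a dermoscopic image
#'
#' The full pipeline: preprocessing, the five candidate segmenters, the
#' winner-takes-all objective selection, and morphological postprocessing.
#' `method` can restrict the run to a single candidate segmenter (the same
#' preprocessing and postprocessing are applied, so standalone methods and
#' the ensemble are compared on equal footing).
#'
#' @param img raw image (matrix or H x W x 3 array, [0, 255]) or a file path.
#' @param method `"ensemble"` (default) or one of `"otsu"`, `"kapur"`,
#'   `"gray"`, `"hho"`, `"acm"`.
#' @param seed integer seed for the stochastic Harris-hawks stage, default 1.
#' @param size working resolution passed to [preprocess_image()].
#' @param postprocess apply [postprocess_mask()] to the winning mask
#'   (default TRUE).
#' @param hho_pop,hho_iters Harris-hawks population and iteration budget.
#' @param cv_mu,cv_iters Chan-Vese regularization weight and iteration cap.
#' @param erode_r,close_r postprocessing disc radii.
#' @return list with `mask` (final binary mask at the working resolution),
#'   `mask_raw` (winner's mask before postprocessing), `winner`, `scores`
#'   (per-candidate objective table; for a single-method run, that method
#'   only), `thresholds` (named thresholds of the histogram methods), and
#'   `image` (the preprocessed intensity grid).
#' @export
segment_lesion <- function(img, method = c("ensemble", "otsu", "kapur", "gray",
                                           "hho", "acm"),
                           seed = 1L, size = c(56L, 56L), postprocess = TRUE,
                           hho_pop = 20L, hho_iters = 50L,
                           cv_mu = 0.2, cv_iters = 200L,
                           erode_r = 1L, close_r = 2L) {
  method <- match.arg(method)
  if (is.character(img)) img <- read_dermoscopy_image(img)
  I <- preprocess_image(img, size = size)
  wanted <- if (method == "ensemble") c("otsu", "acm", "kapur", "hho", "gray")
            else method
  thresholds <- list()
  candidates <- list()
  h <- intensity_histogram(I)
  degenerate_hist <- sum(h$counts > 0L) < 2L
  for (m in wanted) {
    cand <- switch(m,
      otsu = {
        th <- suppressWarnings(otsu_threshold(h))
        thresholds$otsu <- th
        apply_threshold(I, th)
      },
      kapur = {
        th <- suppressWarnings(kapur_threshold(h))
        thresholds$kapur <- th
        apply_threshold(I, th)
      },
      gray = {
        th <- suppressWarnings(gray_feature_threshold(I))
        thresholds$gray <- th
        apply_threshold(I, th)
      },
      hho = {
        th <- if (degenerate_hist) suppressWarnings(otsu_threshold(h))
              else as.integer(hho_threshold(I, pop = hho_pop,
                                            iters = hho_iters, seed = seed))
        thresholds$hho <- th
        apply_threshold(I, th)
      },
      acm = {
        m0 <- suppressWarnings(chan_vese_segment(I, mu = cv_mu, iters = cv_iters))
        matrix(as.numeric(m0), nrow(I), ncol(I))
      })
    candidates[[m]] <- cand
  }
  decision <- withCallingHandlers(
    select_best(candidates),
    warning = function(w) invokeRestart("muffleWarning"))
  raw <- decision$winning_mask_raw
  final <- if (postprocess) suppressWarnings(postprocess_mask(raw, erode_r, close_r))
           else raw
  list(mask = final, mask_raw = raw, winner = decision$winner,
       scores = decision$scores, thresholds = thresholds, image = I)
}
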