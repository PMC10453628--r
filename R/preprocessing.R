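#' Convert an image to grayscale
#'
#' Collapses a 3-channel RGB array to a single luminance channel using the
#' standard Rec. 601 weights \eqn{0.299 R + 0.587 G + 0.114 B}. A 2-D input
#' (already grayscale) is returned unchanged.
#'
#' @param img numeric matrix (grayscale) or H x W x 3 array, intensities in
#'   [0, 255].
#' @return numeric matrix of the same height and width, values in [0, 255].
#' @export
#' @examples
#' rgb <- array(c(255, 0, 0), dim = c(2, 2, 3) )
#' rgb[, , 2:3] <- 0
#' to_grayscale(rgb)[1, 1]  # 0.299 * 255
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (!is.array(img) || length(dim(img)) != 3 || !(dim(img)[3] %in% c(1L, 3L)))
    stop("unsupported image layout: expected 2-D matrix or H x W x {1,3} array",
         call. = FALSE)
  if (dim(img)[3] == 1L) return(img[, , 1, drop = TRUE])
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Resize a grayscale image by bilinear interpolation
#'
#' @param img numeric matrix, intensities in [0, 255].
#' @param target_h,target_w positive integers, output dimensions. The
#'   standardized working size downstream is 56 x 56.
#' @return numeric matrix of dimension `target_h` x `target_w`, clamped to
#'   [0, 255].
#' @export
resize_image <- function(img, target_h = 56L, target_w = 56L) {
  assert_intensity_image(img)
  if (target_h < 1 || target_w < 1) stop("target dimensions must be >= 1", call. = FALSE)
  out <- EBImage::resize(img, w = target_h, h = target_w, filter = "bilinear")
  out <- matrix(as.numeric(out), nrow = target_h, ncol = target_w)
  clamp255(out)
}

#' Median filter with reflective border padding
#'
#' Replaces each pixel by the median of its `window` x `window` neighbourhood.
#' The border is reflect-padded so the image frame is not darkened, and a
#' perfect step edge between two constant regions is preserved away from
#' corners.
#'
#' @param img numeric matrix in [0, 255].
#' @param window odd integer window side, default 3.
#' @return filtered matrix, same dimensions.
#' @export
median_filter <- function(img, window = 3L) {
  assert_intensity_image(img)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer", call. = FALSE)
  if (window == 1L) return(img)
  r <- window %/% 2L
  H <- nrow(img); W <- ncol(img)
  ri <- c(rev(seq_len(min(r, H))), seq_len(H), H + 1L - rev(seq_len(min(r, H))))
  ci <- c(rev(seq_len(min(r, W))), seq_len(W), W + 1L - rev(seq_len(min(r, W))))
  pad <- img[ri, ci, drop = FALSE]
  # stack the window^2 shifted copies and take the per-pixel median
  k <- window * window
  stack <- matrix(0, nrow = H * W, ncol = k)
  idx <- 1L
  for (dr in 0:(window - 1L)) for (dc in 0:(window - 1L)) {
    stack[, idx] <- as.vector(pad[dr + seq_len(H), dc + seq_len(W)])
    idx <- idx + 1L
  }
  med <- apply(stack, 1L, median)
  matrix(med, H, W)
}

#' Linear contrast stretch with quantile saturation
#'
#' Maps the `low_frac` and `1 - high_frac` intensity quantiles to 0 and 255
#' with a linear ramp, saturating values beyond them. With the 1% defaults
#' this reproduces the conventional automatic contrast adjustment of imaging
#' toolboxes. A constant image is returned unchanged with a warning.
#'
#' @param img numeric matrix in [0, 255].
#' @param low_frac,high_frac fractions saturated at the bottom and top of the
#'   intensity range; `low_frac + high_frac` must be < 1.
#' @return contrast-stretched matrix in [0, 255].
#' @export
adjust_contrast <- function(img, low_frac = 0.01, high_frac = 0.01) {
  assert_intensity_image(img)
  if (low_frac < 0 || high_frac < 0 || low_frac + high_frac >= 1)
    stop("need 0 <= low_frac + high_frac < 1", call. = FALSE)
  lo <- as.numeric(quantile(img, low_frac, names = FALSE, type = 7))
  hi <- as.numeric(quantile(img, 1 - high_frac, names = FALSE, type = 7))
  if (hi <= lo) {
    warning("zero dynamic range; image returned unchanged")
    return(img)
  }
  clamp255((img - lo) * 255 / (hi - lo))
}

#' Standard preprocessing pipeline
#'
#' Grayscale conversion, bilinear resize to the working resolution, median
#' denoising, and linear contrast stretching — the fixed front end every
#' candidate segmenter consumes. The result is rounded to integer grey
#' levels so histogram-based thresholds and mask application agree exactly.
#'
#' @param img raw image: matrix or H x W x 3 array in [0, 255].
#' @param size integer length-2 working size, default c(56, 56).
#' @param median_window odd median-filter window, default 3.
#' @param low_frac,high_frac contrast saturation fractions, default 1% each.
#' @return integer-valued numeric matrix of dimension `size` in [0, 255].
#' @export
preprocess_image <- function(img, size = c(56L, 56L), median_window = 3L,
                             low_frac = 0.01, high_frac = 0.01) {
  g <- to_grayscale(img)
  g <- resize_image(g, size[1], size[2])
  g <- median_filter(g, median_window)
  g <- suppressWarnings(adjust_contrast(g, low_frac, high_frac))
  round(clamp255(g))
}

#' Read a dermoscopic image from disk
#'
#' Reads PNG/JPEG/TIFF via EBImage and returns intensities on the [0, 255]
#' scale as a matrix (grayscale) or H x W x 3 array (RGB).
#'
#' @param path file path.
#' @return numeric matrix or array in [0, 255].
#' @export
read_dermoscopy_image <- function(path) {
  x <- EBImage::readImage(path)
  a <- EBImage::imageData(x) * 255
  # EBImage stores (x, y [, c]); transpose to row = image row
  if (length(dim(a)) == 2L) return(t(a))
  a <- a[, , 1:min(3L, dim(a)[3]), drop = FALSE]
  if (dim(a)[3] == 1L) return(t(a[, , 1]))
  aperm(a, c(2L, 1L, 3L))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask binary matrix of {0, 1}.
#' @param path output file path (PNG).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_binary_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask)), path, type = "png")
  invisible(path)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param img numeric matrix in [0, 255].
#' @param path output file path (PNG).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  assert_intensity_image(img)
  EBImage::writeImage(EBImage::Image(t(img) / 255), path, type = "png")
  invisible(path)
}
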