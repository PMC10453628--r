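#' @import EBImage
#' @importFrom stats t.test quantile rnorm runif sd var median
#' @importFrom utils read.csv write.csv
NULL

# Shared input checks for the 2-D intensity grids used throughout the package.
# Intensities are plain numeric matrices on the 8-bit scale [0, 255]; binary
# masks are matrices of {0, 1}.

assert_intensity_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a 2-D numeric matrix", arg), call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (any(img < 0) || any(img > 255))
    stop(sprintf("`%s` has intensities outside [0, 255]", arg), call. = FALSE)
  invisible(img)
}

assert_binary_mask <- function(mask, arg = deparse(substitute(mask))) {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop(sprintf("`%s` must be a 2-D numeric matrix", arg), call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop(sprintf("`%s` must contain only 0 and 1", arg), call. = FALSE)
  invisible(mask)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(NULL)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 4-neighbour boundary-edge count of a binary mask, used as a discrete
# contour-length estimate by the active-contour energy.
mask_perimeter <- function(mask) {
  h <- abs(mask[-1, , drop = FALSE] - mask[-nrow(mask), , drop = FALSE])
  v <- abs(mask[, -1, drop = FALSE] - mask[, -ncol(mask), drop = FALSE])
  # pixels on the image frame also contribute an exposed edge
  frame <- sum(mask[1, ]) + sum(mask[nrow(mask), ]) +
    sum(mask[, 1]) + sum(mask[, ncol(mask)])
  sum(h) + sum(v) + frame
}
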