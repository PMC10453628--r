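#' Specification of one synthetic dermoscopy fixture
#'
#' Describes an elliptical pigmented lesion on lighter skin together with
#' the acquisition artefacts dermoscopic imagery is known for: dark hair
#' streaks, smooth intensity inhomogeneity, bright circular markers,
#' ill-defined (blurred) boundaries, and sensor noise. Intensity defaults
#' (lesion ~60, skin ~190 on the 8-bit scale) encode the dark-lesion-on-
#' light-skin polarity the segmenters assume.
#'
#' @param size integer c(H, W), default c(56, 56).
#' @param centre lesion centre (row, col); default image centre.
#' @param axes ellipse semi-axes (pixels), default c(14, 11).
#' @param rotation ellipse rotation in radians, default 0.
#' @param lesion_mean,lesion_sd lesion intensity distribution, default 60, 6.
#' @param skin_mean,skin_sd background skin intensity, default 190, 8.
#' @param hair_count number of dark hair polylines, default 0.
#' @param hair_thickness hair stroke half-thickness in pixels, default 1.
#' @param hair_intensity hair intensity, default 30.
#' @param inhomogeneity multiplicative planar gradient amplitude (0 = none),
#'   default 0; 0.25 gives a pronounced shading ramp.
#' @param marker add a bright circular rim near the border, default FALSE.
#' @param boundary_blur_sd Gaussian blur (pixels) of the lesion boundary for
#'   ill-defined edges, default 0 (crisp).
#' @param noise_sd additive Gaussian noise sd, default 3.
#' @param seed integer seed, default 1.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(size = c(56L, 56L), centre = NULL, axes = c(14, 11),
                         rotation = 0, lesion_mean = 60, lesion_sd = 6,
                         skin_mean = 190, skin_sd = 8,
                         hair_count = 0L, hair_thickness = 1, hair_intensity = 30,
                         inhomogeneity = 0, marker = FALSE,
                         boundary_blur_sd = 0, noise_sd = 3, seed = 1L) {
  if (is.null(centre)) centre <- (size + 1) / 2
  if (any(size < 8)) stop("fixture too small", call. = FALSE)
  if (any(axes <= 0)) stop("ellipse axes must be positive", call. = FALSE)
  if (centre[1] - max(axes) < 1 || centre[1] + max(axes) > size[1] ||
      centre[2] - max(axes) < 1 || centre[2] + max(axes) > size[2])
    stop("lesion ellipse must lie fully inside the image", call. = FALSE)
  structure(list(size = as.integer(size), centre = centre, axes = axes,
                 rotation = rotation, lesion_mean = lesion_mean,
                 lesion_sd = lesion_sd, skin_mean = skin_mean,
                 skin_sd = skin_sd, hair_count = as.integer(hair_count),
                 hair_thickness = hair_thickness,
                 hair_intensity = hair_intensity,
                 inhomogeneity = inhomogeneity, marker = isTRUE(marker),
                 boundary_blur_sd = boundary_blur_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

ellipse_indicator <- function(size, centre, axes, rotation) {
  rr <- matrix(seq_len(size[1]), size[1], size[2]) - centre[1]
  cc <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE) - centre[2]
  u <- cos(rotation) * rr + sin(rotation) * cc
  v <- -sin(rotation) * rr + cos(rotation) * cc
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

# Stamp an anti-aliased thick segment onto `img` at intensity `value`.
draw_segment <- function(img, p0, p1, half_width, value) {
  H <- nrow(img); W <- ncol(img)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- p1 - p0
  len2 <- sum(d^2)
  t <- if (len2 == 0) matrix(0, H, W)
       else pmin(pmax(((rr - p0[1]) * d[1] + (cc - p0[2]) * d[2]) / len2, 0), 1)
  dist <- sqrt((rr - (p0[1] + t * d[1]))^2 + (cc - (p0[2] + t * d[2]))^2)
  alpha <- pmin(pmax(half_width + 0.5 - dist, 0), 1)  # 1-px anti-aliased edge
  img * (1 - alpha) + value * alpha
}

gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  EBImage::gblur(img, sigma = sd)
}

#' Generate one synthetic dermoscopy image with exact ground truth
#'
#' Deterministic for a given spec (the spec's `seed` drives all randomness).
#' The ground-truth mask is the exact ellipse indicator, recorded before
#' hair, markers, shading or noise are overlaid, so evaluation against it
#' measures robustness to exactly those artefacts. The returned image is
#' rounded to integer grey levels in [0, 255].
#'
#' @param spec a [fixture_spec()].
#' @return list with `image` (numeric matrix, [0, 255]) and `mask` (binary
#'   ground-truth matrix).
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop("`spec` must be a fixture_spec", call. = FALSE)
  with_seed(spec$seed, {
    H <- spec$size[1]; W <- spec$size[2]
    inside <- ellipse_indicator(spec$size, spec$centre, spec$axes, spec$rotation)
    truth <- inside
    mode(truth) <- "numeric"
    skin <- matrix(rnorm(H * W, spec$skin_mean, spec$skin_sd), H, W)
    lesion <- matrix(rnorm(H * W, spec$lesion_mean, spec$lesion_sd), H, W)
    w <- truth
    if (spec$boundary_blur_sd > 0) w <- gaussian_blur(w, spec$boundary_blur_sd)
    img <- skin * (1 - w) + lesion * w
    if (spec$hair_count > 0) {
      for (i in seq_len(spec$hair_count)) {
        # random chord across the image with a slight kink
        p0 <- c(runif(1, 1, H), runif(1, 1, W))
        ang <- runif(1, 0, 2 * pi)
        len <- runif(1, 0.6, 1.4) * max(H, W)
        p1 <- p0 + len * c(sin(ang), cos(ang))
        pm <- (p0 + p1) / 2 + rnorm(2, 0, 3)
        img <- draw_segment(img, p0, pm, spec$hair_thickness / 2, spec$hair_intensity)
        img <- draw_segment(img, pm, p1, spec$hair_thickness / 2, spec$hair_intensity)
      }
    }
    if (spec$inhomogeneity > 0) {
      ang <- runif(1, 0, 2 * pi)
      rr <- matrix(seq_len(H), H, W) / H - 0.5
      cc <- matrix(seq_len(W), H, W, byrow = TRUE) / W - 0.5
      ramp <- (sin(ang) * rr + cos(ang) * cc) / 0.5   # in [-1, 1] along the axis
      img <- img * (1 + spec$inhomogeneity * ramp)
    }
    if (spec$marker) {
      # bright circular rim in a corner region, away from the lesion
      mc <- c(H * 0.15, W * 0.85)
      d <- sqrt((matrix(seq_len(H), H, W) - mc[1])^2 +
                  (matrix(seq_len(W), H, W, byrow = TRUE) - mc[2])^2)
      rim <- abs(d - 0.1 * min(H, W)) <= 1
      img[rim] <- 240
    }
    if (spec$noise_sd > 0) img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    list(image = round(clamp255(img)), mask = truth)
  })
}

suite_strata <- c("clean", "hairy", "inhomogeneous", "low_contrast", "marker")

stratum_spec <- function(stratum, seed) {
  jitter <- with_seed(seed, list(
    centre_off = runif(2, -5, 5),
    axes = c(runif(1, 11, 18), runif(1, 9, 15)),
    rot = runif(1, 0, pi)))
  base <- list(size = c(56L, 56L),
               centre = c(28.5, 28.5) + jitter$centre_off,
               axes = jitter$axes, rotation = jitter$rot, seed = seed)
  extra <- switch(stratum,
    clean = list(),
    hairy = list(hair_count = 15L, hair_thickness = 2),
    inhomogeneous = list(inhomogeneity = 0.25, boundary_blur_sd = 0.8),
    low_contrast = list(lesion_mean = 110, lesion_sd = 9, skin_mean = 165,
                        skin_sd = 9, boundary_blur_sd = 1.2),
    marker = list(marker = TRUE, hair_count = 4L))
  do.call(fixture_spec, c(base, extra))
}

#' Generate a stratified suite of synthetic fixtures
#'
#' Produces a reproducible mix of clean, hairy, shaded (inhomogeneous),
#' low-contrast, and marker-bearing fixtures. Stratum counts follow the
#' requested proportions by largest remainder.
#'
#' @param n number of fixtures.
#' @param proportions named numeric vector over
#'   `c("clean", "hairy", "inhomogeneous", "low_contrast", "marker")`,
#'   summing to 1. Default c(.3, .3, .15, .15, .1).
#' @param seed master seed; each fixture gets a derived sub-seed.
#' @return list of fixtures, each a list with `id`, `stratum`, `seed`,
#'   `spec`, `image`, `mask`.
#' @export
generate_suite <- function(n, proportions = c(clean = 0.30, hairy = 0.30,
                                              inhomogeneous = 0.15,
                                              low_contrast = 0.15,
                                              marker = 0.10),
                           seed = 1L) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("`proportions` must sum to 1", call. = FALSE)
  proportions <- proportions[suite_strata]
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  strata <- rep(suite_strata, counts)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- (as.integer(seed) * 1009L + i * 7907L) %% 2147483647L
    sp <- stratum_spec(strata[i], sub_seed)
    fx <- generate_fixture(sp)
    out[[i]] <- list(id = sprintf("SYN_%04d", i), stratum = strata[i],
                     seed = sub_seed, spec = sp,
                     image = fx$image, mask = fx$mask)
  }
  out
}

#' Write a fixture suite to disk
#'
#' Writes each fixture's image and ground-truth mask as 8-bit PNGs plus a
#' manifest CSV (id, stratum, seed, lesion geometry).
#'
#' @param fixtures list from [generate_suite()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_fixture_suite <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(fixtures, function(fx)
    data.frame(id = fx$id, stratum = fx$stratum, seed = fx$seed,
               centre_row = fx$spec$centre[1], centre_col = fx$spec$centre[2],
               axis_major = fx$spec$axes[1], axis_minor = fx$spec$axes[2],
               rotation = fx$spec$rotation)))
  for (fx in fixtures) {
    write_image_png(fx$image, file.path(dir, paste0(fx$id, ".png")))
    write_mask_png(fx$mask, file.path(dir, paste0(fx$id, "_mask.png")))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
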