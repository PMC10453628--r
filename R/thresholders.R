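#' Intensity histogram over the 256 grey-level bins
#'
#' @param img numeric matrix in [0, 255]; intensities are rounded to the
#'   nearest integer bin.
#' @return list with `counts` (integer vector, bins 0..255) and
#'   `probabilities` (counts normalized by pixel count). Bin `v` is element
#'   `v + 1`.
#' @export
intensity_histogram <- function(img) {
  assert_intensity_image(img)
  counts <- tabulate(as.integer(round(img)) + 1L, nbins = 256L)
  list(counts = counts, probabilities = counts / length(img))
}

#' Binarize an image at a threshold
#'
#' Pigmented lesions are darker than the surrounding skin, so with the
#' default `"dark"` polarity the foreground is the set of pixels with
#' intensity at or below the threshold.
#'
#' @param img numeric matrix in [0, 255].
#' @param th threshold in [0, 255].
#' @param lesion_polarity `"dark"` (foreground = pixel <= th) or `"bright"`
#'   (foreground = pixel > th).
#' @return binary matrix of {0, 1}, same shape as `img`.
#' @export
apply_threshold <- function(img, th, lesion_polarity = c("dark", "bright")) {
  assert_intensity_image(img)
  if (th < 0 || th > 255) stop("`th` must lie in [0, 255]", call. = FALSE)
  lesion_polarity <- match.arg(lesion_polarity)
  m <- if (lesion_polarity == "dark") (img <= th) else (img > th)
  mode(m) <- "numeric"
  m
}

hist_or_image <- function(x) {
  if (is.list(x) && !is.null(x$probabilities)) x else intensity_histogram(x)
}

n_nonempty_bins <- function(h) sum(h$counts > 0L)

single_level <- function(h) which(h$counts > 0L)[1] - 1L

#' Otsu's threshold
#'
#' Selects the grey level minimizing the weighted within-class variance
#' \eqn{\sigma_w^2(th) = w_1 \sigma_1^2 + w_2 \sigma_2^2} of the two classes
#' split at `th` (class 1: bins 0..th, class 2: bins th+1..255). Ties are
#' broken towards the smallest threshold.
#'
#' @param x an intensity image matrix or a histogram from
#'   [intensity_histogram()].
#' @return integer threshold in [0, 255].
#' @export
otsu_threshold <- function(x) {
  h <- hist_or_image(x)
  if (n_nonempty_bins(h) < 2L) {
    warning("degenerate histogram: single grey level")
    return(single_level(h))
  }
  p <- h$probabilities
  v <- 0:255
  w1 <- cumsum(p)                      # P(class 1) for th = 0..255
  m1 <- cumsum(p * v)                  # unnormalized class-1 mean
  mu <- m1[256]
  w2 <- 1 - w1
  mean1 <- ifelse(w1 > 0, m1 / w1, 0)
  mean2 <- ifelse(w2 > 0, (mu - m1) / w2, 0)
  e2 <- cumsum(p * v^2)                # unnormalized second moments
  var1 <- ifelse(w1 > 0, e2 / w1 - mean1^2, 0)
  var2 <- ifelse(w2 > 0, (e2[256] - e2) / w2 - mean2^2, 0)
  sw <- w1 * pmax(var1, 0) + w2 * pmax(var2, 0)
  which.min(sw) - 1L                   # which.min takes the first minimum
}

#' Kapur's maximum-entropy threshold
#'
#' Selects the grey level maximizing the sum of the Shannon entropies
#' (natural log) of the background and foreground intensity distributions,
#' each renormalized within its class. Empty bins contribute zero; an empty
#' class contributes zero entropy. Ties are broken towards the smallest
#' threshold.
#'
#' @inheritParams otsu_threshold
#' @return integer threshold in [0, 255].
#' @export
kapur_threshold <- function(x) {
  h <- hist_or_image(x)
  if (n_nonempty_bins(h) < 2L) {
    warning("degenerate histogram: single grey level")
    return(single_level(h))
  }
  p <- h$probabilities
  plogp <- ifelse(p > 0, p * log(p), 0)
  P1 <- cumsum(p)
  S1 <- cumsum(plogp)
  P2 <- 1 - P1
  S2 <- S1[256] - S1
  H1 <- ifelse(P1 > 0, log(P1) - S1 / P1, 0)
  H2 <- ifelse(P2 > 0, log(P2) - S2 / P2, 0)
  which.max(H1 + H2) - 1L
}

#' Cross-entropy information distance between an image and its two-level
#' reconstruction
#'
#' The minimum cross-entropy segmentation criterion: with \eqn{I_j} the
#' pixel intensities of the image and \eqn{S_j} those of its two-level
#' reconstruction — every pixel replaced by the mean intensity of its class
#' (foreground or background under `mask`) — the information distance is
#' \deqn{Dist(I, S) = \sum_{j=1}^{N} I_j \log(I_j / S_j)}
#' (natural log, sum over all N pixels). Zero-intensity pixels contribute
#' nothing; a zero class mean is smoothed with \eqn{\epsilon = 10^{-12}}.
#' By the log-sum inequality the distance is non-negative, and it is zero
#' exactly when each class is constant, i.e. when the reconstruction
#' reproduces the image. A degenerate mask (empty foreground or background)
#' scores `Inf`.
#'
#' @param img numeric matrix in [0, 255].
#' @param mask binary matrix, same shape; 1 = foreground.
#' @return non-negative score (lower is a better two-level summary).
#' @export
cross_entropy_distance <- function(img, mask) {
  assert_intensity_image(img)
  assert_binary_mask(mask)
  assert_same_shape(img, mask)
  fg <- mask == 1
  n_fg <- sum(fg)
  if (n_fg == 0L || n_fg == length(img)) return(Inf)
  m1 <- mean(img[fg])
  m2 <- mean(img[!fg])
  d <- 0
  x1 <- img[fg];  x1 <- x1[x1 > 0]
  x2 <- img[!fg]; x2 <- x2[x2 > 0]
  if (length(x1)) d <- d + sum(x1 * log(x1 / max(m1, 1e-12)))
  if (length(x2)) d <- d + sum(x2 * log(x2 / max(m2, 1e-12)))
  max(d, 0)
}

#' Grey feature-histogram threshold
#'
#' For every candidate threshold the image is binarized (dark polarity) and a
#' spatial feature of the resulting objects — the mean area of the
#' 8-connected foreground components — is measured, building a feature
#' histogram \eqn{h[th] \leftarrow f(I_{th})}. The selected threshold is the
#' midpoint of the longest run of consecutive thresholds over which the
#' feature is stable (successive relative change below `stability_tol`);
#' stable plateaus indicate thresholds that isolate the same physical
#' object. Thresholds whose foreground covers none or more than
#' `max_fg_frac` of the frame describe the background rather than a lesion
#' object (the same lesion-minority prior the ensemble's centre-distance
#' objective encodes) and are excluded from the plateau search. If no
#' plateau longer than one level exists the global Otsu threshold is
#' returned with a warning.
#'
#' @param img numeric matrix in [0, 255].
#' @param stability_tol relative change defining a plateau, default 0.05.
#' @param max_fg_frac largest foreground fraction considered an object
#'   measurement, default 0.5.
#' @return integer threshold in [0, 255].
#' @export
gray_feature_threshold <- function(img, stability_tol = 0.05, max_fg_frac = 0.5) {
  assert_intensity_image(img)
  cumfrac <- cumsum(intensity_histogram(img)$probabilities)
  valid <- cumfrac > 0 & cumfrac <= max_fg_frac
  f <- rep(NA_real_, 256L)
  for (i in which(valid)) {
    m <- img <= (i - 1L)
    mode(m) <- "numeric"
    f[i] <- sum(m) / max(label8(m))
  }
  # maximal runs of consecutive valid thresholds with stable feature value
  stable <- valid[-256L] & valid[-1L] &
    abs(diff(f)) <= stability_tol * pmax(abs(f[-256L]), 1e-12)
  stable[is.na(stable)] <- FALSE
  best_len <- 0L; best_start <- NA_integer_
  run_start <- 1L
  for (i in seq_along(stable)) {
    if (!stable[i]) run_start <- i + 1L
    len <- i + 1L - run_start
    if (len + 1L > best_len) { best_len <- len + 1L; best_start <- run_start }
  }
  if (is.na(best_start) || best_len < 2L) {
    warning("no stable feature plateau; falling back to Otsu")
    return(suppressWarnings(otsu_threshold(img)))
  }
  as.integer(best_start - 1L + (best_len - 1L) %/% 2L)
}

# -- Harris hawks optimization ------------------------------------------------

levy_step <- function(beta = 1.5) {
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  0.01 * rnorm(1) * sigma / abs(rnorm(1))^(1 / beta)
}

#' Harris-hawks minimum cross-entropy threshold
#'
#' Runs the Harris hawks optimizer — a population metaheuristic alternating
#' exploration with soft/hard "besiege" exploitation moves (including
#' Levy-flight rapid dives) as the prey's escape energy decays — over the
#' scalar threshold in [0, 255], minimizing the cross-entropy information
#' distance ([cross_entropy_distance()]) of the dark-polarity mask the
#' threshold produces. Candidate positions are clamped to the bounds and
#' rounded to the nearest grey level when evaluated, and fitness values are
#' cached per grey level. Fully reproducible for a given `seed`.
#'
#' @param img numeric matrix in [0, 255].
#' @param pop population size (>= 2), default 20.
#' @param iters iteration count (>= 1), default 50.
#' @param seed integer seed driving all randomness, default 1.
#' @param beta Levy-flight exponent, default 1.5.
#' @return integer threshold in [0, 255] with attribute `fitness`, the
#'   cross-entropy distance attained.
#' @export
hho_threshold <- function(img, pop = 20L, iters = 50L, seed = 1L, beta = 1.5) {
  assert_intensity_image(img)
  if (pop < 2L) stop("`pop` must be >= 2", call. = FALSE)
  if (iters < 1L) stop("`iters` must be >= 1", call. = FALSE)
  lb <- 0; ub <- 255
  cache <- rep(NA_real_, 256L)
  fit <- function(x) {
    th <- as.integer(round(pmin(pmax(x, lb), ub)))
    if (is.na(cache[th + 1L]))
      cache[th + 1L] <<- cross_entropy_distance(img, apply_threshold(img, th))
    cache[th + 1L]
  }
  with_seed(seed, {
    X <- runif(pop, lb, ub)
    Fx <- vapply(X, fit, numeric(1))
    best_i <- which.min(Fx)
    rabbit <- X[best_i]; rabbit_f <- Fx[best_i]
    for (t in seq_len(iters)) {
      for (i in seq_len(pop)) {
        E0 <- 2 * runif(1) - 1
        E <- 2 * E0 * (1 - t / iters)
        J <- 2 * (1 - runif(1))
        if (abs(E) >= 1) {                       # exploration
          if (runif(1) >= 0.5) {
            Xr <- X[sample.int(pop, 1L)]
            Xn <- Xr - runif(1) * abs(Xr - 2 * runif(1) * X[i])
          } else {
            Xn <- (rabbit - mean(X)) - runif(1) * (lb + runif(1) * (ub - lb))
          }
        } else {                                 # exploitation
          r <- runif(1)
          if (r >= 0.5 && abs(E) >= 0.5) {       # soft besiege
            Xn <- (rabbit - X[i]) - E * abs(J * rabbit - X[i])
          } else if (r >= 0.5) {                 # hard besiege
            Xn <- rabbit - E * abs(rabbit - X[i])
          } else if (abs(E) >= 0.5) {            # soft besiege, rapid dives
            Y <- rabbit - E * abs(J * rabbit - X[i])
            Z <- Y + runif(1) * levy_step(beta)
            Xn <- if (fit(Y) < Fx[i]) Y else if (fit(Z) < Fx[i]) Z else X[i]
          } else {                               # hard besiege, rapid dives
            Y <- rabbit - E * abs(J * rabbit - mean(X))
            Z <- Y + runif(1) * levy_step(beta)
            Xn <- if (fit(Y) < Fx[i]) Y else if (fit(Z) < Fx[i]) Z else X[i]
          }
        }
        # position updates are unconditional (only the dive branches above
        # are greedy); the best-so-far rabbit is what the optimizer returns
        Xn <- pmin(pmax(Xn, lb), ub)
        Fn <- fit(Xn)
        X[i] <- Xn; Fx[i] <- Fn
        if (Fn < rabbit_f) { rabbit <- Xn; rabbit_f <- Fn }
      }
    }
    structure(as.integer(round(rabbit)), fitness = rabbit_f)
  })
}
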