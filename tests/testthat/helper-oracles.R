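# Independent brute-force oracles and small image builders used across the
# suite. The oracles deliberately avoid the package's vectorized code paths:
# they loop over all 256 candidate thresholds and compute class statistics by
# direct subsetting.

oracle_otsu <- function(img) {
  v <- as.integer(round(img))
  best_th <- NA_integer_; best_val <- Inf
  for (th in 0:255) {
    lo <- v[v <= th]; hi <- v[v > th]
    w1 <- length(lo) / length(v); w2 <- 1 - w1
    s1 <- if (length(lo)) mean((lo - mean(lo))^2) else 0
    s2 <- if (length(hi)) mean((hi - mean(hi))^2) else 0
    val <- w1 * s1 + w2 * s2
    if (val < best_val) { best_val <- val; best_th <- th }
  }
  best_th
}

oracle_kapur <- function(img) {
  v <- as.integer(round(img))
  p <- tabulate(v + 1L, 256L) / length(v)
  class_entropy <- function(idx) {
    P <- sum(p[idx])
    if (P == 0) return(0)
    q <- p[idx][p[idx] > 0] / P
    -sum(q * log(q))
  }
  best_th <- NA_integer_; best_val <- -Inf
  for (th in 0:255) {
    val <- class_entropy(seq_len(th + 1L)) +
      class_entropy(if (th < 255) (th + 2L):256L else integer(0))
    if (val > best_val) { best_val <- val; best_th <- th }
  }
  best_th
}

# direct per-pixel minimum cross-entropy, written from the formula
oracle_cross_entropy <- function(img, mask) {
  fg <- mask == 1
  if (!any(fg) || all(fg)) return(Inf)
  total <- 0
  m <- c(mean(img[!fg]), mean(img[fg]))
  for (j in seq_along(img)) {
    if (img[j] > 0) total <- total + img[j] * log(img[j] / m[mask[j] + 1])
  }
  total
}

# two-Gaussian mixture image rounded to grey levels, always >= 2 levels
random_bimodal_image <- function(h = 56, w = 56) {
  mu <- sort(runif(2, 10, 245))
  sdv <- runif(2, 2, 25)
  frac <- runif(1, 0.1, 0.9)
  n1 <- round(h * w * frac)
  v <- c(rnorm(n1, mu[1], sdv[1]), rnorm(h * w - n1, mu[2], sdv[2]))
  img <- matrix(round(pmin(pmax(sample(v), 0), 255)), h, w)
  if (length(unique(as.vector(img))) < 2) img[1, 1] <- 255 - img[1, 1]
  img
}

# dark disc (value 40) on bright field (value 220)
disc_image <- function(h = 56, w = 56, r = 10, lo = 40, hi = 220) {
  d <- sqrt(outer((seq_len(h) - (h + 1) / 2)^2,
                  (seq_len(w) - (w + 1) / 2)^2, `+`))
  img <- matrix(hi, h, w)
  img[d <= r] <- lo
  list(image = img, mask = matrix(as.numeric(d <= r), h, w))
}

# 4-neighbour boundary-edge perimeter, independent of the package helper
oracle_perimeter <- function(m) {
  H <- nrow(m); W <- ncol(m)
  sum(abs(m[-1, ] - m[-H, ])) + sum(abs(m[, -1] - m[, -W])) +
    sum(m[1, ]) + sum(m[H, ]) + sum(m[, 1]) + sum(m[, W])
}
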