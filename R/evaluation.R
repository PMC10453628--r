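#' Pixelwise confusion counts between a predicted and a ground-truth mask
#'
#' Foreground (1) is the positive class.
#'
#' @param pred,truth binary matrices of {0, 1}, same shape.
#' @return list with integer counts `TP`, `TN`, `FP`, `FN` (summing to the
#'   pixel count).
#' @export
confusion_counts <- function(pred, truth) {
  assert_binary_mask(pred)
  assert_binary_mask(truth)
  assert_same_shape(pred, truth)
  p <- pred == 1; g <- truth == 1
  list(TP = sum(p & g), TN = sum(!p & !g),
       FP = sum(p & !g), FN = sum(!p & g))
}

#' Dice similarity coefficient
#'
#' \eqn{2|A \cap G| / (|A| + |G|)} between predicted mask A and ground truth
#' G. Two empty masks agree perfectly on the absence of a lesion and score 1
#' (with a message).
#'
#' @inheritParams confusion_counts
#' @return Dice score in [0, 1].
#' @export
dice_score <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  denom <- 2 * cc$TP + cc$FP + cc$FN
  if (denom == 0) {
    message("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * cc$TP / denom
}

#' Jaccard index from a Dice score
#'
#' The algebraic identity \eqn{JI = DSC / (2 - DSC)}, equivalent to the
#' direct intersection-over-union.
#'
#' @param dsc Dice score in [0, 1].
#' @return Jaccard index in [0, 1].
#' @export
jaccard_from_dice <- function(dsc) {
  if (any(dsc < 0 | dsc > 1)) stop("`dsc` must lie in [0, 1]", call. = FALSE)
  dsc / (2 - dsc)
}

#' Sensitivity (true positive rate)
#'
#' \eqn{TP / (TP + FN)}: the fraction of lesion pixels recovered. Undefined
#' (empty ground-truth foreground) is reported as `NA`, not 0.
#'
#' @param counts confusion counts from [confusion_counts()].
#' @return sensitivity in [0, 1], or `NA` when undefined.
#' @export
sensitivity <- function(counts) {
  if (counts$TP + counts$FN == 0) {
    message("no positive pixels in ground truth; sensitivity undefined")
    return(NA_real_)
  }
  counts$TP / (counts$TP + counts$FN)
}

#' Specificity (true negative rate)
#'
#' \eqn{TN / (TN + FP)}: the fraction of background pixels excluded.
#' Undefined (no background in ground truth) is reported as `NA`, not 0.
#'
#' @inheritParams sensitivity
#' @return specificity in [0, 1], or `NA` when undefined.
#' @export
specificity <- function(counts) {
  if (counts$TN + counts$FP == 0) {
    message("no negative pixels in ground truth; specificity undefined")
    return(NA_real_)
  }
  counts$TN / (counts$TN + counts$FP)
}

#' All four overlap metrics for one mask pair
#'
#' @inheritParams confusion_counts
#' @return one-row data.frame: dice, jaccard, sensitivity, specificity, and
#'   the four confusion counts.
#' @export
evaluate_mask <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  d <- suppressMessages(dice_score(pred, truth))
  data.frame(dice = d, jaccard = jaccard_from_dice(d),
             sensitivity = suppressMessages(sensitivity(cc)),
             specificity = suppressMessages(specificity(cc)),
             TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN)
}

#' Welch two-sample t-test between two sets of per-image scores
#'
#' Two-sided, unequal variances, significance flagged at alpha = 0.05. When
#' both samples have zero variance the test statistic is degenerate: equal
#' constants give t = 0, p = 1 by convention; unequal constants give
#' infinite t, p = 0 (both with a message).
#'
#' @param scores_a,scores_b numeric vectors of length >= 2 (e.g. per-image
#'   Dice scores of two methods).
#' @return list with `t`, `p`, and `significant` (p <= 0.05).
#' @export
two_sample_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) < 2 || length(scores_b) < 2)
    stop("both samples need length >= 2", call. = FALSE)
  if (any(!is.finite(scores_a)) || any(!is.finite(scores_b)))
    stop("scores must be finite", call. = FALSE)
  if (sd(scores_a) == 0 && sd(scores_b) == 0) {
    if (mean(scores_a) == mean(scores_b)) {
      message("identical constant samples; t = 0, p = 1 by convention")
      return(list(t = 0, p = 1, significant = FALSE))
    }
    message("distinct constant samples; |t| = Inf, p = 0 by convention")
    return(list(t = sign(mean(scores_a) - mean(scores_b)) * Inf, p = 0,
                significant = TRUE))
  }
  tt <- t.test(scores_a, scores_b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value <= 0.05)
}

#' Evaluate the ensemble and every standalone method on a fixture suite
#'
#' Runs [segment_lesion()] for the ensemble and each individual method on
#' every fixture, scores each mask against the exact ground truth, and
#' aggregates: per-image metrics, per-method means, and Welch t-tests of the
#' ensemble's per-image Dice against each standalone method's.
#'
#' @param fixtures list of fixtures from [generate_suite()] (each with
#'   `image`, `mask`, `id`).
#' @param methods character vector of runs; default the ensemble plus all
#'   five standalone methods.
#' @param seed seed forwarded to the stochastic Harris-hawks stage.
#' @param ... further arguments passed to [segment_lesion()].
#' @return list of class `eval_report`: `per_image` (data.frame), `aggregate`
#'   (per-method metric means), `ttests` (ensemble vs each method, when the
#'   ensemble was run).
#' @export
evaluate_suite <- function(fixtures,
                           methods = c("ensemble", "otsu", "acm", "kapur",
                                       "hho", "gray"),
                           seed = 1L, ...) {
  rows <- list()
  for (fx in fixtures) {
    for (m in methods) {
      res <- segment_lesion(fx$image, method = m, seed = seed, ...)
      met <- evaluate_mask(res$mask, fx$mask)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(image_id = fx$id, stratum = fx$stratum, method = m,
                   winner = res$winner),
        met)
    }
  }
  per_image <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_image, per_image$method), function(d)
    data.frame(method = d$method[1], n = nrow(d),
               dice = mean(d$dice), jaccard = mean(d$jaccard),
               sensitivity = mean(d$sensitivity, na.rm = TRUE),
               specificity = mean(d$specificity, na.rm = TRUE))))
  agg <- agg[order(match(agg$method, methods)), ]
  rownames(agg) <- NULL
  ttests <- NULL
  if ("ensemble" %in% methods && length(methods) > 1L) {
    ens <- per_image$dice[per_image$method == "ensemble"]
    ttests <- do.call(rbind, lapply(setdiff(methods, "ensemble"), function(m) {
      other <- per_image$dice[per_image$method == m]
      tt <- suppressMessages(two_sample_ttest(ens, other))
      data.frame(comparison = paste0("ensemble_vs_", m),
                 t = tt$t, p = tt$p, significant = tt$significant)
    }))
  }
  structure(list(per_image = per_image, aggregate = agg, ttests = ttests),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Segmentation evaluation over", length(unique(x$per_image$image_id)),
      "images\n\nPer-method means:\n")
  print(x$aggregate, row.names = FALSE, digits = 4)
  if (!is.null(x$ttests)) {
    cat("\nWelch t-tests on per-image Dice (ensemble vs method):\n")
    print(x$ttests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write / read an evaluation report as CSV
#'
#' The per-image table round-trips exactly.
#'
#' @param report an `eval_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(report$per_image, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
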