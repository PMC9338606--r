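# ROC machinery, clinical high-sensitivity metrics, and the feature
# separation diagnostics (odds ratios, one-sided Welch t, chi-squared with
# Bonferroni) used to check that a cohort shows the expected directions.

check_binary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute ROC metrics")
}

#' Empirical ROC curve
#'
#' Equal scores are grouped into a single threshold step (diagonal segment),
#' so the curve starts at (0, 0) and ends at (1, 1) with both coordinates
#' non-decreasing.
#'
#' @param scores Numeric pathogenicity scores (higher = more pathogenic).
#' @param labels 0/1 vector (1 = pathogenic).
#' @return `data.frame` with `threshold`, `fpr`, `tpr`; the first vertex has
#'   threshold `Inf`.
#' @export
roc_curve <- function(scores, labels) {
  check_binary(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  pos_by_thr <- rowsum(as.numeric(labels == 1), group = scores)
  neg_by_thr <- rowsum(as.numeric(labels == 0), group = scores)
  # rowsum groups are sorted ascending; reverse to descending thresholds
  ord <- order(as.numeric(rownames(pos_by_thr)), decreasing = TRUE)
  tpr <- cumsum(pos_by_thr[ord, 1L]) / np
  fpr <- cumsum(neg_by_thr[ord, 1L]) / nn
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over tie-grouped thresholds (equals the Mann-Whitney
#' statistic with ties counted half).
#' @inheritParams roc_curve
#' @export
auroc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  n <- nrow(rc)
  sum(diff(rc$fpr) * (rc$tpr[-1L] + rc$tpr[-n]) / 2)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation: `sum((R_i - R_{i-1}) * P_i)` over descending
#' thresholds (the average-precision convention).
#' @inheritParams roc_curve
#' @export
auprc <- function(scores, labels) {
  check_binary(scores, labels)
  np <- sum(labels == 1)
  pos_by_thr <- rowsum(as.numeric(labels == 1), group = scores)
  cnt_by_thr <- rowsum(rep(1, length(scores)), group = scores)
  ord <- order(as.numeric(rownames(pos_by_thr)), decreasing = TRUE)
  tp <- cumsum(pos_by_thr[ord, 1L])
  n_called <- cumsum(cnt_by_thr[ord, 1L])
  recall <- tp / np
  precision <- tp / n_called
  sum(diff(c(0, recall)) * precision)
}

#' AUROC restricted to the high-sensitivity region
#'
#' Normalised area between the ROC curve and the sensitivity floor: with the
#' ROC expressed as FPR(t) along TPR = t, this is
#' `integral over t in [floor, 1] of (1 - FPR(t)) dt / (1 - floor)`,
#' using linear interpolation between ROC vertices where the curve crosses
#' the floor. A perfect classifier scores 1; the chance diagonal scores
#' `(1 - floor) / 2`.
#'
#' @inheritParams roc_curve
#' @param sensitivity_floor Lower TPR bound of the region (default 0.95).
#' @export
hsr_auroc <- function(scores, labels, sensitivity_floor = 0.95) {
  stopifnot(sensitivity_floor >= 0, sensitivity_floor < 1)
  rc <- roc_curve(scores, labels)
  area <- 0
  for (i in seq_len(nrow(rc) - 1L)) {
    t1 <- rc$tpr[i]; t2 <- rc$tpr[i + 1L]
    f1 <- rc$fpr[i]; f2 <- rc$fpr[i + 1L]
    if (t2 <= sensitivity_floor || t2 == t1) next
    lo <- max(t1, sensitivity_floor)
    # FPR linear in t on the segment
    ffun <- function(t) f1 + (f2 - f1) * (t - t1) / (t2 - t1)
    area <- area + (t2 - lo) * (1 - (ffun(lo) + ffun(t2)) / 2)
  }
  area / (1 - sensitivity_floor)
}

#' True-negative rate at a sensitivity target
#'
#' `1 - FPR` at the least-stringent score threshold whose sensitivity is at
#' least `target` (the fraction of benign variants a clinician can discard
#' while keeping `target` of pathogenic ones).
#' @inheritParams roc_curve
#' @param target Required sensitivity (default 0.95).
#' @export
tnr_at_sensitivity <- function(scores, labels, target = 0.95) {
  check_binary(scores, labels)
  theta <- calibrate_threshold(scores, labels, target)
  1 - mean(scores[labels == 0] >= theta)
}

#' Odds ratio with 95% confidence interval for a 2x2 table
#'
#' `OR = (a d) / (b c)` with the Haldane-Anscombe 0.5 correction applied to
#' every cell when any cell is zero; the CI is the Woolf log interval
#' `exp(log OR +/- 1.96 sqrt(sum(1/cell)))`.
#'
#' @param table 2x2 matrix or length-4 vector `(a, b, c, d)` read row-wise.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(table) {
  x <- as.numeric(table)
  stopifnot(length(x) == 4L, all(x >= 0))
  if (any(x == 0)) x <- x + 0.5
  or <- (x[1L] * x[4L]) / (x[2L] * x[3L])
  se <- sqrt(sum(1 / x))
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}

#' One-sided Welch's t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom; `alternative =
#' "greater"` tests mean(x) > mean(y).
#' @param x,y Numeric samples (n >= 2 each).
#' @param alternative `"greater"` or `"less"`.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1L) + vy^2 / (length(y) - 1L))
  p <- if (alternative == "greater") stats::pt(t, df, lower.tail = FALSE)
       else stats::pt(t, df)
  list(t = t, df = df, p = p)
}

#' Pearson chi-squared tests with Bonferroni correction
#'
#' @param tables List of 2x2 count tables.
#' @param m Number of tests in the family (default `length(tables)`).
#' @return Numeric vector of adjusted Q values `min(1, m * p)`.
#' @export
chi2_bonferroni <- function(tables, m = length(tables)) {
  stopifnot(m >= 1L)
  vapply(tables, function(tb) {
    p <- stats::chisq.test(matrix(as.numeric(tb), 2L, 2L, byrow = TRUE),
                           correct = FALSE)$p.value
    min(1, m * p)
  }, 0)
}

#' Full metric report for one score set
#'
#' @inheritParams roc_curve
#' @param sensitivity_floor Floor for [hsr_auroc()] and [tnr_at_sensitivity()].
#' @return List with `auroc`, `auprc`, `hsr_auroc`, `tnr_at_95`, `n`,
#'   `n_pathogenic`.
#' @export
evaluate_scores <- function(scores, labels, sensitivity_floor = 0.95) {
  list(auroc = auroc(scores, labels),
       auprc = auprc(scores, labels),
       hsr_auroc = hsr_auroc(scores, labels, sensitivity_floor),
       tnr_at_95 = tnr_at_sensitivity(scores, labels, sensitivity_floor),
       n = length(labels), n_pathogenic = sum(labels == 1))
}
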