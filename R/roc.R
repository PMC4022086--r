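# ROC construction, trapezoid AUC, Hanley-McNeil interval, Youden cutoff,
# and exact binomial operating-point statistics.

#' Empirical ROC curve for an integer score
#'
#' For every threshold c in 0..29 an observation is classified positive iff
#' its score is >= c; sensitivity is the positive-class exceedance fraction
#' and specificity the negative-class sub-threshold fraction. The AUC is the
#' trapezoid area over the empirical (1 - specificity, sensitivity) points,
#' which for a discrete score equals the tie-corrected Mann-Whitney
#' probability P(pos > neg) + P(pos = neg)/2.
#'
#' @param scores_pos Integer scores (0..28) of the positive class.
#' @param scores_neg Integer scores (0..28) of the negative class.
#' @return Object of class `mss_roc`: list with `thresholds` (0..29),
#'   `sens`, `spec`, `auc`, `auc_ci95`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_curve(c(5, 9, 28), c(0, 1, 2))$auc
roc_curve <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  check_scores <- function(x, lab) {
    if (any(is.na(x)) || any(x < 0) || any(x > 28)) {
      stop(lab, " scores must be in 0..28 without NA", call. = FALSE)
    }
  }
  check_scores(scores_pos, "positive")
  check_scores(scores_neg, "negative")
  thresholds <- 0:29
  sens <- vapply(thresholds, function(c) mean(scores_pos >= c), numeric(1))
  spec <- vapply(thresholds, function(c) mean(scores_neg < c), numeric(1))
  # trapezoid over (1 - spec, sens), ordered from (1,1) at c=0 to (0,0)
  fpr <- 1 - spec
  auc <- sum(-diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  ci <- auc_ci_hanley(auc, length(scores_pos), length(scores_neg))
  structure(list(thresholds = thresholds, sens = sens, spec = spec,
                 auc = auc, auc_ci95 = ci,
                 n_pos = length(scores_pos), n_neg = length(scores_neg)),
            class = "mss_roc")
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval using the Hanley-McNeil standard error
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`; the interval is
#' `A +/- 1.96 SE`, clipped to `[0, 1]`.
#'
#' @param auc Observed area under the curve.
#' @param n_pos,n_neg Class sizes.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
auc_ci_hanley <- function(auc, n_pos, n_neg, conf_level = 0.95) {
  if (n_pos < 2L || n_neg < 2L) stop("need >= 2 per class", call. = FALSE)
  if (auc <= 0 || auc >= 1) {
    warning("degenerate AUC; interval clipped", call. = FALSE)
    auc <- min(max(auc, 0), 1)
  }
  a <- auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(lower = max(0, a - z * se), upper = min(1, a + z * se))
}

#' Youden-index cutoff
#'
#' Chooses the score threshold maximizing J = sensitivity + specificity - 1
#' on an [roc_curve()] result. Ties are broken toward the lowest threshold
#' (favouring sensitivity).
#'
#' @param roc An `mss_roc`.
#' @return List with `cutoff` (integer threshold) and `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  j <- roc$sens + roc$spec - 1
  best <- which.max(j)  # which.max returns the first (lowest) maximizer
  list(cutoff = roc$thresholds[best], youden_j = j[best])
}

#' Exact Clopper-Pearson binomial interval
#'
#' Inverts the binomial tail probabilities via beta quantiles:
#' lower = `qbeta(a/2, x, n-x+1)` (0 when x = 0), upper =
#' `qbeta(1-a/2, x+1, n-x)` (1 when x = n).
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(20, 20)  # lower bound 0.025^(1/20)
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Operating-point statistics at a fixed cutoff
#'
#' Sensitivity, specificity, positive and negative predictive value of the
#' rule "positive iff score >= cutoff", each with an exact 95%
#' Clopper-Pearson interval. Predictive values use the sample prevalence.
#' A predictive value with a zero denominator is returned as NA with an
#' NA interval.
#'
#' @param scores_pos,scores_neg Integer scores (0..28) per class.
#' @param cutoff Threshold in 0..29.
#' @return List of class `mss_operating_point` with elements `sens`, `spec`,
#'   `ppv`, `npv` (each a list `estimate`, `ci`, `x`, `n`), plus `cutoff`
#'   and `youden_j`.
#' @export
operating_point <- function(scores_pos, scores_neg, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 29)
  tp <- sum(scores_pos >= cutoff)
  fn <- length(scores_pos) - tp
  tn <- sum(scores_neg < cutoff)
  fp <- length(scores_neg) - tn
  prop <- function(x, n) {
    if (n == 0L) {
      return(list(estimate = NA_real_,
                  ci = c(lower = NA_real_, upper = NA_real_), x = x, n = n))
    }
    list(estimate = x / n, ci = clopper_pearson(x, n), x = x, n = n)
  }
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, tn + fp)
  structure(list(sens = sens, spec = spec,
                 ppv = prop(tp, tp + fp), npv = prop(tn, tn + fn),
                 cutoff = cutoff,
                 youden_j = sens$estimate + spec$estimate - 1),
            class = "mss_operating_point")
}

#' Assemble the ROC sample from an experiment
#'
#' The classification unit is the single assessment, pooled over the whole
#' monitoring timeline: positives are all scheduled analysis-rater
#' assessments of septic mice that died or were euthanized within the
#' horizon; negatives are all scheduled analysis-rater assessments of sham
#' mice. Septic survivors are excluded, so the score is evaluated on its
#' ability to separate healthy animals from animals on a lethal trajectory
#' at an arbitrary point of their course.
#'
#' @param experiment An `mss_experiment` (or list with `mice` and
#'   `assessments`).
#' @param analysis_rater Rater id whose scores are used.
#' @return List with integer vectors `scores_pos` and `scores_neg` and the
#'   count `n_excluded_septic_survivors`.
#' @export
build_roc_inputs <- function(experiment, analysis_rater = "R1") {
  mice <- experiment$mice
  a <- experiment$assessments
  a <- a[a$rater_id == analysis_rater, , drop = FALSE]
  sham_ids <- mice$mouse_id[mice$group == "sham"]
  septic <- mice[mice$group != "sham", , drop = FALSE]
  if (nrow(septic) == 0L) {
    stop("no septic mice in the experiment", call. = FALSE)
  }
  dead_ids <- septic$mouse_id[septic$outcome %in% c("died", "euthanized")]
  if (length(dead_ids) == 0L) {
    stop("no septic non-survivors: positive class is empty", call. = FALSE)
  }
  if (length(sham_ids) == 0L) {
    stop("no sham mice: negative class is empty", call. = FALSE)
  }
  list(scores_pos = a$total[a$mouse_id %in% dead_ids],
       scores_neg = a$total[a$mouse_id %in% sham_ids],
       n_excluded_septic_survivors = nrow(septic) - length(dead_ids))
}

#' Discrimination block of the validation report
#'
#' Builds the pooled-assessment ROC sample, the ROC curve with AUC and
#' Hanley-McNeil interval, selects the Youden cutoff, and computes the
#' operating point with exact intervals at that cutoff.
#'
#' @inheritParams build_roc_inputs
#' @return List of class `mss_discrimination`: `roc`, `cutoff`, `youden_j`,
#'   `operating_point`, `n_excluded_septic_survivors`.
#' @export
discrimination_block <- function(experiment, analysis_rater = "R1") {
  inp <- build_roc_inputs(experiment, analysis_rater)
  roc <- roc_curve(inp$scores_pos, inp$scores_neg)
  yj <- youden_cutoff(roc)
  op <- operating_point(inp$scores_pos, inp$scores_neg, yj$cutoff)
  structure(list(roc = roc, cutoff = yj$cutoff, youden_j = yj$youden_j,
                 operating_point = op,
                 n_excluded_septic_survivors = inp$n_excluded_septic_survivors),
            class = "mss_discrimination")
}

#' @export
print.mss_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$auc_ci95[["lower"]], x$auc_ci95[["upper"]],
              x$n_pos, x$n_neg))
  invisible(x)
}
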