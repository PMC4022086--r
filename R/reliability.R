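# Internal consistency and inter-rater reliability, from first principles.

#' Cronbach's alpha
#'
#' Internal-consistency coefficient of a multi-item scale,
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`,
#' with unbiased (n-1) sample variances.
#'
#' @param item_matrix Numeric matrix or data.frame, one row per subject
#'   (here: per assessment) and one column per item.
#' @return Scalar alpha (<= 1; can be negative for incoherent scales).
#' @export
#' @examples
#' m <- cbind(a = c(0, 2, 4), b = c(1, 2, 3))
#' cronbach_alpha(m)  # 8/9
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (ncol(m) < 2L) stop("need at least 2 items", call. = FALSE)
  if (anyNA(m)) stop("item matrix must be complete", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    stop("total-score variance is zero; alpha is undefined", call. = FALSE)
  }
  item_vars <- apply(m, 2L, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

# Two-way crossed ANOVA mean squares for an n x k complete table
# (subjects x raters), computed from sums of squares.
two_way_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure: the
#' reliability of one rating when every subject is scored by the same set
#' of raters, themselves treated as a random sample. Computed from the
#' two-way ANOVA mean squares as
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with a 95% confidence interval by the F-distribution method of McGraw &
#' Wong (1996).
#'
#' @param score_table Numeric matrix or data.frame, one row per subject
#'   (here: mouse-by-timepoint pairs with both raters observed), one column
#'   per rater. Must be complete; perform listwise deletion upstream.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci` (lower, upper), `n_subjects`, `n_raters`,
#'   and the ANOVA mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_way <- function(score_table, conf_level = 0.95) {
  m <- as.matrix(score_table)
  if (anyNA(m)) {
    stop("score table has missing cells; drop incomplete subjects upstream",
         call. = FALSE)
  }
  if (nrow(m) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (ncol(m) < 2L) stop("need at least 2 raters", call. = FALSE)
  ms <- two_way_mean_squares(m)
  n <- ms$n; k <- ms$k
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)

  # McGraw & Wong F-based interval for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (ms$msr - f_l * ms$mse) /
    (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  upper <- n * (f_u * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)

  list(icc = icc, ci = c(lower = lower, upper = upper),
       n_subjects = n, n_raters = k,
       msr = ms$msr, msc = ms$msc, mse = ms$mse)
}

#' Friedman's test for repeated measures
#'
#' Rank-based test that blocks (here: mice) show no systematic differences
#' across repeated conditions (here: timepoints). Uses mid-ranks for ties
#' and the standard tie correction; the p-value is from the chi-square
#' distribution with k-1 degrees of freedom.
#'
#' @param block_matrix Numeric matrix, one row per block, one column per
#'   condition; must be complete.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
friedman_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m)) stop("block matrix must be complete", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("need at least 2 blocks and 2 conditions", call. = FALSE)
  }
  ranks <- t(apply(m, 1L, rank))  # mid-ranks within block
  col_rank_sums <- colSums(ranks)
  numer <- 12 * sum((col_rank_sums - n * (k + 1) / 2)^2)
  # tie correction subtracts sum(t^3 - t)/(k - 1) from the denominator
  tie_term <- sum(apply(m, 1L, function(row) {
    t_sizes <- table(row)
    sum(t_sizes^3 - t_sizes)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) {
    # every block entirely tied: no evidence of any difference
    return(list(statistic = 0, df = k - 1, p_value = 1))
  }
  stat <- numer / denom
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Reliability block of the validation report
#'
#' Computes Cronbach's alpha on the seven-item matrix of the analysis
#' rater's assessments of septic mice at the reliability timepoints, and
#' ICC(2,1) on the two raters' total scores over all mouse-by-timepoint
#' pairs (sham and septic) alive at those timepoints.
#'
#' @param experiment An `mss_experiment`, or a list with `assessments` in
#'   the canonical long format.
#' @param analysis_rater Rater id used for the alpha item matrix (the
#'   non-blinded rater by default).
#' @param timepoints_h Assessment hours entering both statistics.
#' @param icc_groups Which groups enter the ICC table; defaults to septic
#'   groups only, matching the reference analysis of inter-rater agreement
#'   on diseased animals.
#' @return List of class `mss_reliability`: `cronbach_alpha`, `icc`,
#'   `icc_ci95`, `n_subjects`, `n_raters`, `timepoints_used`.
#' @export
reliability_block <- function(experiment, analysis_rater = "R1",
                              timepoints_h = c(2, 12, 14, 16, 18, 20, 24),
                              icc_groups = c("fs45", "fs90", "fs180")) {
  a <- experiment$assessments
  items <- mss_items()
  septic <- a[a$group != "sham" & a$rater_id == analysis_rater &
                a$time_h %in% timepoints_h, , drop = FALSE]
  if (nrow(septic) < 2L) stop("too few septic assessments", call. = FALSE)
  alpha <- cronbach_alpha(as.matrix(septic[, items]))

  icc_rows <- a[a$group %in% icc_groups & a$time_h %in% timepoints_h, ,
                drop = FALSE]
  raters <- sort(unique(a$rater_id))
  wide <- stats::reshape(
    icc_rows[, c("mouse_id", "time_h", "rater_id", "total")],
    idvar = c("mouse_id", "time_h"), timevar = "rater_id",
    direction = "wide")
  score_cols <- paste0("total.", raters)
  tab <- as.matrix(wide[, score_cols])
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  icc <- icc_two_way(tab)

  structure(list(cronbach_alpha = alpha,
                 icc = icc$icc, icc_ci95 = icc$ci,
                 n_subjects = icc$n_subjects, n_raters = icc$n_raters,
                 timepoints_used = timepoints_h),
            class = "mss_reliability")
}

#' Check that sham scores are stable over time
#'
#' Applies [friedman_test()] to the sham mice's total scores (analysis
#' rater) across a set of timepoints; a large p-value supports pooling sham
#' assessments over time as a single control sample.
#'
#' @inheritParams reliability_block
#' @return The [friedman_test()] result.
#' @export
sham_pooling_check <- function(experiment, analysis_rater = "R1",
                               timepoints_h = c(2, 12, 14, 16, 18, 20, 24)) {
  a <- experiment$assessments
  sham <- a[a$group == "sham" & a$rater_id == analysis_rater &
              a$time_h %in% timepoints_h, c("mouse_id", "time_h", "total")]
  wide <- stats::reshape(sham, idvar = "mouse_id", timevar = "time_h",
                         direction = "wide")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  friedman_test(m)
}
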