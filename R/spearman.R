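# Rank correlation with exact small-sample permutation p-values.

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of mid-ranks, which handles ties exactly.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Scalar rho in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(1:4, c(10, 30, 20, 40))  # 0.8
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero rank variance; rho is undefined", call. = FALSE)
  }
  stats::cor(rx, ry)
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Exact permutation p-value for Spearman's rho
#'
#' Enumerates all n! permutations of one vector's ranks against the other's
#' and reports the fraction of permutations with rho at least as extreme as
#' observed: `rho_perm >= rho_obs` for `alternative = "greater"` or
#' `|rho_perm| >= |rho_obs|` for `"two_sided"`. Feasible for n <= 8
#' (8! = 40,320 permutations); larger samples should use the t
#' approximation.
#'
#' @param x,y Numeric vectors of equal length, 3 <= n <= 8.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return List with `rho`, `p_value`, `n`, `method = "exact_permutation"`.
#' @export
#' @examples
#' spearman_exact_p(1:4, c(2, 5, 9, 14))$p_value  # 1/24
spearman_exact_p <- function(x, y, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (n > 8L) {
    stop("n > 8: enumeration infeasible, use spearman_t_p()", call. = FALSE)
  }
  rho_obs <- spearman_rho(x, y)
  rx <- rank(x)
  ry <- rank(y)
  perms <- all_permutations(n)
  # rho for every permutation at once: Pearson on centred ranks reduces to
  # a single matrix-vector product
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  perm_mat <- matrix(ryc[perms], nrow = nrow(perms))
  rho_perm <- as.vector(perm_mat %*% rxc) / denom
  eps <- 1e-12
  p <- if (alternative == "greater") {
    mean(rho_perm >= rho_obs - eps)
  } else {
    mean(abs(rho_perm) >= abs(rho_obs) - eps)
  }
  list(rho = rho_obs, p_value = p, n = n, method = "exact_permutation")
}

#' t-approximation p-value for Spearman's rho
#'
#' Large-sample p-value from `t = rho sqrt((n-2)/(1-rho^2))` on n-2 degrees
#' of freedom.
#'
#' @inheritParams spearman_exact_p
#' @return List with `rho`, `p_value`, `n`, `method = "t_approximation"`.
#' @export
spearman_t_p <- function(x, y, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  rho <- spearman_rho(x, y)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- stats::pt(tval, df = n - 2, lower.tail = FALSE)
    if (alternative == "two_sided") p <- min(1, 2 * min(p, 1 - p))
  }
  list(rho = rho, p_value = p, n = n, method = "t_approximation")
}

#' Correlate marker profiles with mean MSS
#'
#' Pairs the per-timepoint mean MSS with each marker's group-mean level at
#' the panel timepoints (pooled sham baseline, then 3, 12 and 24 h post
#' induction) and reports Spearman's rho with a one-sided (greater) exact
#' permutation p-value. The mean MSS at a panel timepoint is computed from
#' the analysis rater's assessments of the marker group's mice at the
#' latest scheduled assessment time not after the timepoint (2 h for the
#' 3-h sample); the sham baseline pools all sham assessments.
#'
#' @param experiment An `mss_experiment`.
#' @param analysis_rater Rater id whose scores are used.
#' @param marker_group Septic dose group the marker panel refers to.
#' @param alternative Passed to [spearman_exact_p()].
#' @return data.frame of class `mss_correlations` with one row per marker:
#'   `marker`, `rho`, `p_value`, `n_points`, `method`. Markers with a
#'   degenerate (constant) profile are skipped with a warning.
#' @export
correlate_markers <- function(experiment, analysis_rater = "R1",
                              marker_group = "fs90",
                              alternative = "greater") {
  a <- experiment$assessments
  a <- a[a$rater_id == analysis_rater, , drop = FALSE]
  sched <- sort(unique(a$time_h))
  at_or_before <- function(tp) max(sched[sched <= tp])
  mss_mean <- c(
    sham = mean(a$total[a$group == "sham"]),
    h3 = mean(a$total[a$group == marker_group & a$time_h == at_or_before(3)]),
    h12 = mean(a$total[a$group == marker_group & a$time_h == at_or_before(12)]),
    h24 = mean(a$total[a$group == marker_group & a$time_h == at_or_before(24)])
  )
  if (anyNA(mss_mean)) stop("missing MSS means at panel timepoints", call. = FALSE)

  markers <- experiment$markers
  out <- lapply(unique(markers$marker), function(m) {
    prof <- markers[markers$marker == m, , drop = FALSE]
    vals <- prof$value[match(c("sham", "h3", "h12", "h24"), prof$timepoint)]
    if (anyNA(vals)) {
      warning("marker '", m, "' missing a timepoint; skipped", call. = FALSE)
      return(NULL)
    }
    res <- tryCatch(
      spearman_exact_p(mss_mean, vals, alternative = alternative),
      error = function(e) {
        warning("marker '", m, "': ", conditionMessage(e), "; skipped",
                call. = FALSE)
        NULL
      })
    if (is.null(res)) return(NULL)
    data.frame(marker = m, rho = res$rho, p_value = res$p_value,
               n_points = res$n, method = res$method)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mss_correlations", class(res))
  res
}
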