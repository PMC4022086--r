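# Survival curves by dose group and score-conditional mortality windows.

#' Kaplan-Meier product-limit survival curve
#'
#' Deaths and humane euthanasias both count as events; the only censoring
#' is administrative at the horizon, so the estimate coincides with the
#' crude cumulative-mortality complement at every event time.
#'
#' @param mice data.frame with columns `mouse_id`, `group`, `outcome`
#'   (survived/died/euthanized), `outcome_time_h` (NA iff survived);
#'   typically one group's subset of `mss_experiment$mice`.
#' @param horizon_h Administrative censoring time (hours).
#' @return Object of class `mss_survival`: list with `times` (0 and the
#'   distinct event times), `surv`, `n_risk` (at-risk count just before
#'   each time), `n_event`, `group`.
#' @export
km_curve <- function(mice, horizon_h = 24) {
  if (nrow(mice) == 0L) stop("empty group", call. = FALSE)
  events <- mice$outcome %in% c("died", "euthanized")
  ev_times <- mice$outcome_time_h[events]
  if (any(is.na(ev_times))) {
    stop("event without outcome_time_h", call. = FALSE)
  }
  if (any(ev_times > horizon_h)) {
    stop("event time beyond the horizon", call. = FALSE)
  }
  n <- nrow(mice)
  times <- sort(unique(ev_times))
  surv <- numeric(length(times))
  n_risk <- integer(length(times))
  n_event <- integer(length(times))
  s <- 1
  at_risk <- n
  for (i in seq_along(times)) {
    d <- sum(ev_times == times[i])
    n_risk[i] <- at_risk
    n_event[i] <- d
    s <- s * (1 - d / at_risk)
    surv[i] <- s
    at_risk <- at_risk - d
  }
  group <- if (length(unique(mice$group)) == 1L) mice$group[1L] else "mixed"
  structure(list(times = c(0, times), surv = c(1, surv),
                 n_risk = c(n, n_risk), n_event = c(0L, n_event),
                 group = group),
            class = "mss_survival")
}

#' @export
print.mss_survival <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve, group %s: S(end) = %.3f (%d mice)\n",
              x$group, x$surv[length(x$surv)], x$n_risk[1L]))
  invisible(x)
}

#' Mortality within a window of first attaining a score
#'
#' Among mice whose analysis-rater total first reaches at least
#' `score_threshold` at some scheduled assessment time t0, the proportion
#' that die or are euthanized by t0 + `window_h` (closed boundary: an
#' outcome exactly at the window edge counts).
#'
#' @param experiment An `mss_experiment`.
#' @param score_threshold Integer score in 0..28.
#' @param window_h Positive window length in hours.
#' @param groups Dose groups considered (default the 90 mg/mL group, the
#'   dose the reference mortality-window figures describe).
#' @param analysis_rater Rater id whose scores define attainment.
#' @return List of class `mss_mortality_window`: `score_threshold`,
#'   `window_h`, `n_reached`, `n_died_within`, `proportion` (NA when no
#'   mouse reached the threshold).
#' @export
mortality_within_window <- function(experiment, score_threshold, window_h,
                                    groups = "fs90", analysis_rater = "R1") {
  stopifnot(score_threshold >= 0, score_threshold <= 28, window_h > 0)
  mice <- experiment$mice
  a <- experiment$assessments
  a <- a[a$rater_id == analysis_rater & a$group %in% groups, , drop = FALSE]
  ids <- mice$mouse_id[mice$group %in% groups]
  n_reached <- 0L
  n_died <- 0L
  for (id in ids) {
    am <- a[a$mouse_id == id, , drop = FALSE]
    hit <- am$time_h[am$total >= score_threshold]
    if (length(hit) == 0L) next
    t0 <- min(hit)
    n_reached <- n_reached + 1L
    rec <- mice[mice$mouse_id == id, ]
    if (rec$outcome %in% c("died", "euthanized") &&
        !is.na(rec$outcome_time_h) &&
        rec$outcome_time_h <= t0 + window_h) {
      n_died <- n_died + 1L
    }
  }
  structure(list(score_threshold = score_threshold, window_h = window_h,
                 n_reached = n_reached, n_died_within = n_died,
                 proportion = if (n_reached > 0L) n_died / n_reached
                              else NA_real_),
            class = "mss_mortality_window")
}
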