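# Murine Sepsis Score rubric: seven clinical items, each scored 0-4.

#' The seven MSS items, in canonical order
#'
#' The Murine Sepsis Score grades seven clinical variables -- coat appearance
#' (piloerection), level of consciousness, spontaneous activity, response to
#' auditory/tactile stimulus, eye closure, respiration rate, and respiration
#' quality -- each on an ordinal 0 (normal) to 4 (moribund) scale. The order
#' returned here is fixed and used for all serialization (CSV columns,
#' threshold matrices).
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' mss_items()
mss_items <- function() {
  c("appearance", "consciousness", "activity", "response_to_stimulus",
    "eyes", "respiration_rate", "respiration_quality")
}

# Validate a single set of item scores; returns the scores as a named
# numeric vector in canonical order, or stops naming the offending item.
validate_items <- function(items) {
  nm <- mss_items()
  if (is.list(items)) items <- unlist(items)
  if (is.null(names(items)) && length(items) == 7L) {
    names(items) <- nm
  }
  missing_items <- setdiff(nm, names(items))
  if (length(missing_items) > 0L) {
    stop("missing item score(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  items <- items[nm]
  for (j in nm) {
    v <- items[[j]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v %% 1 != 0 || v < 0 || v > 4) {
      stop("item '", j, "' must be an integer in 0..4 (got ",
           format(v), ")", call. = FALSE)
    }
  }
  items
}

#' Aggregate MSS total
#'
#' Sums the seven item scores of one assessment. Every item must be present
#' exactly once and lie in 0..4, so the total lies in 0..28.
#'
#' @param items Named numeric vector (or list) with one integer score in
#'   0..4 per item of [mss_items()]. An unnamed length-7 vector is taken to
#'   be in canonical item order.
#' @return Integer total in 0..28.
#' @export
#' @examples
#' mss_total(c(appearance = 2, consciousness = 3, activity = 3,
#'             response_to_stimulus = 2, eyes = 1,
#'             respiration_rate = 2, respiration_quality = 2))
mss_total <- function(items) {
  items <- validate_items(items)
  as.integer(sum(items))
}

#' Humane-endpoint euthanasia rule
#'
#' A mouse must be euthanized if its MSS total at any assessment is strictly
#' greater than 21, or if the score ascribed to respiration rate or
#' respiration quality increased by more than 3 points since the immediately
#' preceding assessment of the same mouse.
#'
#' @param current A list/one-row data.frame with at least `total`,
#'   `respiration_rate`, `respiration_quality`, `time_h`, `mouse_id`.
#' @param previous The preceding assessment of the same mouse in the same
#'   form, or `NULL` if this is the first assessment.
#' @return A list with `required` (logical) and `reason` (`"total"`,
#'   `"respiratory"`, or `NA_character_`). When both rules fire, `"total"`
#'   is reported.
#' @export
euthanasia_required <- function(current, previous = NULL) {
  cur <- as.list(current)
  if (!is.null(previous)) {
    prev <- as.list(previous)
    if (!is.null(cur$mouse_id) && !is.null(prev$mouse_id) &&
        !identical(as.character(cur$mouse_id), as.character(prev$mouse_id))) {
      stop("current and previous assessments belong to different mice",
           call. = FALSE)
    }
    if (!is.null(cur$time_h) && !is.null(prev$time_h) &&
        prev$time_h >= cur$time_h) {
      stop("previous assessment must precede the current one (",
           prev$time_h, " h >= ", cur$time_h, " h)", call. = FALSE)
    }
  }
  if (cur$total > 21) {
    return(list(required = TRUE, reason = "total"))
  }
  if (!is.null(previous)) {
    prev <- as.list(previous)
    d_rate <- cur$respiration_rate - prev$respiration_rate
    d_qual <- cur$respiration_quality - prev$respiration_quality
    if (d_rate > 3 || d_qual > 3) {
      return(list(required = TRUE, reason = "respiratory"))
    }
  }
  list(required = FALSE, reason = NA_character_)
}

#' Monitoring schedule after sepsis induction
#'
#' Mice are assessed every 2 hours after induction for the first 12 hours,
#' then every hour thereafter, up to the horizon. Induction time (0 h) is
#' not itself a scheduled assessment.
#'
#' @param horizon_h Positive number of hours to schedule up to (inclusive).
#' @return Strictly increasing numeric vector of assessment times in hours.
#' @export
#' @examples
#' monitoring_schedule(24)
#' monitoring_schedule(6)
monitoring_schedule <- function(horizon_h) {
  if (!is.numeric(horizon_h) || length(horizon_h) != 1L || is.na(horizon_h) ||
      horizon_h <= 0) {
    stop("horizon_h must be a single positive number", call. = FALSE)
  }
  two_hourly <- seq(2, 12, by = 2)
  out <- two_hourly[two_hourly <= horizon_h]
  if (horizon_h >= 13) {
    out <- c(out, seq(13, floor(horizon_h), by = 1))
  }
  out
}
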