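# End-to-end validation pipeline: CSV I/O with schema checks, stage
# orchestration, JSON/markdown reporting.

assessment_columns <- function() {
  c("mouse_id", "group", "time_h", "rater_id", mss_items(), "total")
}

#' Read the canonical CSV inputs
#'
#' `read_assessments()` reads the long-format assessments table and
#' validates the schema: exact columns, item scores in 0..4, totals equal
#' to the item sum. `read_outcomes()` reads the per-mouse outcomes table
#' (`mouse_id`, `group`, `outcome`, `outcome_time_h`); `read_markers()`
#' reads the marker panel (`marker`, `timepoint`, `value`). Schema
#' violations raise errors naming the file, row and column.
#'
#' @param path CSV file path.
#' @return The validated data.frame.
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- assessment_columns()
  if (!identical(sort(names(df)), sort(want))) {
    stop("schema error in ", path, ": expected columns ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  df <- df[, want]
  for (j in mss_items()) {
    bad <- which(!(df[[j]] %in% 0:4))
    if (length(bad) > 0L) {
      stop("schema error in ", path, ", row ", bad[1L], ", column '", j,
           "': item score ", df[[j]][bad[1L]], " outside 0..4",
           call. = FALSE)
    }
  }
  sums <- rowSums(df[, mss_items()])
  bad <- which(sums != df$total)
  if (length(bad) > 0L) {
    stop("schema error in ", path, ", row ", bad[1L],
         ", column 'total': total does not equal the item sum",
         call. = FALSE)
  }
  if (any(df$time_h < 0)) {
    stop("schema error in ", path, ": negative time_h", call. = FALSE)
  }
  df
}

#' @rdname read_assessments
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("mouse_id", "group", "outcome", "outcome_time_h")
  if (!identical(sort(names(df)), sort(want))) {
    stop("schema error in ", path, ": expected columns ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  df <- df[, want]
  bad <- which(!(df$outcome %in% c("survived", "died", "euthanized")))
  if (length(bad) > 0L) {
    stop("schema error in ", path, ", row ", bad[1L],
         ", column 'outcome': unknown outcome '", df$outcome[bad[1L]], "'",
         call. = FALSE)
  }
  bad <- which((df$outcome == "survived") != is.na(df$outcome_time_h))
  if (length(bad) > 0L) {
    stop("schema error in ", path, ", row ", bad[1L],
         ": outcome_time_h must be present iff the mouse did not survive",
         call. = FALSE)
  }
  df
}

#' @rdname read_assessments
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("marker", "timepoint", "value")
  if (!identical(sort(names(df)), sort(want))) {
    stop("schema error in ", path, ": expected columns ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  df[, want]
}

#' Run the full score-validation pipeline
#'
#' Executes the validation stages in order -- reliability (alpha, ICC,
#' sham pooling check), discrimination (ROC/AUC, Youden cutoff, operating
#' point), survival curves per dose group, score-conditional mortality
#' windows, and marker correlations -- and returns a consolidated report.
#' Inputs may be file paths (CSV, validated on read) or in-memory
#' data.frames/`mss_experiment` parts. The pipeline never mutates its
#' inputs and is deterministic given them.
#'
#' @param assessments Path to the assessments CSV or a data.frame.
#' @param outcomes Path to the outcomes CSV or a data.frame.
#' @param markers Optional path to the marker CSV or a data.frame; when
#'   absent the marker stage is marked skipped.
#' @param analysis_rater Rater id used for single-rater stages.
#' @param mortality_windows data.frame of `score_threshold`, `window_h`
#'   pairs to evaluate; the default covers the reference windows (1 h and
#'   2 h after score 10, 1 h and 2 h after score 15).
#' @param out_dir Optional directory; when given, the JSON report, the
#'   markdown summary, the ROC table, the survival curves and the
#'   mortality-window/correlation tables are written there.
#' @return Object of class `mss_report` with blocks `reliability`,
#'   `discrimination`, `survival`, `mortality_windows`, `correlations`,
#'   `counts` and `provenance`.
#' @export
run_pipeline <- function(assessments, outcomes, markers = NULL,
                         analysis_rater = "R1",
                         mortality_windows = data.frame(
                           score_threshold = c(10, 10, 15, 15),
                           window_h = c(1, 2, 1, 2)),
                         out_dir = NULL) {
  a <- if (is.character(assessments)) read_assessments(assessments)
       else assessments
  mice <- if (is.character(outcomes)) read_outcomes(outcomes) else outcomes
  mk <- if (is.character(markers)) read_markers(markers) else markers
  experiment <- structure(list(mice = mice, assessments = a, markers = mk),
                          class = "mss_experiment")

  reliability <- reliability_block(experiment, analysis_rater)
  pooling <- tryCatch(sham_pooling_check(experiment, analysis_rater),
                      error = function(e) NULL)
  discrimination <- discrimination_block(experiment, analysis_rater)

  groups <- unique(mice$group)
  survival <- lapply(stats::setNames(groups, groups), function(g) {
    km_curve(mice[mice$group == g, , drop = FALSE],
             horizon_h = max(a$time_h))
  })

  windows <- lapply(seq_len(nrow(mortality_windows)), function(i) {
    mortality_within_window(experiment,
                            mortality_windows$score_threshold[i],
                            mortality_windows$window_h[i],
                            analysis_rater = analysis_rater)
  })

  correlations <- if (is.null(mk)) {
    structure(list(skipped = "no marker panel supplied"),
              class = "mss_skipped")
  } else {
    correlate_markers(experiment, analysis_rater)
  }

  counts <- list(
    n_mice = nrow(mice),
    n_assessments = nrow(a),
    n_septic_survivors_excluded_from_roc =
      discrimination$n_excluded_septic_survivors
  )
  report <- structure(list(
    reliability = reliability,
    sham_pooling = pooling,
    discrimination = discrimination,
    survival = survival,
    mortality_windows = windows,
    correlations = correlations,
    counts = counts,
    provenance = list(package_version =
                        as.character(utils::packageVersion("mssval")),
                      analysis_rater = analysis_rater,
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "mss_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a validation report to disk
#'
#' Writes `report.json` (machine-readable), `report.md` (the
#' [render_report()] summary), `roc_table.csv`, `survival_curves.csv`,
#' `mortality_windows.csv` and, when present, `marker_correlations.csv`.
#'
#' @param report An `mss_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  strip <- function(x) {
    if (is.data.frame(x)) return(as.data.frame(unclass(x),
                                               stringsAsFactors = FALSE))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report(report), file.path(dir, "report.md"))
  roc <- report$discrimination$roc
  utils::write.csv(data.frame(threshold = roc$thresholds, sens = roc$sens,
                              spec = roc$spec),
                   file.path(dir, "roc_table.csv"), row.names = FALSE)
  surv <- do.call(rbind, lapply(report$survival, function(s) {
    data.frame(group = s$group, time_h = s$times, surv = s$surv,
               n_risk = s$n_risk)
  }))
  utils::write.csv(surv, file.path(dir, "survival_curves.csv"),
                   row.names = FALSE)
  mw <- do.call(rbind, lapply(report$mortality_windows, function(w) {
    data.frame(score_threshold = w$score_threshold, window_h = w$window_h,
               n_reached = w$n_reached, n_died_within = w$n_died_within,
               proportion = w$proportion)
  }))
  utils::write.csv(mw, file.path(dir, "mortality_windows.csv"),
                   row.names = FALSE)
  if (!inherits(report$correlations, "mss_skipped")) {
    utils::write.csv(as.data.frame(unclass(report$correlations)),
                     file.path(dir, "marker_correlations.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Render a human-readable report summary
#'
#' Produces a markdown summary in the reporting style of a clinical-score
#' validation: reliability coefficients with intervals, AUC and cutoff with
#' operating-point intervals, per-group survival at the end of follow-up,
#' mortality windows, and marker correlations.
#'
#' @param report An `mss_report`.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  pct <- function(x) sprintf("%.0f%%", 100 * x)
  ci_pct <- function(ci) sprintf("(%.0f-%.0f%%)", 100 * ci[[1L]], 100 * ci[[2L]])
  rel <- report$reliability
  disc <- report$discrimination
  op <- disc$operating_point
  lines <- c(
    "# MSS validation report",
    "",
    "## Reliability",
    sprintf("- Cronbach's alpha (7 items, septic assessments): %.2f",
            rel$cronbach_alpha),
    sprintf("- Inter-rater ICC(2,1): %.2f (95%% CI: %.2f - %.2f), %d paired scores",
            rel$icc, rel$icc_ci95[["lower"]], rel$icc_ci95[["upper"]],
            rel$n_subjects)
  )
  if (!is.null(report$sham_pooling)) {
    lines <- c(lines, sprintf(
      "- Sham stability over time (Friedman): chi2 = %.2f, p = %.3f",
      report$sham_pooling$statistic, report$sham_pooling$p_value))
  }
  lines <- c(lines,
    "",
    "## Discrimination",
    sprintf("- AUC: %.3f (95%% CI: %.3f - %.3f); %d positive / %d negative assessments",
            disc$roc$auc, disc$roc$auc_ci95[["lower"]],
            disc$roc$auc_ci95[["upper"]], disc$roc$n_pos, disc$roc$n_neg),
    sprintf("- Youden cutoff: MSS >= %d (J = %.2f)", disc$cutoff,
            disc$youden_j),
    sprintf("- Sensitivity %s %s; specificity %s %s; PPV %s; NPV %s",
            pct(op$sens$estimate), ci_pct(op$sens$ci),
            pct(op$spec$estimate), ci_pct(op$spec$ci),
            pct(op$ppv$estimate), pct(op$npv$estimate)),
    sprintf("- Septic survivors excluded from the ROC sample: %d",
            disc$n_excluded_septic_survivors),
    "",
    "## Survival at end of follow-up")
  for (g in names(report$survival)) {
    s <- report$survival[[g]]
    lines <- c(lines, sprintf("- %s: %s (n = %d)", g,
                              pct(s$surv[length(s$surv)]), s$n_risk[1L]))
  }
  lines <- c(lines, "", "## Mortality windows")
  for (w in report$mortality_windows) {
    lines <- c(lines, sprintf(
      "- score >= %d, within %g h: %s (%d/%d)", w$score_threshold,
      w$window_h,
      if (is.na(w$proportion)) "undefined (none reached)" else pct(w$proportion),
      w$n_died_within, w$n_reached))
  }
  lines <- c(lines, "", "## Marker correlations")
  if (inherits(report$correlations, "mss_skipped")) {
    lines <- c(lines, sprintf("- markers: skipped (%s)",
                              report$correlations$skipped))
  } else {
    for (i in seq_len(nrow(report$correlations))) {
      r <- report$correlations[i, ]
      lines <- c(lines, sprintf("- %s: rho = %.2f, p = %.3f (n = %d, %s)",
                                r$marker, r$rho, r$p_value, r$n_points,
                                r$method))
    }
  }
  lines
}

#' @export
print.mss_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
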