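# Stochastic cohort simulator: latent-severity trajectories, two-rater
# ordinal scoring by threshold crossing, discrete-time mortality, and the
# humane-endpoint rule.

# Deterministic per-mouse substream seed. Group index and within-group index
# occupy disjoint bit ranges so changing one group's size never perturbs
# another group's draws.
mouse_seed <- function(seed, group_index, mouse_index) {
  base <- (abs(as.integer(seed)) %% 32768L) * 65536L
  base + group_index * 8192L + mouse_index
}

#' Simulate a fecal-induced-peritonitis scoring experiment
#'
#' Generates a full synthetic experiment under a configuration from
#' [default_config()]: per-mouse latent severity trajectories, assessments
#' by a non-blinded and a blinded rater at every scheduled monitoring time
#' while the mouse is alive, deaths from a score-dependent hazard, humane
#' euthanasias per [euthanasia_required()], and a group-mean marker panel.
#' Identical configurations (including `seed`) give identical output.
#'
#' @param config An `mss_config`; defaults to the shipped calibrated set.
#' @return An object of class `mss_experiment`: a list with
#' \describe{
#'   \item{mice}{data.frame: `mouse_id`, `group`, `outcome`
#'     (survived/died/euthanized), `outcome_time_h` (NA if survived).}
#'   \item{assessments}{data.frame in long format: `mouse_id`, `group`,
#'     `time_h`, `rater_id`, the seven item columns of [mss_items()], and
#'     `total`.}
#'   \item{markers}{data.frame of group-mean marker levels: `marker`,
#'     `timepoint` (one of sham/h3/h12/h24), `value`.}
#'   \item{config}{the configuration used.}
#' }
#' @export
#' @examples
#' exp1 <- simulate_experiment(default_config(seed = 1))
#' table(exp1$mice$group, exp1$mice$outcome)
simulate_experiment <- function(config = default_config()) {
  validate_config(config)
  times <- monitoring_schedule(config$horizon_h)
  groups <- names(config$n_per_group)
  items <- mss_items()
  th <- config$item_thresholds
  raters <- config$raters

  mice_list <- vector("list", sum(config$n_per_group))
  assess_list <- vector("list", sum(config$n_per_group))
  idx <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_g <- config$n_per_group[[g]]
    if (n_g == 0L) next
    for (i in seq_len(n_g)) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", g, i)
      set.seed(mouse_seed(config$seed, gi, i))
      sim <- simulate_mouse(id, g, config, times, th, items, raters)
      mice_list[[idx]] <- sim$mouse
      assess_list[[idx]] <- sim$assessments
    }
  }
  mice <- do.call(rbind, mice_list[seq_len(idx)])
  assessments <- do.call(rbind, assess_list[seq_len(idx)])
  rownames(mice) <- rownames(assessments) <- NULL

  markers <- do.call(rbind, lapply(names(config$marker_profiles), function(m) {
    prof <- config$marker_profiles[[m]]
    data.frame(marker = m, timepoint = c("sham", "h3", "h12", "h24"),
               value = unname(prof[c("sham", "h3", "h12", "h24")]))
  }))

  structure(list(mice = mice, assessments = assessments, markers = markers,
                 config = config),
            class = "mss_experiment")
}

# One mouse: draws its latent trajectory, walks the monitoring schedule,
# scores it with both raters, and resolves euthanasia/death per interval.
# RNG state must already be set by the caller.
simulate_mouse <- function(id, group, config, times, th, items, raters) {
  septic <- group != "sham"
  nt <- length(times)
  if (septic) {
    baseline <- stats::rnorm(1, config$septic_baseline_mean,
                             config$septic_baseline_sd)
    onset <- stats::rnorm(1, config$onset_mean_h, config$onset_sd_h)
    mu <- config$progression_rate_mean[[group]]
    cv <- config$progression_rate_cv
    sdlog <- sqrt(log(1 + cv^2))
    rate <- stats::rlnorm(1, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    fsd <- sqrt(log(1 + config$frailty_cv^2))
    frailty <- stats::rlnorm(1, meanlog = -fsd^2 / 2, sdlog = fsd)
    s_path <- baseline + pmax(0, times - onset) * rate +
      stats::rnorm(nt, 0, config$latent_noise_sd)
  } else {
    s_path <- config$sham_latent_mean +
      stats::rnorm(nt, 0, config$sham_latent_sd) +
      stats::rnorm(nt, 0, config$latent_noise_sd)
    frailty <- 1
  }

  n_items <- length(items)
  rows <- vector("list", nt)
  outcome <- "survived"
  outcome_time <- NA_real_
  prev_nonblinded <- NULL
  n_obs <- 0L
  for (k in seq_len(nt)) {
    t_k <- times[k]
    # observation noise scales with severity: scoring a well mouse is
    # nearly unambiguous, moribund items are contentious
    ramp <- min(1, max(config$noise_floor,
                       (s_path[k] - config$noise_ramp_start) /
                         (config$noise_ramp_latent - config$noise_ramp_start)))
    eps_item <- stats::rnorm(n_items, 0, config$item_noise_sd * ramp)
    scores <- matrix(0L, nrow = n_items, ncol = 2L,
                     dimnames = list(items, raters))
    for (r in 1:2) {
      eps_rater <- stats::rnorm(n_items, 0, config$rater_noise_sd * ramp)
      latent <- s_path[k] + eps_item + eps_rater
      scores[, r] <- vapply(seq_len(n_items),
                            function(j) sum(th[j, ] < latent[j]), integer(1))
    }
    totals <- colSums(scores)
    n_obs <- n_obs + 1L
    rows[[k]] <- data.frame(
      mouse_id = id, group = group, time_h = rep(t_k, 2L),
      rater_id = unname(raters),
      t(scores), total = as.integer(unname(totals)),
      row.names = NULL, check.names = FALSE
    )

    current <- c(list(mouse_id = id, time_h = t_k,
                      total = totals[[1L]]),
                 as.list(scores[, 1L]))
    verdict <- euthanasia_required(current, prev_nonblinded)
    if (verdict$required) {
      outcome <- "euthanized"
      outcome_time <- t_k
      break
    }
    prev_nonblinded <- current

    if (k < nt) {
      dt <- times[k + 1L] - t_k
      # death risk is driven by the true physiological severity (the
      # noise-free threshold crossings of the latent state), not by what a
      # rater happened to record
      true_total <- sum(vapply(seq_len(n_items),
                               function(j) sum(th[j, ] < s_path[k]),
                               integer(1)))
      h <- if (true_total < config$hazard_score_floor) 0 else
        frailty * min(config$hazard_cap,
                      config$hazard_baseline *
                        exp(config$hazard_score_coef *
                              (true_total - config$hazard_score_floor)))
      if (stats::runif(1) < 1 - exp(-h * dt)) {
        outcome <- "died"
        outcome_time <- t_k + dt / 2
        break
      }
    }
  }

  assessments <- do.call(rbind, rows[seq_len(n_obs)])
  mouse <- data.frame(mouse_id = id, group = group, outcome = outcome,
                      outcome_time_h = outcome_time)
  list(mouse = mouse, assessments = assessments)
}

#' @export
print.mss_experiment <- function(x, ...) {
  cat("MSS simulated experiment\n")
  tab <- table(x$mice$group, x$mice$outcome)
  print(tab)
  cat(nrow(x$assessments), "assessment rows;",
      length(unique(x$markers$marker)), "markers\n")
  invisible(x)
}

#' Write an experiment to CSV files
#'
#' Writes the long-format assessments table, the per-mouse outcomes table
#' and the marker panel as plain CSVs with the canonical column layout read
#' back by [read_assessments()], [read_outcomes()] and [read_markers()].
#'
#' @param experiment An `mss_experiment`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(assessments = file.path(dir, "assessments.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             markers = file.path(dir, "markers.csv"))
  utils::write.csv(experiment$assessments, paths[["assessments"]],
                   row.names = FALSE)
  utils::write.csv(experiment$mice, paths[["outcomes"]], row.names = FALSE)
  utils::write.csv(experiment$markers, paths[["markers"]], row.names = FALSE)
  invisible(paths)
}
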