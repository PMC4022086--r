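# Simulator configuration: the generative parameters of a synthetic
# fecal-induced-peritonitis (FIP) experiment.

#' Default calibrated simulator configuration
#'
#' Returns the shipped parameter set for [simulate_experiment()]. The group
#' sizes and 24-h survival structure follow the reference experimental
#' design: sham controls (saline, n = 60, 100% survival), and fecal-solution
#' doses of 45 mg/mL (n = 20, ~40% survival), 90 mg/mL (n = 200, ~25%
#' survival) and 180 mg/mL (n = 20, 0% survival). The remaining parameters
#' were calibrated once, against the published validation summaries of the
#' score (internal consistency ~0.92, inter-rater ICC ~0.96, AUC ~0.825,
#' sensitivity ~57% / specificity ~100% at a cutoff of 3, and the
#' score-10/score-15 mortality windows), and are not meant to be tuned per
#' run.
#'
#' Model structure (see the package vignette for details):
#' * Each mouse carries a latent severity S(t): sham mice are stationary
#'   around `sham_latent_mean`; septic mice sit at a per-mouse baseline
#'   until a deterioration onset drawn around `onset_mean_h`, then rise
#'   linearly at a per-mouse log-normal rate whose mean is dose-scaled.
#' * Item scores are threshold crossings: item j scores the number of its
#'   four increasing cutpoints lying below S(t) plus item-level biological
#'   noise (shared by both raters) plus rater-level observation noise.
#' * Death is a discrete-time hazard between scheduled checks,
#'   `1 - exp(-h dt)`, driven by the true (noise-free) severity expressed
#'   on the score scale: zero below `hazard_score_floor`, then
#'   `hazard_baseline * exp(hazard_score_coef * (score - floor))`
#'   saturating at `hazard_cap`, times a per-mouse log-normal frailty
#'   (`frailty_cv`). The humane-endpoint rule ([euthanasia_required()]) is
#'   applied at each check using the non-blinded rater's recorded scores.
#'
#' @param seed Integer seed stored in the configuration; all randomness in
#'   [simulate_experiment()] derives from it.
#' @return An object of class `mss_config` (a named list).
#' @export
#' @examples
#' cfg <- default_config(seed = 1)
#' cfg$n_per_group
default_config <- function(seed = 1L) {
  items <- mss_items()
  # Four increasing cutpoints per item on the latent scale. First-level
  # cutpoints are staggered so mild disease shows as piloerection and
  # reduced activity first, respiratory signs last; upper levels are spaced
  # 0.85 latent units apart.
  first <- c(appearance = 0.35, consciousness = 0.95, activity = 0.58,
             response_to_stimulus = 1.15, eyes = 1.35,
             respiration_rate = 1.55, respiration_quality = 1.75)
  thresholds <- t(vapply(items, function(j) first[[j]] + 0.85 * 0:3,
                         numeric(4)))
  dimnames(thresholds) <- list(items, paste0("cut", 1:4))

  structure(list(
    n_per_group = c(sham = 60L, fs45 = 20L, fs90 = 200L, fs180 = 20L),
    horizon_h = 24,
    # deterioration onset (h post induction), shared across septic doses
    onset_mean_h = 13,
    onset_sd_h = 2,
    # per-mouse latent progression rate (latent units / h), log-normal;
    # mean is dose-scaled, coefficient of variation shared
    progression_rate_mean = c(fs45 = 0.23, fs90 = 0.35, fs180 = 1.50),
    progression_rate_cv = 1.5,
    latent_noise_sd = 0.06,
    item_thresholds = thresholds,
    item_noise_sd = 0.74,
    rater_noise_sd = 0.63,
    # observation noise ramps with severity: noise_floor of the full sd
    # while latent severity is below noise_ramp_start (scoring a well mouse
    # is nearly unambiguous), rising linearly to the full sd at
    # noise_ramp_latent (moribund items are contentious)
    noise_floor = 0.15,
    noise_ramp_start = 0.85,
    noise_ramp_latent = 1.9,
    # death hazard acts in the moribund score range only, rising
    # exponentially from the floor score and saturating at hazard_cap
    hazard_baseline = 0.09,
    # per-mouse log-normal frailty multiplier on the hazard
    frailty_cv = 0.4,
    hazard_score_coef = 0.60,
    hazard_score_floor = 6,
    hazard_cap = 0.95,
    sham_latent_mean = 0.50,
    sham_latent_sd = 0.15,
    septic_baseline_mean = 0.78,
    septic_baseline_sd = 0.40,
    # group-mean marker (cytokine-like) profiles at the panel timepoints
    # (pooled sham baseline, then 3, 12, 24 h post induction), pg/mL-scale.
    # Monotone profiles emulate mediators that track severity (IL-6-like);
    # early-peak profiles emulate mediators that spike and resolve
    # (TNF-alpha-like).
    marker_profiles = list(
      IL6     = c(sham = 12, h3 = 850, h12 = 4200, h24 = 11000),
      eotaxin = c(sham = 420, h3 = 710, h12 = 1350, h24 = 2100),
      GCSF    = c(sham = 95, h3 = 2400, h12 = 9800, h24 = 21000),
      MCSF    = c(sham = 6, h3 = 14, h12 = 33, h24 = 61),
      MIG     = c(sham = 110, h3 = 340, h12 = 980, h24 = 2500),
      RANTES  = c(sham = 28, h3 = 41, h12 = 76, h24 = 130),
      TNFa    = c(sham = 9, h3 = 1650, h12 = 480, h24 = 210),
      IL1b    = c(sham = 22, h3 = 540, h12 = 260, h24 = 140)
    ),
    raters = c(nonblinded = "R1", blinded = "R2"),
    seed = as.integer(seed)
  ), class = "mss_config")
}

#' Validate a simulator configuration
#'
#' Checks structural invariants: positive horizon, non-negative noise
#' standard deviations, strictly increasing item cutpoints, group counts,
#' and marker profiles covering all four panel timepoints.
#'
#' @param config An `mss_config` list as returned by [default_config()].
#' @return The configuration, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  req <- c("n_per_group", "horizon_h", "onset_mean_h", "onset_sd_h",
           "progression_rate_mean", "progression_rate_cv", "latent_noise_sd",
           "item_thresholds", "item_noise_sd", "rater_noise_sd",
           "noise_floor", "noise_ramp_start", "noise_ramp_latent",
           "hazard_baseline", "hazard_score_coef", "hazard_score_floor",
           "hazard_cap", "frailty_cv",
           "sham_latent_mean",
           "sham_latent_sd", "septic_baseline_mean", "septic_baseline_sd",
           "marker_profiles", "raters", "seed")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0L) {
    stop("config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (config$horizon_h <= 0) stop("horizon_h must be > 0", call. = FALSE)
  sds <- c("onset_sd_h", "latent_noise_sd", "item_noise_sd",
           "rater_noise_sd", "sham_latent_sd", "septic_baseline_sd")
  for (s in sds) {
    if (config[[s]] < 0) stop(s, " must be >= 0", call. = FALSE)
  }
  th <- config$item_thresholds
  if (!is.matrix(th) || nrow(th) != 7L || ncol(th) != 4L ||
      !identical(rownames(th), mss_items())) {
    stop("item_thresholds must be a 7 x 4 matrix with rows named by mss_items()",
         call. = FALSE)
  }
  if (any(apply(th, 1L, function(x) any(diff(x) <= 0)))) {
    stop("item_thresholds must be strictly increasing within each item",
         call. = FALSE)
  }
  groups <- names(config$n_per_group)
  if (!all(groups %in% c("sham", "fs45", "fs90", "fs180"))) {
    stop("n_per_group names must be among sham, fs45, fs90, fs180",
         call. = FALSE)
  }
  if (any(config$n_per_group < 0)) stop("group sizes must be >= 0", call. = FALSE)
  septic <- setdiff(groups, "sham")
  miss_rate <- setdiff(septic, names(config$progression_rate_mean))
  if (length(miss_rate) > 0L) {
    stop("progression_rate_mean missing for group(s): ",
         paste(miss_rate, collapse = ", "), call. = FALSE)
  }
  if (any(config$progression_rate_mean <= 0) || config$progression_rate_cv < 0) {
    stop("progression rates must be positive, cv >= 0", call. = FALSE)
  }
  if (config$hazard_baseline < 0) stop("hazard_baseline must be >= 0", call. = FALSE)
  for (m in names(config$marker_profiles)) {
    prof <- config$marker_profiles[[m]]
    if (!all(c("sham", "h3", "h12", "h24") %in% names(prof))) {
      stop("marker profile '", m,
           "' must have values named sham, h3, h12, h24", call. = FALSE)
    }
  }
  invisible(config)
}

#' Read / write a simulator configuration
#'
#' Configurations serialize to a flat JSON file whose keys match the fields
#' of [default_config()].
#'
#' @param config An `mss_config` object.
#' @param path File path.
#' @return `read_config()` returns an `mss_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$item_thresholds <- as.data.frame(out$item_thresholds)
  # named atomic vectors must become JSON objects, not bare arrays
  out$n_per_group <- as.list(out$n_per_group)
  out$progression_rate_mean <- as.list(out$progression_rate_mean)
  out$raters <- as.list(out$raters)
  out$marker_profiles <- lapply(out$marker_profiles, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- as.matrix(raw$item_thresholds)
  rownames(th) <- mss_items()
  colnames(th) <- paste0("cut", 1:4)
  raw$item_thresholds <- th
  raw$n_per_group <- vapply(raw$n_per_group, as.integer, integer(1))
  raw$progression_rate_mean <- unlist(raw$progression_rate_mean)
  raw$marker_profiles <- lapply(raw$marker_profiles, unlist)
  raw$raters <- unlist(raw$raters)
  raw$seed <- as.integer(raw$seed)
  cfg <- structure(raw, class = "mss_config")
  validate_config(cfg)
  cfg
}

#' @export
print.mss_config <- function(x, ...) {
  cat("MSS cohort simulator configuration\n")
  cat("  groups: ",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
            collapse = ", "), "\n", sep = "")
  cat("  horizon:", x$horizon_h, "h; onset ~ N(", x$onset_mean_h, ",",
      x$onset_sd_h, ") h\n")
  cat("  noise sd (latent/item/rater):", x$latent_noise_sd, "/",
      x$item_noise_sd, "/", x$rater_noise_sd, "\n")
  cat("  hazard: ", format(x$hazard_baseline), " * exp(",
      x$hazard_score_coef, " * MSS) per h\n", sep = "")
  cat("  markers:", paste(names(x$marker_profiles), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
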