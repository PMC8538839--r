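#' Default exposure calibration
#'
#' Marginal and correlation targets for the synthetic prenatal / age-1 / age-3
#' exposure draws. Margins are truncated normal; `mean`, `sd` and `range` are
#' the targets for the truncated distribution (units ug/m3/day), `iqr_ref` the
#' interquartile range used to express planted score effects per IQR of
#' exposure. Correlations are Pearson targets on the realized exposures:
#' `r_birth_age1`, `r_birth_age3` within pollutant, `r_age1_age3` a generator
#' choice, and `cross_same_anchor` / `cross_other_anchor` between pollutants.
#'
#' @return nested list of per-pollutant calibration targets.
#' @export
default_exposure_calibration <- function() {
  list(
    pm25 = list(mean = 27.9, sd = 7.04, range = c(14.3, 45.0), iqr_ref = 10.73,
                r_birth_age1 = 0.54, r_birth_age3 = 0.57, r_age1_age3 = 0.65),
    pm10 = list(mean = 15.0, sd = 3.06, range = c(7.5, 20.2), iqr_ref = 3.20,
                r_birth_age1 = 0.71, r_birth_age3 = 0.69, r_age1_age3 = 0.75),
    cross_same_anchor = 0.20,
    cross_other_anchor = 0.12
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the generator: cohort size and visit structure,
#' exposure calibration targets, planted exposure-to-score effects (in SD of
#' standardized score per `iqr_ref` of exposure), visit-to-visit correlation of
#' score-CpG betas, planted QC fault counts, and the RNG seed. The defaults
#' are the study conditions the package emulates; see the methods vignette.
#'
#' @param n_participants number of participants.
#' @param visits named list of visit definitions (`label`, `age_mean`,
#'   `age_sd`); default age-9 and age-15 visits.
#' @param exposure_calibration see [default_exposure_calibration()].
#' @param planted_effects named numeric: true slope of the standardized
#'   z-scored cumulative score per `iqr_ref` increase in prenatal exposure.
#' @param score_site_longitudinal_r named numeric: visit-to-visit correlation
#'   of score-CpG betas (and hence of the scores) per pollutant.
#' @param qc_fault_counts named integer vector `detection`, `sex_discordant`,
#'   `abnormal`: planted counts of QC-failing samples.
#' @param n_single_visit participants contributing the second visit only.
#' @param n_deconv_sites reference CpGs for cell deconvolution.
#' @param n_background_sites background (non-score, non-reference) CpGs.
#' @param signal_fraction fraction of each score-CpG's sd aligned with the
#'   latent score signal (the rest is site noise).
#' @param bg_longitudinal_r within-person visit-to-visit correlation of
#'   background CpG betas.
#' @param immune_mean,immune_sd per-visit mean/sd of the immune cell fraction.
#' @param generate_betas generate beta/detection matrices (disable for
#'   exposure-only cohorts at large n).
#' @param generate_monitors generate a monitor network plus daily series that
#'   reproduce the assigned exposures through inverse-distance weighting.
#' @param seed integer RNG seed; identical config + seed gives a
#'   byte-identical cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 800,
                          visits = list(
                            list(label = "9",  age_mean = 9.30, age_sd = 0.34),
                            list(label = "15", age_mean = 15.4, age_sd = 0.49)),
                          exposure_calibration = default_exposure_calibration(),
                          planted_effects = c(pm25 = -0.029, pm10 = -0.024, no2 = 0),
                          score_site_longitudinal_r = c(pm25 = 0.55, pm10 = 0.22,
                                                        no2 = 0.45),
                          qc_fault_counts = c(detection = 0L, sex_discordant = 0L,
                                              abnormal = 0L),
                          n_single_visit = 0L,
                          n_deconv_sites = 200L,
                          n_background_sites = 400L,
                          signal_fraction = 0.3,
                          bg_longitudinal_r = 0.4,
                          immune_mean = c(0.953, 0.925),
                          immune_sd = c(0.118, 0.149),
                          generate_betas = TRUE,
                          generate_monitors = FALSE,
                          seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants), visits = visits,
              exposure_calibration = exposure_calibration,
              planted_effects = planted_effects,
              score_site_longitudinal_r = score_site_longitudinal_r,
              qc_fault_counts = qc_fault_counts,
              n_single_visit = as.integer(n_single_visit),
              n_deconv_sites = as.integer(n_deconv_sites),
              n_background_sites = as.integer(n_background_sites),
              signal_fraction = signal_fraction,
              bg_longitudinal_r = bg_longitudinal_r,
              immune_mean = immune_mean, immune_sd = immune_sd,
              generate_betas = isTRUE(generate_betas),
              generate_monitors = isTRUE(generate_monitors),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) stop_ms("n_participants must be >= 1")
  if (length(cfg$visits) < 1) stop_ms("at least one visit required")
  for (v in cfg$visits) {
    if (v$age_sd <= 0) stop_ms("visit age_sd must be > 0")
  }
  cal <- cfg$exposure_calibration
  for (p in c("pm25", "pm10")) {
    m <- cal[[p]]
    if (m$sd <= 0) stop_ms("%s calibration sd must be > 0", p)
    if (m$range[1] >= m$range[2]) stop_ms("%s range invalid", p)
    rr <- c(m$r_birth_age1, m$r_birth_age3, m$r_age1_age3)
    if (any(abs(rr) > 1)) stop_ms("%s correlations must be in [-1, 1]", p)
  }
  if (any(abs(c(cal$cross_same_anchor, cal$cross_other_anchor)) > 1))
    stop_ms("cross-pollutant correlations must be in [-1, 1]")
  if (any(abs(cfg$score_site_longitudinal_r) > 1))
    stop_ms("score_site_longitudinal_r must be in [-1, 1]")
  n_obs <- cfg$n_participants * length(cfg$visits) -
    cfg$n_single_visit * (length(cfg$visits) - 1L)
  if (any(cfg$qc_fault_counts < 0) || sum(cfg$qc_fault_counts) > n_obs)
    stop_ms("qc_fault_counts infeasible for %d observations", n_obs)
  if (cfg$signal_fraction <= 0 || cfg$signal_fraction >= 1)
    stop_ms("signal_fraction must be in (0, 1)")
  if (cfg$n_single_visit < 0 || cfg$n_single_visit > cfg$n_participants)
    stop_ms("n_single_visit out of range")
  invisible(cfg)
}

#' Read or write a cohort configuration as YAML
#'
#' @param file path to a YAML file.
#' @param cfg a `cohort_config` object.
#' @return `read_cohort_config()` returns a `cohort_config`.
#' @export
read_cohort_config <- function(file) {
  raw <- yaml::read_yaml(file)
  base <- cohort_config()
  for (nm in names(raw)) {
    if (!nm %in% names(base)) stop_ms("unknown config field '%s'", nm)
    if (nm %in% c("planted_effects", "score_site_longitudinal_r",
                  "qc_fault_counts", "immune_mean", "immune_sd")) {
      base[[nm]] <- unlist(raw[[nm]])
    } else if (nm == "exposure_calibration") {
      for (p in names(raw[[nm]])) {
        if (is.list(raw[[nm]][[p]])) {
          for (f in names(raw[[nm]][[p]]))
            base[[nm]][[p]][[f]] <- unlist(raw[[nm]][[p]][[f]])
        } else base[[nm]][[p]] <- raw[[nm]][[p]]
      }
    } else base[[nm]] <- raw[[nm]]
  }
  do.call(cohort_config, unclass(base))
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "cohort_config"))
  out <- unclass(cfg)
  out$planted_effects <- as.list(out$planted_effects)
  out$score_site_longitudinal_r <- as.list(out$score_site_longitudinal_r)
  out$qc_fault_counts <- as.list(out$qc_fault_counts)
  yaml::write_yaml(out, file)
  invisible(file)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d (%d single-visit), visits: %s\n",
              x$n_participants, x$n_single_visit,
              paste(vapply(x$visits, `[[`, "", "label"), collapse = ", ")))
  cat(sprintf("  planted effects (SD/IQR): %s\n",
              paste(sprintf("%s=%g", names(x$planted_effects),
                            x$planted_effects), collapse = ", ")))
  cat(sprintf("  QC faults planted: detection=%d sex=%d abnormal=%d\n",
              x$qc_fault_counts[["detection"]],
              x$qc_fault_counts[["sex_discordant"]],
              x$qc_fault_counts[["abnormal"]]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
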