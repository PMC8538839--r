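# Assemble the per-observation analysis table from a cohort: QC-filtered
# pooled betas, cumulative scores, cell proportions, exposures and covariates.

default_adjustment <- function() {
  c("sex", "age", "race", "income_needs", "marital", "immune")
}

#' Build the analysis table for association models
#'
#' Runs the QC filters per visit, pools the surviving betas over the
#' standardization population, computes the cumulative scores for every
#' pollutant and variant, estimates cell proportions from the reference
#' panel, and merges exposures and covariates into one observation-level
#' table.
#'
#' @param cohort a `synthetic_cohort` with beta bundles.
#' @param exposures optional exposure table (`participant_id`, `pollutant`,
#'   `anchor`, `value`), e.g. from [compute_exposures()]; defaults to the
#'   cohort's assigned exposures.
#' @param qc apply [filter_samples()] and [filter_probes()] first (default
#'   TRUE).
#' @param blocklist passed to [filter_probes()].
#' @param variants score variants to compute.
#' @param use_estimated_cells estimate cell proportions from the betas via
#'   [estimate_cell_proportions()]; if FALSE, use the generator's true
#'   proportions.
#' @return list with `data` (one row per observation: ids, visit, age,
#'   covariates, `immune`/`epithelial`, `exp_<pollutant>_<anchor>` columns,
#'   `score_<pollutant>_<variant>` columns, and `cpg_<id>` percent-methylation
#'   columns for the PM10 score sites), `sample_log`, `probe_log`, and
#'   `flow` (observation counts entering/leaving QC).
#' @export
build_analysis_table <- function(cohort, exposures = NULL, qc = TRUE,
                                 blocklist = character(0),
                                 variants = c("zscored", "raw", "centered"),
                                 use_estimated_cells = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$bundles)) stop_ms("cohort has no beta bundles")
  if (is.null(exposures)) exposures <- cohort$exposures

  sample_log <- probe_log <- NULL
  bundles <- cohort$bundles
  n_in <- sum(vapply(bundles, function(b) ncol(b$beta), 1L))
  if (qc) {
    bundles <- lapply(bundles, function(b) {
      fs <- filter_samples(b)
      fp <- filter_probes(fs$bundle, blocklist = blocklist)
      sample_log <<- rbind(sample_log, fs$log)
      probe_log <<- rbind(probe_log, fp$log)
      fp$bundle
    })
  }
  common <- Reduce(intersect, lapply(bundles, function(b) rownames(b$beta)))
  beta <- do.call(cbind, lapply(bundles, function(b) b$beta[common, , drop = FALSE]))
  detp <- do.call(cbind, lapply(bundles, function(b) b$detp[common, , drop = FALSE]))
  samples <- do.call(rbind, c(lapply(bundles, `[[`, "samples"),
                              make.row.names = FALSE))
  pooled <- new_beta_bundle(beta, detp, samples, "pooled")

  ## scores
  tab <- samples[, c("sample_id", "participant_id", "visit", "age")]
  for (p in c("pm25", "pm10", "no2")) {
    wt <- weight_table(p)
    for (v in variants) {
      sc <- cumulative_score(beta, wt, v)
      tab[[sprintf("score_%s_%s", p, v)]] <- sc$score[match(tab$sample_id,
                                                            sc$sample_id)]
    }
  }

  ## cell proportions
  cp <- if (use_estimated_cells && !is.null(cohort$reference))
    estimate_cell_proportions(pooled, cohort$reference)
  else cohort$truth$cell_props
  tab$immune <- cp$immune[match(tab$sample_id, cp$sample_id)]
  tab$epithelial <- cp$epithelial[match(tab$sample_id, cp$sample_id)]

  ## exposures, wide
  for (p in unique(exposures$pollutant)) for (a in unique(exposures$anchor)) {
    e <- exposures[exposures$pollutant == p & exposures$anchor == a, ]
    tab[[sprintf("exp_%s_%s", p, a)]] <- e$value[match(tab$participant_id,
                                                       e$participant_id)]
  }

  ## single-CpG percent outcomes for the PM10 score sites
  for (cg in weight_table("pm10")$cpg_id) {
    if (cg %in% rownames(beta))
      tab[[paste0("cpg_", cg)]] <- 100 * beta[cg, match(tab$sample_id,
                                                        colnames(beta))]
  }

  ## covariates
  cv <- cohort$covariates
  idx <- match(tab$participant_id, cv$participant_id)
  for (col in setdiff(names(cv), "participant_id")) tab[[col]] <- cv[[col]][idx]
  # reference levels: largest race category, married
  tab$race <- stats::relevel(factor(tab$race),
                             ref = names(sort(table(tab$race),
                                              decreasing = TRUE))[1])
  tab$marital <- stats::relevel(factor(tab$marital, levels = c("married",
                                                               "not married")),
                                ref = "married")
  tab$sex <- factor(tab$sex)

  flow <- data.frame(stage = c("input", "post_sample_qc"),
                     n_obs = c(n_in, nrow(tab)))
  list(data = tab, sample_log = sample_log, probe_log = probe_log,
       flow = flow, n_cpgs = length(common))
}
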