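# Association models: per-visit OLS, random-intercept mixed models,
# median-split bivariate tests, and the sensitivity suite. Effects are
# reported per interquartile-range increase in exposure.

#' Median-split bivariate tests
#'
#' Dichotomizes `split_on` at its median (ties to the lower stratum) and
#' tests each covariate for a difference between strata: Welch t-tests for
#' continuous covariates, Fisher's exact test for categorical ones.
#'
#' @param data analysis table (see [build_analysis_table()]).
#' @param split_on column name to dichotomize (an exposure or score column).
#' @param covariates columns to test.
#' @return data.frame `covariate`, `type`, `p_value`, `reason` (`NA` unless
#'   the test was degenerate).
#' @export
bivariate_tests <- function(data, split_on,
                            covariates = c("sex", "age", "race",
                                           "income_needs", "marital",
                                           "immune")) {
  x <- data[[split_on]]
  if (is.null(x)) stop_ms("column %s not found", split_on)
  ok <- !is.na(x)
  g <- factor(ifelse(x[ok] <= median(x[ok]), "low", "high"),
              levels = c("low", "high"))
  if (min(table(g)) < 2) stop_ms("fewer than 2 observations in a stratum")
  rows <- lapply(covariates, function(cv) {
    v <- data[[cv]][ok]
    if (is.numeric(v)) {
      p <- tryCatch(t.test(v ~ g)$p.value, error = function(e) NA_real_)
      reason <- if (is.na(p)) "degenerate stratum" else NA_character_
      data.frame(covariate = cv, type = "continuous", p_value = p,
                 reason = reason, stringsAsFactors = FALSE)
    } else {
      tb <- table(factor(v), g)
      tb <- tb[rowSums(tb) > 0, , drop = FALSE]
      p <- if (nrow(tb) < 2) 1 else
        tryCatch(fisher.test(tb)$p.value,
                 error = function(e) fisher.test(tb, simulate.p.value = TRUE,
                                                 B = 1e4)$p.value)
      data.frame(covariate = cv, type = "categorical", p_value = p,
                 reason = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

# Core fitter shared by the visit and mixed models.
fit_assoc <- function(data, outcome, exposure, covariates, mixed, iqr,
                      conf_level, stratum_label, pollutant, variant) {
  need <- c(outcome, exposure, covariates, "participant_id")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop_ms("missing columns: %s", paste(miss, collapse = ", "))
  cc <- data[complete.cases(data[, need]), , drop = FALSE]
  if (nrow(cc) < length(covariates) + 3) stop_ms("too few complete cases (%d)",
                                                 nrow(cc))
  if (var(cc[[exposure]]) == 0) stop_ms("exposure %s has zero variance", exposure)
  iqr_used <- if (is.null(iqr)) unname(diff(quantile(cc[[exposure]],
                                                     c(0.25, 0.75)))) else iqr
  cc$.exp_iqr <- cc[[exposure]] / iqr_used
  rhs <- paste(c(".exp_iqr", covariates), collapse = " + ")
  fml <- as.formula(paste(outcome, "~", rhs))
  alpha <- 1 - conf_level

  n_indiv <- length(unique(cc$participant_id))
  model_type <- "lm"
  if (mixed && any(duplicated(cc$participant_id))) {
    fit <- tryCatch(
      nlme::lme(fml, random = ~ 1 | participant_id, data = cc,
                method = "REML"),
      error = function(e) stop_ms("mixed model did not converge: %s (see nlme::lmeControl to adjust iterations)", conditionMessage(e)))
    tt <- summary(fit)$tTable
    est <- tt[".exp_iqr", "Value"]
    se <- tt[".exp_iqr", "Std.Error"]
    p <- 2 * pnorm(-abs(est / se))
    ci <- est + c(-1, 1) * qnorm(1 - alpha / 2) * se
    vc <- as.numeric(nlme::VarCorr(fit)[, "StdDev"])
    varcomp <- c(sd_intercept = vc[1], sd_residual = vc[2])
    model_type <- "lme"
  } else {
    fit <- lm(fml, data = cc)
    X <- model.matrix(fit)
    if (fit$rank < ncol(X)) {
      aliased <- names(which(is.na(coef(fit))))
      stop_ms("model is rank deficient; aliased terms: %s",
              paste(aliased, collapse = ", "))
    }
    sm <- summary(fit)
    est <- coef(fit)[".exp_iqr"]
    se <- sm$coefficients[".exp_iqr", "Std. Error"]
    p <- sm$coefficients[".exp_iqr", "Pr(>|t|)"]
    ci <- as.numeric(confint(fit, ".exp_iqr", level = conf_level))
    varcomp <- c(sd_intercept = NA_real_, sd_residual = sm$sigma)
    if (mixed) model_type <- "lm_degenerate_mixed"
  }
  structure(list(effect = unname(est), ci_low = ci[1], ci_high = ci[2],
                 p_value = unname(p), n_indiv = n_indiv, n_obs = nrow(cc),
                 iqr_used = iqr_used, outcome = outcome, exposure = exposure,
                 pollutant = pollutant, stratum = stratum_label,
                 variant = variant, model_type = model_type,
                 varcomp = varcomp, conf_level = conf_level, fit = fit),
            class = "mrs_assoc")
}

#' Per-visit linear association model
#'
#' OLS of the standardized cumulative score on exposure plus the adjustment
#' set within one visit; the exposure coefficient is reported per
#' interquartile-range increase, with a t-based confidence interval.
#'
#' @param data analysis table (see [build_analysis_table()]).
#' @param pollutant `"pm25"` or `"pm10"`.
#' @param visit visit label (e.g. `"9"` or `"15"`).
#' @param variant score variant column to use.
#' @param covariates adjustment set (default: child sex, age at measure,
#'   race/ethnicity, income-to-needs, marital status, immune proportion).
#' @param iqr fixed IQR (ug/m3/day) for effect scaling; `NULL` (default)
#'   uses the analytic subsample's exposure IQR.
#' @param anchor exposure anchor (default `"birth"`).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `mrs_assoc`.
#' @export
fit_visit_model <- function(data, pollutant, visit, variant = "zscored",
                            covariates = default_adjustment(), iqr = NULL,
                            anchor = "birth", conf_level = 0.95) {
  d <- data[data$visit == visit, , drop = FALSE]
  if (nrow(d) == 0) stop_ms("no observations for visit %s", visit)
  fit_assoc(d, sprintf("score_%s_%s", pollutant, variant),
            sprintf("exp_%s_%s", pollutant, anchor), covariates,
            mixed = FALSE, iqr = iqr, conf_level = conf_level,
            stratum_label = visit, pollutant = pollutant, variant = variant)
}

#' Random-intercept mixed association model over all visits
#'
#' Linear mixed model (REML) of the standardized cumulative score on exposure
#' plus the adjustment set, with a per-participant random intercept capturing
#' repeated measures; participants with a single observation are included.
#' The exposure fixed effect is reported per interquartile-range increase
#' with a Wald z interval. When no participant has repeated measures the
#' random intercept is unidentifiable and the model reduces to OLS (flagged
#' `lm_degenerate_mixed`).
#'
#' @inheritParams fit_visit_model
#' @return an object of class `mrs_assoc`.
#' @export
fit_mixed_model <- function(data, pollutant, variant = "zscored",
                            covariates = default_adjustment(), iqr = NULL,
                            anchor = "birth", conf_level = 0.95) {
  fit_assoc(data, sprintf("score_%s_%s", pollutant, variant),
            sprintf("exp_%s_%s", pollutant, anchor), covariates,
            mixed = TRUE, iqr = iqr, conf_level = conf_level,
            stratum_label = "All", pollutant = pollutant, variant = variant)
}

#' Sensitivity analyses
#'
#' Re-fits the primary models with (a) mutual adjustment for the other
#' pollutant (`"copollutant"`), (b) adjustment for postnatal exposure at age
#' one (`"age1"`), (c) at age three (`"age3"`), (d) the NO2 score as outcome
#' for a specificity check (`"no2"`), and (e) per-CpG percent-methylation
#' outcomes at the six published PM10 sites, age-15 stratum (`"cpg"`).
#' Analyses whose required columns are missing are skipped with a log entry.
#'
#' @inheritParams fit_visit_model
#' @param analyses subset of
#'   `c("copollutant", "age1", "age3", "no2", "cpg")`.
#' @param stratum `"All"` (mixed model) or a visit label (OLS).
#' @return list with `results` (named list of `mrs_assoc`) and `log`
#'   (character notes for skipped analyses).
#' @export
sensitivity_suite <- function(data, pollutant,
                              analyses = c("copollutant", "age1", "age3",
                                           "no2", "cpg"),
                              stratum = "All", variant = "zscored",
                              covariates = default_adjustment(), iqr = NULL,
                              conf_level = 0.95) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  other <- if (pollutant == "pm10") "pm25" else "pm10"
  results <- list(); log <- character(0)
  refit <- function(extra_cov = character(0), outcome_variant = variant,
                    outcome_pollutant = pollutant, outcome_col = NULL) {
    covs <- c(covariates, extra_cov)
    outc <- if (is.null(outcome_col))
      sprintf("score_%s_%s", outcome_pollutant, outcome_variant) else outcome_col
    if (stratum == "All")
      fit_assoc(data, outc, sprintf("exp_%s_birth", pollutant), covs,
                mixed = TRUE, iqr = iqr, conf_level = conf_level,
                stratum_label = "All", pollutant = pollutant, variant = variant)
    else
      fit_assoc(data[data$visit == stratum, , drop = FALSE], outc,
                sprintf("exp_%s_birth", pollutant), covs, mixed = FALSE,
                iqr = iqr, conf_level = conf_level, stratum_label = stratum,
                pollutant = pollutant, variant = variant)
  }
  try_add <- function(name, need_cols, expr) {
    miss <- setdiff(need_cols, names(data))
    if (length(miss) > 0) {
      log <<- c(log, sprintf("%s skipped: missing %s", name,
                             paste(miss, collapse = ", ")))
    } else results[[name]] <<- expr()
  }
  if ("copollutant" %in% analyses)
    try_add("copollutant", sprintf("exp_%s_birth", other),
            function() refit(extra_cov = sprintf("exp_%s_birth", other)))
  if ("age1" %in% analyses)
    try_add("age1", sprintf("exp_%s_age1", pollutant),
            function() refit(extra_cov = sprintf("exp_%s_age1", pollutant)))
  if ("age3" %in% analyses)
    try_add("age3", sprintf("exp_%s_age3", pollutant),
            function() refit(extra_cov = sprintf("exp_%s_age3", pollutant)))
  if ("no2" %in% analyses)
    try_add("no2", sprintf("score_no2_%s", variant),
            function() refit(outcome_pollutant = "no2"))
  if ("cpg" %in% analyses) {
    for (cg in weight_table("pm10")$cpg_id) {
      col <- paste0("cpg_", cg)
      local({
        cgl <- cg; coll <- col
        try_add(paste0("cpg_", cgl), coll, function() {
          d15 <- data[data$visit == "15", , drop = FALSE]
          fit_assoc(d15, coll, sprintf("exp_%s_birth", pollutant), covariates,
                    mixed = FALSE, iqr = iqr, conf_level = conf_level,
                    stratum_label = "15", pollutant = pollutant,
                    variant = "percent")
        })
      })
    }
  }
  list(results = results, log = log)
}

#' @export
print.mrs_assoc <- function(x, ...) {
  cat(sprintf("Cumulative methylation score association (%s)\n", x$model_type))
  cat(sprintf("  outcome %s ~ %s, stratum %s\n", x$outcome, x$exposure,
              x$stratum))
  cat(sprintf("  effect per IQR (%.2f ug/m3/day): %.4f  [%.4f, %.4f]  p = %.3g\n",
              x$iqr_used, x$effect, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  n_indiv = %d, n_obs = %d\n", x$n_indiv, x$n_obs))
  invisible(x)
}

#' @export
summary.mrs_assoc <- function(object, ...) {
  print(object)
  cat("\nUnderlying fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.mrs_assoc <- function(object, ...) {
  c(effect_per_iqr = object$effect)
}

#' @export
confint.mrs_assoc <- function(object, parm, level, ...) {
  probs <- c((1 - object$conf_level) / 2, 1 - (1 - object$conf_level) / 2)
  matrix(c(object$ci_low, object$ci_high), 1,
         dimnames = list("effect_per_iqr", sprintf("%g %%", 100 * probs)))
}

#' Tabulate association results
#'
#' Collapses a list of `mrs_assoc` objects into a results table shaped like
#' the study's main report: one row per exposure/stratum with effect, CI,
#' p-value and sample sizes.
#'
#' @param models list of `mrs_assoc` objects.
#' @return data.frame.
#' @export
assoc_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(exposure = m$pollutant, stratum = m$stratum,
               variant = m$variant, outcome = m$outcome,
               n_indiv = m$n_indiv, n_obs = m$n_obs,
               effect = m$effect, ci_low = m$ci_low, ci_high = m$ci_high,
               p_value = m$p_value, iqr_used = m$iqr_used,
               model = m$model_type, stringsAsFactors = FALSE)
  }))
}
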