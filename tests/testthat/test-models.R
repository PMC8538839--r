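test_that("effects are scaled exactly by the exposure IQR", {
  d <- make_model_data(n = 400, slope_per_unit = 0.01, seed = 41, sigma = 0.01)
  m_unit <- fit_visit_model(d, "pm10", "15", covariates = c("age", "sex"),
                            iqr = 1)
  m_iqr <- fit_visit_model(d, "pm10", "15", covariates = c("age", "sex"),
                           iqr = 3.20)
  expect_equal(m_iqr$effect, m_unit$effect * 3.20, tolerance = 1e-10)
  expect_equal(m_iqr$effect, 0.01 * 3.20, tolerance = 0.05)
  # subsample IQR is used when no fixed IQR is supplied
  m_sub <- fit_visit_model(d, "pm10", "15", covariates = c("age", "sex"))
  d15 <- d[d$visit == "15", ]
  expect_equal(m_sub$iqr_used,
               unname(diff(quantile(d15$exp_pm10_birth, c(0.25, 0.75)))))
  expect_lte(m_sub$ci_low, m_sub$effect)
  expect_gte(m_sub$ci_high, m_sub$effect)
})

test_that("rank-deficient adjustment sets raise an aliased-term error", {
  d <- make_model_data(n = 100, seed = 42)
  d$exp_copy <- 2 * d$exp_pm10_birth   # perfectly collinear with exposure
  expect_error(fit_visit_model(d, "pm10", "15",
                               covariates = c("age", "exp_copy")),
               "aliased")
})

test_that("the mixed model matches OLS when every participant has one visit", {
  d <- make_model_data(n = 250, slope_per_unit = 0.02, seed = 43,
                       visits = "15")
  ols <- fit_visit_model(d, "pm10", "15", covariates = c("age", "sex"),
                         iqr = 3.2)
  mix <- fit_mixed_model(d, "pm10", covariates = c("age", "sex"), iqr = 3.2)
  expect_identical(mix$model_type, "lm_degenerate_mixed")
  expect_equal(mix$effect, ols$effect, tolerance = 1e-6)
  expect_equal(mix$p_value, ols$p_value, tolerance = 1e-6)
})

test_that("the random-intercept model recovers planted variance components", {
  set.seed(44)
  n <- 750
  pid <- sprintf("P%04d", seq_len(n))
  u <- rnorm(n, 0, 0.5)
  d <- do.call(rbind, lapply(c("9", "15"), function(v)
    data.frame(participant_id = pid, visit = v, age = rnorm(n, 12, 1),
               exp_pm10_birth = rnorm(n, 15, 3)[1:n], stringsAsFactors = FALSE)))
  d$exp_pm10_birth <- rep(rnorm(n, 15, 3), 2)
  d$score_pm10_zscored <- rep(u, 2) + rnorm(2 * n, 0, 0.5)
  m <- fit_mixed_model(d, "pm10", covariates = "age", iqr = 3.2)
  expect_identical(m$model_type, "lme")
  ratio <- m$varcomp[["sd_intercept"]] / m$varcomp[["sd_residual"]]
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.18)
})

test_that("the mixed model recovers a pooled planted slope of -0.1472 SD/IQR", {
  est <- vapply(1:12, function(s) {
    cfg <- cohort_config(n_participants = 400, seed = 4100 + s,
                         n_deconv_sites = 20, n_background_sites = 30,
                         planted_effects = c(pm25 = -0.029, pm10 = -0.1472,
                                             no2 = 0))
    d <- build_analysis_table(generate_cohort(cfg))$data
    fit_mixed_model(d, "pm10", iqr = 3.20)$effect
  }, 0)
  expect_lt(abs(mean(est) - (-0.1472)), 3 * sd(est) / sqrt(length(est)))
})

test_that("null models cover zero at the nominal 95% rate", {
  hits <- vapply(1:500, function(s) {
    d <- make_model_data(n = 120, slope_per_unit = 0, seed = 5000 + s,
                         visits = "15")
    m <- fit_visit_model(d, "pm10", "15", covariates = c("age", "sex"))
    m$ci_low <= 0 && m$ci_high >= 0
  }, TRUE)
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("median-split bivariate tests behave at the null and under shifts", {
  set.seed(46)
  n <- 800
  d <- data.frame(exp_pm10_birth = rnorm(n, 15, 3),
                  score = rnorm(n),
                  cat = factor(sample(c("a", "b", "c"), n, TRUE)),
                  const = factor(rep("x", n)))
  out <- bivariate_tests(d, "exp_pm10_birth",
                         covariates = c("score", "cat", "const"))
  expect_equal(out$p_value[out$covariate == "const"], 1)
  expect_gt(out$p_value[out$covariate == "score"], 0.001)  # null covariate
  # ties go to the lower stratum: a point mass at the median lands in "low",
  # leaving a 3/2 split that supports a t-test
  d2 <- data.frame(x = c(1, 1, 1, 2, 3), v = c(0.1, 0.9, 0.5, 1.2, 1.4))
  out2 <- bivariate_tests(d2, "x", covariates = "v")
  expect_true(is.finite(out2$p_value))
  # zero variance in both strata is reported as degenerate, not an error
  d3 <- data.frame(x = c(1, 1, 2, 2), v = c(0, 0, 1, 1))
  out3 <- bivariate_tests(d3, "x", covariates = "v")
  expect_true(is.na(out3$p_value))
  expect_identical(out3$reason, "degenerate stratum")

  # planted 1-sd mean shift at n=400/arm is detected at p < 0.001
  ps <- vapply(1:20, function(s) {
    set.seed(600 + s)
    dd <- data.frame(x = rep(c(0, 1), each = 400),
                     v = rnorm(800) + rep(c(0, 1), each = 400))
    bivariate_tests(dd, "x", covariates = "v")$p_value
  }, 0)
  expect_true(all(ps < 0.001))
})

test_that("the sensitivity suite adjusts, switches outcomes and skips cleanly", {
  d <- make_model_data(n = 300, slope_per_unit = 0.02, seed = 47)
  d$exp_pm25_birth <- rnorm(nrow(d), 27.9, 7)       # uncorrelated co-pollutant
  d$score_no2_zscored <- rnorm(nrow(d))
  base <- fit_mixed_model(d, "pm10", covariates = c("age", "sex"), iqr = 3.2)
  out <- sensitivity_suite(d, "pm10", analyses = c("copollutant", "no2",
                                                   "age1", "cpg"),
                           covariates = c("age", "sex"), iqr = 3.2)
  # co-pollutant with zero correlation and zero co-effect barely moves the
  # primary estimate
  expect_lt(abs(out$results$copollutant$effect - base$effect),
            2 * (base$ci_high - base$effect))
  expect_identical(out$results$no2$outcome, "score_no2_zscored")
  # missing postnatal exposure and CpG columns are skipped with log entries
  expect_true(any(grepl("age1 skipped", out$log)))
  expect_true(any(grepl("cpg_cg00905156 skipped", out$log)))
})

test_that("single-CpG models recover a planted percent-scale effect", {
  set.seed(48)
  reps <- vapply(1:40, function(s) {
    set.seed(900 + s)
    n <- 735
    expo <- rnorm(n, 15, 3.06)
    d <- data.frame(participant_id = sprintf("P%04d", 1:n), visit = "15",
                    age = rnorm(n, 15.4, 0.5),
                    sex = factor(rep_len(c("male", "female"), n)),
                    exp_pm10_birth = expo, stringsAsFactors = FALSE)
    # plant +0.135 percent methylation per 3.20 ug/m3/day at cg20340716
    d$cpg_cg20340716 <- 92.8 + 0.135 * expo / 3.20 + rnorm(n, 0, 1.37)
    out <- sensitivity_suite(d, "pm10", analyses = "cpg",
                             covariates = c("age", "sex"), iqr = 3.20)
    out$results$cpg_cg20340716$effect
  }, 0)
  expect_lt(abs(mean(reps) - 0.135), 3 * sd(reps) / sqrt(length(reps)))
})
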