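small_cfg <- function(seed = 11, ...) {
  cohort_config(n_participants = 30, n_deconv_sites = 20,
                n_background_sites = 30, seed = seed, ...)
}

test_that("identical config and seed give identical cohorts and files", {
  c1 <- generate_cohort(small_cfg())
  c2 <- generate_cohort(small_cfg())
  expect_identical(c1, c2)

  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("different seeds change the cohort", {
  c1 <- generate_cohort(small_cfg())
  c2 <- generate_cohort(small_cfg(seed = 12))
  expect_false(identical(c1$truth$exposures_wide, c2$truth$exposures_wide))
})

test_that("exposure margins and correlations match their calibration targets", {
  cfg <- cohort_config(n_participants = 10000, generate_betas = FALSE, seed = 13)
  W <- generate_cohort(cfg)$truth$exposures_wide
  n <- nrow(W)
  # means/sds within 3 Monte-Carlo standard errors; all values in range
  expect_lt(abs(mean(W$pm25_birth) - 27.9), 3 * 7.04 / sqrt(n))
  expect_lt(abs(sd(W$pm25_birth) - 7.04), 3 * 7.04 / sqrt(2 * n))
  expect_lt(abs(mean(W$pm10_birth) - 15.0), 3 * 3.06 / sqrt(n))
  expect_lt(abs(sd(W$pm10_birth) - 3.06), 3 * 3.06 / sqrt(2 * n))
  expect_true(all(W$pm25_birth >= 14.3 & W$pm25_birth <= 45.0))
  expect_true(all(W$pm10_birth >= 7.5 & W$pm10_birth <= 20.2))
  se_r <- function(r) (1 - r^2) / sqrt(n)
  expect_lt(abs(cor(W$pm25_birth, W$pm25_age1) - 0.54), 3 * se_r(0.54))
  expect_lt(abs(cor(W$pm25_birth, W$pm25_age3) - 0.57), 3 * se_r(0.57))
  expect_lt(abs(cor(W$pm10_birth, W$pm10_age1) - 0.71), 3 * se_r(0.71))
  expect_lt(abs(cor(W$pm25_birth, W$pm10_birth) - 0.20), 3 * se_r(0.20))
})

test_that("infeasible correlation targets raise a block-naming error", {
  cal <- default_exposure_calibration()
  cal$pm25$r_birth_age1 <- 0.99
  cal$pm25$r_birth_age3 <- -0.99
  cal$pm25$r_age1_age3 <- 0.99
  expect_error(generate_cohort(cohort_config(n_participants = 5,
                                             exposure_calibration = cal,
                                             generate_betas = FALSE)),
               "positive definite")
})

test_that("betas are bounded, visits covered, and truth labels planted faults", {
  coh <- generate_cohort(small_cfg(qc_fault_counts = c(detection = 4,
                                                       sex_discordant = 2,
                                                       abnormal = 1)))
  for (b in coh$bundles) {
    expect_true(all(b$beta >= 0 & b$beta <= 1))
    expect_true(all(b$detp >= 0 & b$detp <= 1))
  }
  expect_equal(nrow(coh$truth$faults), 7)
  expect_equal(as.integer(table(coh$truth$faults$rule)[c("detection",
                                                         "sex_discordant",
                                                         "abnormal")]),
               c(4L, 2L, 1L))
  # every participant appears in at least one bundle
  seen <- unique(unlist(lapply(coh$bundles, function(b) b$samples$participant_id)))
  expect_setequal(seen, coh$covariates$participant_id)
})

test_that("re-injection with new counts produces exactly those faults", {
  coh <- generate_cohort(small_cfg())
  coh2 <- inject_qc_faults(coh, c(detection = 5, sex_discordant = 0,
                                  abnormal = 0))
  logs <- do.call(rbind, lapply(coh2$bundles, function(b) filter_samples(b)$log))
  expect_equal(nrow(logs), 5)
  expect_true(all(logs$rule == "detection"))
  # zero counts leave the bundles untouched
  coh3 <- inject_qc_faults(coh, c(detection = 0, sex_discordant = 0,
                                  abnormal = 0))
  expect_identical(coh3$bundles, coh$bundles)
  expect_equal(nrow(coh3$truth$faults), 0)
  # infeasible counts error
  expect_error(inject_qc_faults(coh, c(detection = 1000)), "exceed")
})

test_that("null planted effects leave the score unrelated to exposure", {
  slopes <- vapply(1:25, function(s) {
    cfg <- cohort_config(n_participants = 120, seed = 300 + s,
                         n_deconv_sites = 10, n_background_sites = 10,
                         planted_effects = c(pm25 = 0, pm10 = 0, no2 = 0))
    coh <- generate_cohort(cfg)
    d <- build_analysis_table(coh, qc = FALSE)$data
    xt <- (d$exp_pm10_birth - 15) / 3.2
    unname(coef(lm(d$score_pm10_zscored ~ xt))[2])
  }, 0)
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("the realized standardized score carries the planted slope", {
  # strong plants need a matching visit-to-visit correlation floor: the
  # between-person score correlation cannot fall below the shared
  # exposure-driven share of variance
  cfg <- cohort_config(n_participants = 4000, seed = 17,
                       n_deconv_sites = 10, n_background_sites = 10,
                       planted_effects = c(pm25 = -0.25, pm10 = -0.4, no2 = 0),
                       score_site_longitudinal_r = c(pm25 = 0.55, pm10 = 0.6,
                                                     no2 = 0.45))
  d <- build_analysis_table(generate_cohort(cfg), qc = FALSE)$data
  for (p in c("pm25", "pm10")) {
    iqr <- default_exposure_calibration()[[p]]$iqr_ref
    mu <- default_exposure_calibration()[[p]]$mean
    xt <- (d[[sprintf("exp_%s_birth", p)]] - mu) / iqr
    sl <- unname(coef(lm(d[[sprintf("score_%s_zscored", p)]] ~ xt))[2])
    b <- cfg$planted_effects[[p]]
    se <- 1 / (sd(xt) * sqrt(nrow(d)))
    expect_lt(abs(sl - b), 4 * se)
  }
})

test_that("cell proportions and covariates track their calibration", {
  coh <- generate_cohort(cohort_config(n_participants = 1500, seed = 19,
                                       n_deconv_sites = 5,
                                       n_background_sites = 5))
  cp <- coh$truth$cell_props
  expect_gt(mean(cp$immune), 0.90)
  expect_lt(mean(cp$immune), 0.97)
  expect_equal(cp$immune + cp$epithelial, rep(1, nrow(cp)))
  cv <- coh$covariates
  expect_lt(abs(mean(cv$sex == "male") - 0.505), 0.05)
  expect_lt(abs(mean(cv$marital == "married") - 0.237), 0.05)
  # visit ages follow the configured distributions
  a9 <- coh$bundles[["9"]]$samples$age
  a15 <- coh$bundles[["15"]]$samples$age
  expect_lt(abs(mean(a9) - 9.30), 0.05)
  expect_lt(abs(mean(a15) - 15.4), 0.07)
})

test_that("configs validate and roundtrip through YAML", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(signal_fraction = 1.2), "signal_fraction")
  expect_error(cohort_config(qc_fault_counts = c(detection = 1e6)),
               "infeasible")
  cfg <- small_cfg(planted_effects = c(pm25 = -0.1, pm10 = -0.2, no2 = 0))
  f <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, f)
  cfg2 <- read_cohort_config(f)
  expect_equal(cfg2$planted_effects, cfg$planted_effects)
  expect_equal(cfg2$n_participants, cfg$n_participants)
  expect_identical(generate_cohort(cfg)$truth$exposures_wide,
                   generate_cohort(cfg2)$truth$exposures_wide)
  unlink(f)
})

test_that("cohort files roundtrip through the bundle reader", {
  coh <- generate_cohort(small_cfg())
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(coh, d)
  b <- read_beta_bundle(file.path(d, "betas_visit9.tsv"),
                        file.path(d, "detp_visit9.tsv"),
                        file.path(d, "samples_visit9.csv"), visit = "9")
  expect_equal(dim(b$beta), dim(coh$bundles[["9"]]$beta))
  expect_equal(b$beta, coh$bundles[["9"]]$beta, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
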