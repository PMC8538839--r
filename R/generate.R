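# Synthetic cohort generator.
#
# The generator draws calibrated exposures through a gaussian copula with
# truncated-normal margins, then realizes score-CpG betas so that the z-scored
# cumulative methylation score computed downstream carries, in population, the
# planted slope per IQR of prenatal exposure and the configured visit-to-visit
# correlation. Derivation: with site signal loadings a_j = f * sd_j * sign(w_j)
# and independent site noise, the z-scored weighted sum equals
# lambda * S + N with lambda = f * sum|w|, Var(N) = (1 - f^2) * sum(w^2), so a
# latent slope b' = b * sqrt(lambda^2 + Var(N)) / lambda yields a realized
# standardized-score slope of exactly b.

# Fixed score-site baselines. PM10 means follow the published site-level
# summaries; sds are held in a narrow band so the raw- and z-scored-variant
# scores stay highly correlated (see vignette). PM2.5/NO2 sites are synthetic.
score_site_params <- function() {
  list(
    pm10 = data.frame(
      cpg_id = c("cg00905156", "cg06849931", "cg15082635",
                 "cg18640183", "cg20340716", "cg24127244"),
      mu = c(0.0248, 0.734, 0.0191, 0.0482, 0.928, 0.0246),
      sd = c(0.015, 0.018, 0.012, 0.014, 0.013, 0.016),
      stringsAsFactors = FALSE),
    pm25 = data.frame(
      cpg_id = sprintf("cg900000%02d", 1:14),
      mu = c(0.05, 0.12, 0.88, 0.31, 0.66, 0.09, 0.74, 0.45,
             0.21, 0.93, 0.58, 0.15, 0.82, 0.37),
      sd = rep(c(0.014, 0.017, 0.012, 0.016, 0.013, 0.015, 0.018), 2),
      stringsAsFactors = FALSE),
    no2 = data.frame(
      cpg_id = sprintf("cg910000%02d", 1:10),
      mu = c(0.11, 0.86, 0.28, 0.63, 0.07, 0.71, 0.49, 0.90, 0.19, 0.55),
      sd = rep(c(0.013, 0.016, 0.012, 0.017, 0.015), 2),
      stringsAsFactors = FALSE)
  )
}

# Latent copula correlation matrix and matched margins for the six exposure
# variables (two pollutants x three anchors). Errors if a correlation block is
# infeasible (not positive definite).
exposure_copula_setup <- function(cal) {
  margins <- list(
    pm25 = match_trunc_normal(cal$pm25$mean, cal$pm25$sd,
                              cal$pm25$range[1], cal$pm25$range[2]),
    pm10 = match_trunc_normal(cal$pm10$mean, cal$pm10$sd,
                              cal$pm10$range[1], cal$pm10$range[2]))
  vars <- c("pm25_birth", "pm25_age1", "pm25_age3",
            "pm10_birth", "pm10_age1", "pm10_age3")
  pol <- rep(c("pm25", "pm10"), each = 3)
  anc <- rep(c("birth", "age1", "age3"), 2)
  tgt <- diag(6)
  for (i in 1:5) for (j in (i + 1):6) {
    if (pol[i] == pol[j]) {
      key <- sort(c(anc[i], anc[j]))
      r <- if (identical(key, c("age1", "birth"))) cal[[pol[i]]]$r_birth_age1
      else if (identical(key, c("age3", "birth"))) cal[[pol[i]]]$r_birth_age3
      else cal[[pol[i]]]$r_age1_age3
    } else {
      r <- if (anc[i] == anc[j]) cal$cross_same_anchor else cal$cross_other_anchor
    }
    tgt[i, j] <- tgt[j, i] <- r
  }
  ev <- eigen(tgt, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop_ms("exposure correlation targets are not positive definite (min eigenvalue %.3g); check the within/cross-pollutant correlation block", min(ev))
  lat <- tgt
  for (i in 1:5) for (j in (i + 1):6) {
    lat[i, j] <- lat[j, i] <- latent_rho(tgt[i, j], margins[[pol[i]]],
                                         margins[[pol[j]]])
  }
  ev <- eigen(lat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop_ms("latent copula correlation matrix is not positive definite (min eigenvalue %.3g)", min(ev))
  dimnames(lat) <- list(vars, vars)
  list(margins = margins, latent = lat, vars = vars, pol = pol)
}

draw_exposures <- function(setup, n) {
  L <- chol(setup$latent)
  Z <- matrix(rnorm(n * 6), n, 6) %*% L
  X <- matrix(NA_real_, n, 6, dimnames = list(NULL, setup$vars))
  for (k in 1:6)
    X[, k] <- qtrunc_normal(pnorm(Z[, k]), setup$margins[[setup$pol[k]]])
  X
}

beta_dist_ab <- function(mean, sd) {
  v <- min(sd^2, mean * (1 - mean) * 0.95)
  nu <- mean * (1 - mean) / v - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

#' Generate a synthetic cohort
#'
#' Produces a seeded synthetic cohort with the statistical structure the
#' downstream analysis assumes: calibrated correlated exposures, 450k-style
#' beta and detection-p matrices for up to two visits containing the score
#' CpGs, a two-cell-type (immune/epithelial) reference panel and mixing
#' structure, covariates, sex-check features, an optional monitor network
#' whose inverse-distance-weighted window averages reproduce the assigned
#' exposures, and a truth record of everything planted.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with elements
#'   `config`, `covariates`, `exposures` (long), `bundles` (one
#'   `beta_bundle` per visit), `reference` (deconvolution panel),
#'   `monitors`/`residences` (if configured) and `truth`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 20, seed = 7))
#' coh
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cohort <- with_seed(config$seed, generate_cohort_impl(config))
  k <- config$qc_fault_counts
  if (sum(k) > 0) cohort <- inject_qc_faults(cohort, k)
  cohort
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  pid <- sprintf("P%05d", seq_len(n))
  nv <- length(cfg$visits)

  ## covariates (frequencies follow the cohort the generator emulates)
  race_lev <- c("NH White", "NH Black", "Hispanic", "Other", "Multiracial")
  race_p <- c(0.166, 0.563, 0.198, 0.0285, 0.0441)
  covariates <- data.frame(
    participant_id = pid,
    sex = ifelse(runif(n) < 0.505, "male", "female"),
    race = race_lev[apply(rmultinom(n, 1, race_p / sum(race_p)) == 1, 2, which)],
    income_needs = round(rlnorm(n, log(1.4), 0.983), 3),
    marital = ifelse(runif(n) < 0.237, "married", "not married"),
    stringsAsFactors = FALSE)

  ## exposures
  setup <- exposure_copula_setup(cfg$exposure_calibration)
  X <- draw_exposures(setup, n)
  exposures <- data.frame(
    participant_id = rep(pid, 6),
    pollutant = rep(setup$pol, each = n),
    anchor = rep(rep(c("birth", "age1", "age3"), 2), each = n),
    value = as.vector(X), stringsAsFactors = FALSE)

  ## visit / sample structure: single-visit participants keep the last visit
  single <- if (cfg$n_single_visit > 0)
    pid[seq_len(cfg$n_single_visit)] else character(0)
  samples <- list()
  for (vi in seq_len(nv)) {
    v <- cfg$visits[[vi]]
    keep <- if (vi < nv) setdiff(pid, single) else pid
    idx <- match(keep, pid)
    samples[[v$label]] <- data.frame(
      sample_id = sprintf("%s_V%s", keep, v$label),
      participant_id = keep,
      visit = v$label,
      age = round(rnorm(length(keep), v$age_mean, v$age_sd), 2),
      recorded_sex = covariates$sex[idx],
      stringsAsFactors = FALSE)
  }

  ## latent standardized scores per pollutant
  site_par <- score_site_params()
  wtabs <- all_weight_tables()
  truth_scores <- list()
  latentS <- list()   # latentS[[pollutant]][[visit]] aligned to samples rows
  plant <- list()
  for (p in names(wtabs)) {
    w <- wtabs[[p]]$weight
    f <- cfg$signal_fraction
    lambda <- f * sum(abs(w))
    sigN2 <- (1 - f^2) * sum(w^2)
    sT <- sqrt(lambda^2 + sigN2)
    b <- unname(cfg$planted_effects[[p]])
    bp <- if (b == 0) 0 else b * sT / lambda
    r_s <- unname(cfg$score_site_longitudinal_r[[p]])
    if (p == "no2") {
      xt <- rep(0, n)  # specificity null: no exposure drives the NO2 score
      Vx <- 0
    } else {
      calp <- cfg$exposure_calibration[[p]]
      xt <- (X[, paste0(p, "_birth")] - calp$mean) / calp$iqr_ref
      Vx <- (calp$sd / calp$iqr_ref)^2
    }
    if (bp^2 * Vx >= 1)
      stop_ms("planted effect for %s too large for a unit-variance score", p)
    cc <- (r_s - bp^2 * Vx) / (1 - bp^2 * Vx)
    if (cc < 0 || cc > 1)
      stop_ms("score_site_longitudinal_r[%s]=%.3g infeasible with planted effect %.3g", p, r_s, b)
    u <- rnorm(n)
    resid_sd <- sqrt(1 - bp^2 * Vx)
    latentS[[p]] <- list()
    for (v in names(samples)) {
      sm <- samples[[v]]
      i <- match(sm$participant_id, pid)
      e <- rnorm(nrow(sm))
      S <- bp * xt[i] + resid_sd * (sqrt(cc) * u[i] + sqrt(1 - cc) * e)
      latentS[[p]][[v]] <- S
      truth_scores[[paste(p, v)]] <- data.frame(
        sample_id = sm$sample_id, pollutant = p, visit = v,
        latent_score = S, stringsAsFactors = FALSE)
    }
    plant[[p]] <- list(slope_per_iqr = b, latent_slope = bp,
                       attenuation = lambda / sT, longitudinal_r = r_s)
  }

  ## reference panel for deconvolution
  nd <- cfg$n_deconv_sites
  r_imm <- runif(nd, 0.05, 0.95)
  delta <- runif(nd, 0.25, 0.6) * sample(c(-1, 1), nd, replace = TRUE)
  r_epi <- clamp(r_imm + delta, 0.02, 0.98)
  reference <- data.frame(cpg_id = sprintf("cgD%05d", seq_len(nd)),
                          immune = r_imm, epithelial = r_epi,
                          stringsAsFactors = FALSE)

  ## cell proportions per observation
  cell_props <- list()
  for (vi in seq_len(nv)) {
    v <- cfg$visits[[vi]]$label
    ab <- beta_dist_ab(cfg$immune_mean[min(vi, length(cfg$immune_mean))],
                       cfg$immune_sd[min(vi, length(cfg$immune_sd))])
    pimm <- stats::rbeta(nrow(samples[[v]]), ab["a"], ab["b"])
    cell_props[[v]] <- data.frame(sample_id = samples[[v]]$sample_id,
                                  immune = pimm, epithelial = 1 - pimm,
                                  stringsAsFactors = FALSE)
  }

  bundles <- NULL
  if (cfg$generate_betas) {
    ## background site baselines shared across visits
    nb <- cfg$n_background_sites
    comp <- sample.int(3, nb, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    bg_mu <- rnorm(nb, c(-3, 3, 0)[comp], c(0.5, 0.5, 1)[comp])
    bg_tau <- runif(nb, 0.25, 0.6)
    rho_bg <- cfg$bg_longitudinal_r
    bg_shared <- list()  # per participant latent, drawn below per visit member

    score_ids <- unlist(lapply(site_par, `[[`, "cpg_id"), use.names = FALSE)
    cpg_ids <- c(score_ids, reference$cpg_id, sprintf("cgB%05d", seq_len(nb)))

    # shared (cross-visit) site noise for score CpGs and background CpGs
    eta0 <- matrix(rnorm(n * length(score_ids)), n,
                   dimnames = list(pid, score_ids))
    z0 <- matrix(rnorm(n * nb), n, dimnames = list(pid, NULL))

    bundles <- list()
    for (v in names(samples)) {
      sm <- samples[[v]]
      ns <- nrow(sm)
      i <- match(sm$participant_id, pid)
      beta <- matrix(NA_real_, length(cpg_ids), ns,
                     dimnames = list(cpg_ids, sm$sample_id))
      ## score sites
      for (p in names(wtabs)) {
        sp <- site_par[[p]]
        w <- wtabs[[p]]$weight
        f <- cfg$signal_fraction
        r_s <- unname(cfg$score_site_longitudinal_r[[p]])
        S <- latentS[[p]][[v]]
        for (j in seq_len(nrow(sp))) {
          epsv <- rnorm(ns)
          eps <- sqrt(r_s) * eta0[i, sp$cpg_id[j]] + sqrt(1 - r_s) * epsv
          beta[sp$cpg_id[j], ] <-
            sp$mu[j] + f * sp$sd[j] * sign(w[j]) * S +
            sp$sd[j] * sqrt(1 - f^2) * eps
        }
      }
      ## deconvolution sites: two-cell mixtures plus noise
      pimm <- cell_props[[v]]$immune
      mix <- outer(reference$immune, pimm) + outer(reference$epithelial, 1 - pimm)
      beta[reference$cpg_id, ] <- mix + rnorm(nd * ns, 0, 0.02)
      ## background sites: logit-normal with bimodal baselines
      zv <- matrix(rnorm(nb * ns), nrow = nb, ncol = ns)
      lat <- bg_mu + bg_tau * (sqrt(rho_bg) * t(z0[i, , drop = FALSE]) +
                                 sqrt(1 - rho_bg) * zv)
      beta[sprintf("cgB%05d", seq_len(nb)), ] <- plogis(lat)
      beta <- clamp(beta, 0, 1)

      detp <- matrix(runif(length(cpg_ids) * ns, 0, 0.005),
                     length(cpg_ids), ns, dimnames = dimnames(beta))
      sm$predicted_sex <- sm$recorded_sex
      sm$sexchrom_intensity <- clamp(rnorm(ns), -3.5, 3.5)
      bundles[[v]] <- new_beta_bundle(beta, detp, sm, v)
    }
  }

  ## monitors + residences reproducing the assigned exposures through IDW
  monitors <- residences <- NULL
  if (cfg$generate_monitors) {
    idx <- seq_len(n) - 1L
    row <- idx %% 16L; col <- (idx %/% 16L) %% 26L; k <- idx %/% 416L
    lat_ <- 29 + 1.2 * row + 0.001 * k
    lon_ <- -124 + 2 * col
    birth <- as.Date("1998-02-01") + sample.int(850, n, replace = TRUE) - 1L
    residences <- data.frame(participant_id = pid, lat = lat_, lon = lon_,
                             birth_date = birth, age1_date = birth + 365L,
                             age3_date = birth + 1095L, stringsAsFactors = FALSE)
    # one 91-day window per participant x pollutant x anchor; bounded daily
    # noise is re-centered within each window so the window mean is exact
    noise_amp <- c(pm25 = 4, pm10 = 2)
    win <- expand.grid(ii = seq_len(n), pollutant = c("pm25", "pm10"),
                       anchor = c("birth", "age1", "age3"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    offs <- c(birth = 0L, age1 = 365L, age3 = 1095L)
    anchor_dates <- birth[win$ii] + offs[win$anchor]
    targets <- X[cbind(win$ii, match(paste0(win$pollutant, "_", win$anchor),
                                     colnames(X)))]
    E <- matrix(runif(91L * nrow(win), -1, 1), nrow = 91L) *
      rep(noise_amp[win$pollutant], each = 91L)
    E <- sweep(E, 2, colMeans(E))
    monitors <- data.frame(
      monitor_id = rep(sprintf("M%05d", win$ii), each = 91L),
      lat = rep(lat_[win$ii], each = 91L),
      lon = rep(lon_[win$ii], each = 91L),
      date = rep(anchor_dates, each = 91L) - 91L + 0:90,
      pollutant = rep(win$pollutant, each = 91L),
      value = rep(targets, each = 91L) + as.vector(E),
      stringsAsFactors = FALSE)
  }

  truth <- list(planted = plant,
                scores = do.call(rbind, c(truth_scores, make.row.names = FALSE)),
                cell_props = do.call(rbind, c(cell_props, make.row.names = FALSE)),
                faults = data.frame(sample_id = character(0), rule = character(0),
                                    stringsAsFactors = FALSE),
                exposures_wide = cbind(data.frame(participant_id = pid,
                                                  stringsAsFactors = FALSE),
                                       as.data.frame(X)),
                calibration = list(margins = setup$margins, latent = setup$latent))

  structure(list(config = cfg, covariates = covariates, exposures = exposures,
                 bundles = bundles, reference = reference, monitors = monitors,
                 residences = residences, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_obs <- sum(vapply(x$bundles, function(b) nrow(b$samples), 1L))
  cat(sprintf("Synthetic cohort: %d participants, %d visits, %s observations\n",
              x$config$n_participants, length(x$config$visits),
              if (is.null(x$bundles)) "exposure-only" else n_obs))
  if (!is.null(x$bundles))
    cat(sprintf("  CpGs per bundle: %d; planted faults: %d\n",
                nrow(x$bundles[[1]]$beta), nrow(x$truth$faults)))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}

#' Inject quality-control faults into a synthetic cohort
#'
#' Plants count-exact QC failures across the pooled samples of all visits:
#' `detection` samples get >10\% of sites with detection p-value > 0.01 (the
#' affected cells are redrawn from Uniform(0.02, 1)); `sex_discordant` samples
#' get the predicted-sex feature flipped; `abnormal` samples get a
#' sex-chromosome intensity outside the normal band. Fault sets are disjoint
#' (sampled without replacement), so downstream first-match drop attribution
#' recovers the exact planted counts.
#'
#' @param cohort a `synthetic_cohort` with beta bundles.
#' @param counts named vector `detection`, `sex_discordant`, `abnormal`.
#' @param seed RNG seed for fault placement; default derives from the cohort
#'   seed.
#' @return the cohort with modified bundles and an updated `truth$faults`.
#' @export
inject_qc_faults <- function(cohort, counts, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$bundles))
    stop_ms("cohort has no beta bundles (generate_betas = FALSE)")
  k <- c(detection = 0L, sex_discordant = 0L, abnormal = 0L)
  k[names(counts)] <- as.integer(counts)
  all_ids <- unlist(lapply(cohort$bundles, function(b) b$samples$sample_id),
                    use.names = FALSE)
  if (sum(k) > length(all_ids))
    stop_ms("fault counts (%d) exceed sample count (%d)", sum(k), length(all_ids))
  if (is.null(seed)) seed <- cohort$config$seed + 1L
  faults <- with_seed(seed, {
    chosen <- sample(all_ids, sum(k))
    data.frame(sample_id = chosen,
               rule = rep(c("detection", "sex_discordant", "abnormal"), k),
               stringsAsFactors = FALSE)
  })
  if (sum(k) > 0) {
    cohort$bundles <- with_seed(seed + 1L, lapply(cohort$bundles, function(b) {
      hit <- faults[faults$sample_id %in% b$samples$sample_id, , drop = FALSE]
      for (r in seq_len(nrow(hit))) {
        sid <- hit$sample_id[r]
        j <- match(sid, b$samples$sample_id)
        switch(hit$rule[r],
          detection = {
            nfail <- ceiling(0.15 * nrow(b$detp))
            sites <- sample.int(nrow(b$detp), nfail)
            b$detp[sites, j] <- runif(nfail, 0.02, 1)
          },
          sex_discordant = {
            b$samples$predicted_sex[j] <-
              ifelse(b$samples$predicted_sex[j] == "male", "female", "male")
          },
          abnormal = {
            b$samples$sexchrom_intensity[j] <- sample(c(-6, 6), 1)
          })
      }
      b
    }))
  }
  cohort$truth$faults <- faults
  cohort
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `monitors.csv`, `residences.csv` (when generated), `covariates.csv`,
#' `exposures.csv`, `reference.csv`, per-visit `betas_visit<label>.tsv`,
#' `detp_visit<label>.tsv`, `samples_visit<label>.csv`, and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(cohort$covariates, "covariates.csv")
  wr(cohort$exposures, "exposures.csv")
  wr(cohort$reference, "reference.csv")
  if (!is.null(cohort$monitors)) wr(cohort$monitors, "monitors.csv")
  if (!is.null(cohort$residences)) wr(cohort$residences, "residences.csv")
  for (v in names(cohort$bundles)) {
    b <- cohort$bundles[[v]]
    write.table(b$beta, file.path(dir, sprintf("betas_visit%s.tsv", v)),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(b$detp, file.path(dir, sprintf("detp_visit%s.tsv", v)),
                sep = "\t", quote = FALSE, col.names = NA)
    wr(b$samples, sprintf("samples_visit%s.csv", v))
  }
  truth <- cohort$truth
  truth$calibration <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
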