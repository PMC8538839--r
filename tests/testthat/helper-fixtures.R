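# Shared fixtures, built in code.

# Independent haversine implementation (oracle for distance-weighted means).
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}

# Brute-force inverse-distance weighted mean.
oracle_idw <- function(point, monitors_sub) {
  d <- oracle_haversine_km(point[1], point[2], monitors_sub$lat,
                           monitors_sub$lon)
  if (any(d == 0)) return(mean(monitors_sub$value[d == 0]))
  sum(monitors_sub$value / d) / sum(1 / d)
}

make_monitors <- function(lat, lon, value, date = as.Date("1999-06-01"),
                          pollutant = "pm10") {
  data.frame(monitor_id = sprintf("m%02d", seq_along(lat)), lat = lat,
             lon = lon, date = date, pollutant = pollutant, value = value,
             stringsAsFactors = FALSE)
}

# Minimal hand-built beta bundle with controllable detection failures and
# sex features. `fail_frac` gives, per sample, the fraction of sites with
# detection p above threshold.
make_bundle <- function(n_cpg = 100, n_sample = 10, fail_frac = NULL,
                        predicted_sex = NULL, intensity = NULL, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  beta <- withr_seed(matrix(runif(n_cpg * n_sample), n_cpg, n_sample))
  dimnames(beta) <- list(sprintf("cg%05d", seq_len(n_cpg)),
                         sprintf("s%03d", seq_len(n_sample)))
  detp <- matrix(0.001, n_cpg, n_sample, dimnames = dimnames(beta))
  if (!is.null(fail_frac)) {
    for (j in seq_along(fail_frac)) {
      k <- round(fail_frac[j] * n_cpg)
      if (k > 0) detp[seq_len(k), j] <- 0.5
    }
  }
  sex <- rep(c("male", "female"), length.out = n_sample)
  samples <- data.frame(
    sample_id = colnames(beta),
    participant_id = sprintf("P%03d", seq_len(n_sample)),
    visit = "9", age = 9.3, recorded_sex = sex,
    predicted_sex = if (is.null(predicted_sex)) sex else predicted_sex,
    sexchrom_intensity = if (is.null(intensity)) rep(0, n_sample) else intensity,
    stringsAsFactors = FALSE)
  methylscore:::new_beta_bundle(beta, detp, samples, "9")
}

# Small analysis-style data frame with a known exposure-score slope, for
# model-level tests that do not need the full generator.
make_model_data <- function(n = 300, slope_per_unit = 0, seed = 1,
                            visits = c("9", "15"), sigma = 1) {
  set.seed(seed)
  pid <- sprintf("P%04d", seq_len(n))
  rows <- do.call(rbind, lapply(visits, function(v) {
    data.frame(participant_id = pid, visit = v,
               age = rnorm(n, ifelse(v == "9", 9.3, 15.4), 0.4),
               stringsAsFactors = FALSE)
  }))
  rows$sample_id <- paste0(rows$participant_id, "_V", rows$visit)
  expo <- rnorm(n, 15, 3)
  rows$exp_pm10_birth <- expo[match(rows$participant_id, pid)]
  u <- rnorm(n, 0, 0)
  rows$score_pm10_zscored <- slope_per_unit * rows$exp_pm10_birth +
    rnorm(nrow(rows), 0, sigma)
  rows$sex <- factor(rep_len(c("male", "female"), nrow(rows)))
  rows$income_needs <- rlnorm(nrow(rows), 0.3, 1)
  rows$immune <- runif(nrow(rows), 0.7, 1)
  rows
}
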