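# Sample and probe quality control plus cell-composition estimation.

#' Filter samples on detection rate, sex concordance and intensity
#'
#' Applies the three sample-level drop rules in order, with first-match
#' attribution: (1) detection — more than `sample_frac_threshold` of sites
#' have detection p-value > `detp_threshold` (strict inequalities, so a sample
#' failing at exactly the threshold fraction is kept); (2) sex discordance —
#' predicted sex differs from recorded sex; (3) abnormal sex-chromosome
#' intensity — the intensity feature falls outside `intensity_band`.
#'
#' @param bundle a `beta_bundle`.
#' @param detp_threshold per-site detection p-value cutoff (default 0.01).
#' @param sample_frac_threshold fraction of failing sites above which the
#'   sample is dropped (default 0.10, strict `>`).
#' @param intensity_band normal band for the sex-chromosome intensity feature.
#' @return list with `bundle` (kept samples) and `log` (data.frame
#'   `sample_id`, `rule` for each dropped sample).
#' @export
filter_samples <- function(bundle, detp_threshold = 0.01,
                           sample_frac_threshold = 0.10,
                           intensity_band = c(-4, 4)) {
  stopifnot(inherits(bundle, "beta_bundle"))
  sm <- bundle$samples
  if (any(is.na(sm$recorded_sex)))
    stop_ms("recorded sex missing for some samples")
  frac_fail <- colMeans(bundle$detp > detp_threshold)
  rule <- rep(NA_character_, nrow(sm))
  rule[frac_fail > sample_frac_threshold] <- "detection"
  sexbad <- is.na(rule) & sm$predicted_sex != sm$recorded_sex
  rule[sexbad] <- "sex_discordant"
  intbad <- is.na(rule) & (sm$sexchrom_intensity < intensity_band[1] |
                             sm$sexchrom_intensity > intensity_band[2])
  rule[intbad] <- "abnormal"
  drop <- !is.na(rule)
  log <- data.frame(sample_id = sm$sample_id[drop], rule = rule[drop],
                    stringsAsFactors = FALSE)
  keep <- !drop
  kept <- structure(list(beta = bundle$beta[, keep, drop = FALSE],
                         detp = bundle$detp[, keep, drop = FALSE],
                         samples = sm[keep, , drop = FALSE],
                         visit = bundle$visit), class = "beta_bundle")
  list(bundle = kept, log = log)
}

#' Filter probes on detection failure rate and a cross-reactive blocklist
#'
#' Removes probes whose detection p-value exceeds `detp_threshold` in at least
#' `probe_frac_threshold` of samples (inclusive `>=` on the fraction), then
#' removes probes named in the blocklist. Blocklist ids absent from the matrix
#' produce a warning, not an error.
#'
#' @param bundle a `beta_bundle` (normally after [filter_samples()]).
#' @param blocklist character vector of CpG ids, or a path to a one-id-per-line
#'   text file.
#' @param detp_threshold per-site detection p-value cutoff (default 0.01).
#' @param probe_frac_threshold fraction of failing samples at or above which
#'   the probe is removed (default 0.05).
#' @return list with `bundle` (kept probes) and `log` (data.frame `cpg_id`,
#'   `rule`).
#' @export
filter_probes <- function(bundle, blocklist = character(0),
                          detp_threshold = 0.01, probe_frac_threshold = 0.05) {
  stopifnot(inherits(bundle, "beta_bundle"))
  if (length(blocklist) == 1 && file.exists(blocklist))
    blocklist <- readLines(blocklist)
  blocklist <- blocklist[nzchar(blocklist)]
  frac_fail <- rowMeans(bundle$detp > detp_threshold)
  rule <- rep(NA_character_, nrow(bundle$beta))
  rule[frac_fail >= probe_frac_threshold] <- "detection"
  missing_bl <- setdiff(blocklist, rownames(bundle$beta))
  if (length(missing_bl) > 0)
    warn_ms("%d blocklist ids absent from the matrix", length(missing_bl))
  inbl <- is.na(rule) & rownames(bundle$beta) %in% blocklist
  rule[inbl] <- "cross_reactive"
  drop <- !is.na(rule)
  log <- data.frame(cpg_id = rownames(bundle$beta)[drop], rule = rule[drop],
                    stringsAsFactors = FALSE)
  kept <- structure(list(beta = bundle$beta[!drop, , drop = FALSE],
                         detp = bundle$detp[!drop, , drop = FALSE],
                         samples = bundle$samples, visit = bundle$visit),
                    class = "beta_bundle")
  list(bundle = kept, log = log)
}

#' Estimate immune/epithelial cell proportions by constrained projection
#'
#' Per sample, solves least squares of the observed betas on the two reference
#' profiles subject to nonnegativity and sum-to-one. With two cell types the
#' constrained problem has a closed form: project the sample onto the
#' reference difference vector and clamp the immune fraction to [0, 1].
#'
#' @param bundle a `beta_bundle`.
#' @param reference data.frame with columns `cpg_id`, `immune`, `epithelial`
#'   (a CpG-by-2 reference panel).
#' @return data.frame `sample_id`, `immune`, `epithelial` (summing to 1).
#' @export
estimate_cell_proportions <- function(bundle, reference) {
  stopifnot(inherits(bundle, "beta_bundle"))
  common <- intersect(reference$cpg_id, rownames(bundle$beta))
  if (length(common) < 2)
    stop_ms("fewer than 2 reference CpGs present in the bundle")
  ref <- reference[match(common, reference$cpg_id), ]
  R <- cbind(immune = ref$immune, epithelial = ref$epithelial)
  kap <- kappa(R, exact = TRUE)
  if (kap > 1e8)
    stop_ms("reference columns are collinear (condition number %.3g)", kap)
  d <- R[, "immune"] - R[, "epithelial"]
  if (sum(d^2) == 0)
    stop_ms("reference columns are identical (condition number Inf)")
  B <- bundle$beta[common, , drop = FALSE]
  p <- clamp(colSums((B - R[, "epithelial"]) * d) / sum(d^2), 0, 1)
  data.frame(sample_id = bundle$samples$sample_id, immune = unname(p),
             epithelial = unname(1 - p), stringsAsFactors = FALSE)
}
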