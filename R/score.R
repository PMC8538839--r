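# Cumulative DNA methylation scores.
#
# S_i = sum_j w_j * t(beta_ij), where t is the per-site transform of the
# chosen variant and the w_j are effect estimates from an independent EWAS
# meta-analysis; the sums are then z-score-standardized over the
# standardization population. Per-site mean-centering shifts every sum by the
# same constant, so the "raw" and "centered" variants are identical after
# standardization.

#' Cumulative DNA methylation score
#'
#' @param beta CpG-by-sample beta matrix, pooled over the standardization
#'   population (e.g. both visits after QC).
#' @param weights a weight table ([weight_table()]): columns `cpg_id`,
#'   `weight`.
#' @param variant per-site transform before weighting: `"zscored"` (per-site
#'   z-score, the primary score), `"raw"` (untransformed betas), or
#'   `"centered"` (per-site mean-centering). Site statistics are computed
#'   over the columns of `beta`.
#' @param standardize z-score the resulting sums over the same population
#'   (default TRUE).
#' @return data.frame `sample_id`, `variant`, `score_raw_sum` (weighted sum
#'   before final standardization), `score` (standardized), `n_sites_used`.
#'   Weight-table CpGs absent from `beta` are dropped with a warning; under
#'   `"zscored"` zero-variance sites are likewise dropped.
#' @examples
#' b <- matrix(c(0.2, 0.4, 0.6, 0.8, 0.6, 0.4), 2, byrow = TRUE,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
#' w <- data.frame(cpg_id = c("cg1", "cg2"), weight = c(1, -1))
#' cumulative_score(b, w, "raw", standardize = FALSE)$score_raw_sum
#' @export
cumulative_score <- function(beta, weights,
                             variant = c("zscored", "raw", "centered"),
                             standardize = TRUE) {
  variant <- match.arg(variant)
  validate_weight_table(weights)
  present <- weights$cpg_id %in% rownames(beta)
  if (!any(present))
    stop_ms("none of the %d weight-table CpGs are present in the beta matrix",
            nrow(weights))
  if (!all(present))
    warn_ms("%d weight-table CpGs absent from the beta matrix; dropped",
            sum(!present))
  w <- weights[present, , drop = FALSE]
  B <- beta[w$cpg_id, , drop = FALSE]
  if (variant == "zscored") {
    sds <- apply(B, 1, sd)
    zero <- sds == 0 | is.na(sds)
    if (any(zero)) {
      warn_ms("%d zero-variance sites dropped under the zscored variant",
              sum(zero))
      w <- w[!zero, , drop = FALSE]
      B <- B[!zero, , drop = FALSE]
      sds <- sds[!zero]
    }
    if (nrow(B) == 0)
      stop_ms("all sites have zero variance; zscored score undefined")
    Bt <- (B - rowMeans(B)) / sds
  } else if (variant == "centered") {
    Bt <- B - rowMeans(B)
  } else {
    Bt <- B
  }
  raw_sum <- as.vector(colSums(Bt * w$weight))
  score <- raw_sum
  if (standardize) {
    s <- sd(raw_sum)
    if (is.na(s) || s == 0)
      stop_ms("score has zero variance; standardization undefined")
    score <- (raw_sum - mean(raw_sum)) / s
  }
  data.frame(sample_id = colnames(beta), variant = variant,
             score_raw_sum = raw_sum, score = score,
             n_sites_used = nrow(B), stringsAsFactors = FALSE)
}

#' Between-visit correlation of cumulative scores
#'
#' Pearson correlation of the scores over participants present at both
#' visits, matched on `participant_id`.
#'
#' @param scores_v1,scores_v2 data.frames with columns `participant_id` and
#'   `score`.
#' @return Pearson r (scalar).
#' @export
score_visit_correlation <- function(scores_v1, scores_v2) {
  for (s in list(scores_v1, scores_v2))
    if (!all(c("participant_id", "score") %in% names(s)))
      stop_ms("score tables need participant_id and score columns")
  common <- intersect(scores_v1$participant_id, scores_v2$participant_id)
  if (length(common) < 3)
    stop_ms("fewer than 3 participants present at both visits (%d)",
            length(common))
  a <- scores_v1$score[match(common, scores_v1$participant_id)]
  b <- scores_v2$score[match(common, scores_v2$participant_id)]
  cor(a, b)
}
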