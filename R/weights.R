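#' CpG weight tables for cumulative DNA methylation scores
#'
#' A weight table maps CpG probes to effect estimates from an independent
#' cord-blood EWAS meta-analysis; the cumulative score is the weighted sum of
#' (transformed) beta values over these probes. The PM10 table carries the six
#' published probes and their meta-analysis effect estimates. The PM2.5
#' (14 sites) and NO2 (10 sites) tables are synthetic placeholders: the source
#' meta-analysis's site lists for those pollutants are not reprinted here, so
#' the packaged tables use clearly labelled synthetic probe ids with weights on
#' the same scale. They exercise the identical code path.
#'
#' @param pollutant one of `"pm10"`, `"pm25"`, `"no2"`.
#' @param file optional path to a user-supplied CSV with columns
#'   `cpg_id,weight,gene`, overriding the packaged table.
#' @return a `data.frame` with columns `cpg_id`, `weight`, `gene`.
#' @examples
#' nrow(weight_table("pm10"))  # 6
#' @export
weight_table <- function(pollutant = c("pm10", "pm25", "no2"), file = NULL) {
  pollutant <- match.arg(pollutant)
  if (is.null(file)) {
    fname <- switch(pollutant,
                    pm10 = "weights_pm10.csv",
                    pm25 = "weights_pm25_synthetic.csv",
                    no2  = "weights_no2_synthetic.csv")
    file <- system.file("extdata", fname, package = "methylscore", mustWork = TRUE)
  }
  w <- read.csv(file, stringsAsFactors = FALSE)
  validate_weight_table(w)
  w
}

validate_weight_table <- function(w) {
  need <- c("cpg_id", "weight")
  if (!all(need %in% names(w)))
    stop_ms("weight table needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(w$cpg_id))
    stop_ms("weight table has duplicated cpg_ids")
  if (any(!is.finite(w$weight)) || any(w$weight == 0))
    stop_ms("weights must be finite and nonzero")
  invisible(w)
}

# All packaged tables keyed by pollutant.
all_weight_tables <- function() {
  list(pm25 = weight_table("pm25"),
       pm10 = weight_table("pm10"),
       no2  = weight_table("no2"))
}
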