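# BetaBundle: one visit's beta matrix, detection p-values and sample metadata.

new_beta_bundle <- function(beta, detp, samples, visit) {
  b <- structure(list(beta = beta, detp = detp, samples = samples,
                      visit = visit), class = "beta_bundle")
  validate_beta_bundle(b)
  b
}

validate_beta_bundle <- function(b) {
  if (!identical(dim(b$beta), dim(b$detp)))
    stop_ms("beta and detection-p matrices must have identical shape")
  if (!identical(colnames(b$beta), b$samples$sample_id))
    stop_ms("beta columns must match sample metadata order")
  if (any(b$beta < 0 | b$beta > 1, na.rm = TRUE))
    stop_ms("beta values must lie in [0, 1]")
  if (any(b$detp < 0 | b$detp > 1, na.rm = TRUE))
    stop_ms("detection p-values must lie in [0, 1]")
  invisible(b)
}

#' @export
print.beta_bundle <- function(x, ...) {
  cat(sprintf("Beta bundle (visit %s): %d CpGs x %d samples\n",
              x$visit, nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

#' Read a beta bundle from TSV/CSV files
#'
#' `betas` and `detp` are CpG-by-sample TSV matrices (first column CpG ids);
#' `samples` is a CSV of per-sample metadata with a `sample_id` column and,
#' for sex checks, `recorded_sex`, `predicted_sex`, `sexchrom_intensity`.
#'
#' @param betas,detp,samples file paths.
#' @param visit visit label.
#' @return a `beta_bundle`.
#' @export
read_beta_bundle <- function(betas, detp, samples, visit = "") {
  rd <- function(f) {
    m <- as.matrix(read.delim(f, row.names = 1, check.names = FALSE))
    storage.mode(m) <- "double"
    m
  }
  beta <- rd(betas)
  dp <- rd(detp)
  sm <- read.csv(samples, stringsAsFactors = FALSE,
                 colClasses = c(sample_id = "character"))
  sm <- sm[match(colnames(beta), sm$sample_id), , drop = FALSE]
  new_beta_bundle(beta, dp, sm, visit)
}

#' @importFrom utils read.delim write.table
NULL
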