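#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef complete.cases cor dnorm fisher.test lm median
#'   na.omit optim pnorm qnorm quantile rlnorm rmultinom rnorm runif sd
#'   t.test uniroot var plogis confint model.matrix as.formula
#' @importFrom utils read.csv write.csv head
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate an expression with a temporary RNG seed, restoring prior state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

stop_ms <- function(...) stop(sprintf(...), call. = FALSE)
warn_ms <- function(...) warning(sprintf(...), call. = FALSE)

# Moments of a normal(m, s) truncated to [a, b].
trunc_normal_moments <- function(m, s, a, b) {
  al <- (a - m) / s
  be <- (b - m) / s
  Z <- pnorm(be) - pnorm(al)
  mu <- m + s * (dnorm(al) - dnorm(be)) / Z
  v <- s^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                ((dnorm(al) - dnorm(be)) / Z)^2)
  c(mean = mu, sd = sqrt(v))
}

# Parent normal parameters whose [a, b]-truncation has the requested mean/sd.
match_trunc_normal <- function(mean, sd, a, b) {
  obj <- function(p) {
    mo <- trunc_normal_moments(p[1], exp(p[2]), a, b)
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  o <- optim(c(mean, log(sd)), obj, control = list(reltol = 1e-14, maxit = 5000))
  if (o$value > 1e-8)
    stop_ms("cannot match truncated-normal moments mean=%g sd=%g on [%g, %g]",
            mean, sd, a, b)
  list(m = o$par[1], s = exp(o$par[2]), a = a, b = b)
}

# Quantile function of the truncated normal given margin parameters.
qtrunc_normal <- function(u, margin) {
  pa <- pnorm(margin$a, margin$m, margin$s)
  pb <- pnorm(margin$b, margin$m, margin$s)
  clamp(qnorm(pa + u * (pb - pa), margin$m, margin$s), margin$a, margin$b)
}

# Pearson correlation realized between two truncated-normal margins when the
# underlying gaussian copula has latent correlation rho (Gauss-Hermite, 48 pt).
gh_nodes <- function() {
  if (is.null(.ms_cache$gh)) .ms_cache$gh <- pracma::gaussHermite(48)
  .ms_cache$gh
}
.ms_cache <- new.env(parent = emptyenv())

realized_pearson <- function(rho, margin1, margin2) {
  gh <- gh_nodes()
  x <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  g1 <- qtrunc_normal(pnorm(x), margin1)
  g2fun <- function(z) qtrunc_normal(pnorm(z), margin2)
  g2 <- g2fun(x)
  mu1 <- sum(w * g1); mu2 <- sum(w * g2)
  s1 <- sqrt(sum(w * (g1 - mu1)^2)); s2 <- sqrt(sum(w * (g2 - mu2)^2))
  E <- 0
  for (i in seq_along(x)) {
    z2 <- rho * x[i] + sqrt(1 - rho^2) * x
    E <- E + w[i] * sum(w * g1[i] * g2fun(z2))
  }
  (E - mu1 * mu2) / (s1 * s2)
}

# Latent copula correlation producing a target Pearson r after the margin maps.
latent_rho <- function(target_r, margin1, margin2) {
  if (target_r == 0) return(0)
  lo <- max(-0.995, target_r - 0.25)
  hi <- min(0.995, target_r + 0.25)
  uniroot(function(r) realized_pearson(r, margin1, margin2) - target_r,
          c(lo, hi), tol = 1e-9)$root
}
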