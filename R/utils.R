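## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded package functions do
#' not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample from a truncated normal by inverse-CDF
#'
#' @param n number of draws.
#' @param mean,sd parameters of the parent normal (sd = 0 collapses to a
#'   point mass at \code{mean}, which must lie inside the support).
#' @param lower,upper truncation bounds.
#' @return numeric vector of length \code{n}, all within \code{[lower, upper]}.
#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper)
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside support", call. = FALSE)
    return(rep(mean, n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  x <- qnorm(u, mean, sd)
  # inverse CDF can round onto a bound in extreme tails; clamp to support
  pmin(pmax(x, lower), upper)
}

## A truncated-Gaussian component spec used throughout EnsembleConfig.
truncSpec <- function(mean, sd, lower, upper) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, lower < upper)
  c(mean = mean, sd = sd, lower = lower, upper = upper)
}

rtruncSpec <- function(n, spec) {
  rtruncnorm(n, spec[["mean"]], spec[["sd"]], spec[["lower"]], spec[["upper"]])
}
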