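## Variable-slope dose-response (Hill) simulation and fitting, used purely
## as parameter recovery on synthetic activation data.

#' Hill (four-parameter logistic) parameters
#'
#' @param bottom,top baseline and plateau activity (top > bottom).
#' @param ec50 half-maximal concentration (> 0; units carried by the data).
#' @param hillN dimensionless slope (> 0 for activation; the fitted value
#'   may be negative for inhibition curves, see [fitHill()]).
#' @return object of class \code{"HillParameters"}.
#' @export
hillParameters <- function(bottom = 0, top = 1, ec50 = 100, hillN = 2) {
  stopifnot(top > bottom, ec50 > 0)
  structure(list(bottom = bottom, top = top, ec50 = ec50, hillN = hillN),
            class = "HillParameters")
}

#' Variable-slope dose-response curve
#'
#' \deqn{y(c) = bottom + (top - bottom) / (1 + (ec50/c)^{hillN})}
#'
#' @param conc concentrations (> 0).
#' @param params a [hillParameters()].
#' @return predicted responses.
#' @examples
#' hillResponse(100, hillParameters(ec50 = 100))  # the midpoint, 0.5
#' @export
hillResponse <- function(conc, params) {
  stopifnot(inherits(params, "HillParameters"), all(conc > 0))
  params$bottom + (params$top - params$bottom) /
    (1 + (params$ec50 / conc)^params$hillN)
}

#' Simulate a dose-response experiment
#'
#' Responses follow the variable-slope Hill curve with multiplicative
#' Gaussian noise of the stated coefficient of variation.
#'
#' @param params a [hillParameters()].
#' @param doses concentrations (log-spaced recommended).
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param nReplicates replicates per dose.
#' @param seed RNG seed.
#' @return data.frame with \code{concentration}, \code{response},
#'   \code{replicate}.
#' @export
simulateDoseResponse <- function(params, doses, noiseCv = 0.05,
                                 nReplicates = 1L, seed = 1L) {
  stopifnot(inherits(params, "HillParameters"), all(doses > 0), noiseCv >= 0)
  mu <- hillResponse(doses, params)
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_len(nReplicates), function(r) {
      data.frame(concentration = doses,
                 response = mu * (1 + rnorm(length(mu), 0, noiseCv)),
                 replicate = r)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Fit a variable-slope dose-response curve
#'
#' Least-squares fit of the four-parameter logistic in log10 dose,
#' \deqn{y = bottom + (top - bottom) / (1 + 10^{hillN (\log_{10} ec50 -
#' \log_{10} c)}),} by Levenberg-Marquardt. Parameter standard errors come
#' from the fit covariance; the EC50 standard error is delta-method
#' propagated from the fitted log10 EC50. A fitted \code{hillN < 0}
#' corresponds to a monotone-decreasing (inhibition) curve; the same form
#' fits both directions.
#'
#' @param data data.frame with \code{concentration} and \code{response}
#'   (e.g. from [simulateDoseResponse()]), or a vector of concentrations.
#' @param response responses, when \code{data} is a vector.
#' @return object of class \code{"HillFit"}: list with \code{params}
#'   (a [hillParameters()]-style list), \code{se} (named standard errors
#'   including \code{ec50} and \code{logEc50}), \code{fit} (the underlying
#'   \code{nls} object) and \code{flat} (TRUE when the data carry no
#'   identifiable transition).
#' @examples
#' d <- simulateDoseResponse(hillParameters(ec50 = 100, hillN = 2),
#'                           10^seq(0, 4, length.out = 8), noiseCv = 0)
#' fitHill(d)
#' @export
fitHill <- function(data, response = NULL) {
  if (is.numeric(data)) data <- data.frame(concentration = data,
                                           response = response)
  stopifnot(all(c("concentration", "response") %in% names(data)),
            all(data$concentration > 0))
  if (length(unique(data$concentration)) < 5L)
    stop("need at least 5 distinct doses spanning the transition",
         call. = FALSE)
  lx <- log10(data$concentration)
  y <- data$response
  if (sd(y) < 1e-12 * max(abs(y), 1))
    return(structure(list(params = NULL, se = NULL, fit = NULL, flat = TRUE),
                     class = "HillFit"))
  start <- list(bottom = min(y), top = max(y),
                logEc50 = stats::weighted.mean(lx, w = abs(diff(c(y[1], y)))),
                hillN = if (stats::cor(lx, y) >= 0) 1 else -1)
  if (!is.finite(start$logEc50)) start$logEc50 <- stats::median(lx)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hillN * (logEc50 - lx))),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("dose-response fit failed: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  ec50 <- 10^cf[["logEc50"]]
  seEc50 <- log(10) * ec50 * se[["logEc50"]]
  structure(list(
    params = list(bottom = cf[["bottom"]], top = cf[["top"]],
                  ec50 = ec50, hillN = cf[["hillN"]]),
    se = c(bottom = unname(se["bottom"]), top = unname(se["top"]),
           logEc50 = unname(se["logEc50"]), ec50 = unname(seEc50),
           hillN = unname(se["hillN"])),
    fit = fit, flat = FALSE), class = "HillFit")
}

#' @export
print.HillFit <- function(x, ...) {
  if (x$flat) { cat("HillFit: flat data, unidentifiable\n"); return(invisible(x)) }
  p <- x$params
  cat(sprintf("HillFit: bottom %.4g  top %.4g  EC50 %.4g (se %.2g)  Hill n %.3g (se %.2g)\n",
              p$bottom, p$top, p$ec50, x$se[["ec50"]], p$hillN, x$se[["hillN"]]))
  invisible(x)
}

#' EC50 fold change and Hill-coefficient difference between two fits
#'
#' Reports \code{ec50_b / ec50_a} and \code{hillN_b - hillN_a} with
#' delta-method standard errors (the ratio's from the fitted log10 EC50s,
#' the difference's by quadrature).
#'
#' @param fitA,fitB converged [fitHill()] results (condition A vs B).
#' @return list with \code{ec50Ratio}, \code{ec50RatioSe},
#'   \code{hillDiff}, \code{hillDiffSe}.
#' @export
foldChange <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "HillFit"), inherits(fitB, "HillFit"),
            !fitA$flat, !fitB$flat)
  ratio <- fitB$params$ec50 / fitA$params$ec50
  seLog <- sqrt(fitA$se[["logEc50"]]^2 + fitB$se[["logEc50"]]^2)
  list(ec50Ratio = ratio,
       ec50RatioSe = log(10) * ratio * seLog,
       hillDiff = fitB$params$hillN - fitA$params$hillN,
       hillDiffSe = sqrt(fitA$se[["hillN"]]^2 + fitB$se[["hillN"]]^2))
}
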