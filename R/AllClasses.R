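#' @import methods
NULL

## ---------------------------------------------------------------------------
## EnsembleConfig
## ---------------------------------------------------------------------------

#' EnsembleConfig: parameters of the synthetic holoenzyme ensemble
#'
#' Holds every parameter of the calibrated conformational-ensemble generator:
#' oligomer probabilities, the truncated-Gaussian radius and separation
#' mixtures, the categorical distribution of kinase-domain pair counts, and
#' the RNG seed. Truncated-Gaussian components are stored as named numeric
#' vectors \code{c(mean, sd, lower, upper)} (all lengths in Angstrom).
#'
#' The defaults are calibrated so that a large generated ensemble reproduces
#' the published single-particle statistics for the basal CaMKII-alpha
#' holoenzyme: kinase radii with mean ~127 A (s.d. ~16 A) on support
#' 77–175 A, neighbour separations with mean ~58 A (s.d. ~15 A), ~20% of
#' separations below the 45 A steric-contact threshold, <3% of radii below
#' the 100 A compact threshold, and <4% tetradecamers.
#'
#' @slot nParticles number of holoenzyme particles to generate.
#' @slot seed integer RNG seed; the generator is fully reproducible.
#' @slot mode \code{"separation_explicit"} (samples measured quantities
#'   directly) or \code{"angular"} (realises 2D coordinates with ring
#'   closure).
#' @slot pTetradecamer probability that a particle is a 14-mer.
#' @slot hubRadius rigid hub-complex radius (A).
#' @slot kinaseRadius average kinase-domain radius (A); the kinase diameter
#'   is twice this value.
#' @slot pCompact per-subunit probability of the compact (hub-docked) radius
#'   component.
#' @slot radiusExtended,radiusCompact truncated-Gaussian specs for the
#'   extended and compact radius components.
#' @slot pairCountProbs categorical probabilities over 0..6 kinase-domain
#'   pairs per 12-mer (14-mers reuse it, with zero mass on 7 pairs).
#' @slot sepPaired,sepUnpaired truncated-Gaussian specs for the paired
#'   (<45 A) and unpaired (>=45 A) separation components.
#' @slot angularPairedGap \code{c(mean, sd)} in degrees for the angular gap
#'   across a paired edge (angular mode only).
#' @slot angularUnpairedSd s.d. in degrees of the jitter applied to unpaired
#'   angular gaps before renormalisation (angular mode only).
#'
#' @seealso [ensembleConfig()] for the user-facing constructor,
#'   [generateEnsemble()].
#' @export
setClass("EnsembleConfig", representation(
  nParticles = "integer",
  seed = "integer",
  mode = "character",
  pTetradecamer = "numeric",
  hubRadius = "numeric",
  kinaseRadius = "numeric",
  pCompact = "numeric",
  radiusExtended = "numeric",
  radiusCompact = "numeric",
  pairCountProbs = "numeric",
  sepPaired = "numeric",
  sepUnpaired = "numeric",
  angularPairedGap = "numeric",
  angularUnpairedSd = "numeric"
))

validEnsembleConfig <- function(object) {
  msg <- character()
  if (object@nParticles < 1L)
    msg <- c(msg, "nParticles must be a positive integer")
  if (!object@mode %in% c("separation_explicit", "angular"))
    msg <- c(msg, "mode must be 'separation_explicit' or 'angular'")
  if (object@pTetradecamer < 0 || object@pTetradecamer > 1)
    msg <- c(msg, "pTetradecamer must lie in [0,1]")
  if (object@pCompact < 0 || object@pCompact > 1)
    msg <- c(msg, "pCompact must lie in [0,1]")
  p <- object@pairCountProbs
  if (length(p) != 7L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "pairCountProbs must be 7 non-negative values summing to 1")
  for (nm in c("radiusExtended", "radiusCompact", "sepPaired", "sepUnpaired")) {
    s <- slot(object, nm)
    if (length(s) != 4L || s[["sd"]] < 0 || s[["lower"]] >= s[["upper"]])
      msg <- c(msg, sprintf("%s must be c(mean, sd, lower, upper) with lower < upper", nm))
  }
  # compact radius support entirely below extended support
  if (object@radiusCompact[["upper"]] > object@radiusExtended[["lower"]])
    msg <- c(msg, "compact radius support must lie entirely below extended support")
  # paired separations strictly below, unpaired at/above, the 45 A threshold,
  # so threshold classification recovers pair labels exactly
  thr <- 2 * object@kinaseRadius
  if (object@sepPaired[["upper"]] > thr)
    msg <- c(msg, "sepPaired support must lie strictly below the pairing threshold")
  if (object@sepUnpaired[["lower"]] < thr)
    msg <- c(msg, "sepUnpaired support must lie at or above the pairing threshold")
  # extended kinase domains must clear the hub
  if (object@hubRadius + 2 * object@kinaseRadius > object@radiusExtended[["lower"]])
    msg <- c(msg, "hubRadius + kinase diameter must not exceed the extended radius lower bound")
  if (length(msg)) msg else TRUE
}
setValidity("EnsembleConfig", validEnsembleConfig)

#' Construct an ensemble generator configuration
#'
#' All arguments default to the calibrated basal-state values; see
#' \linkS4class{EnsembleConfig} for their meaning. Lengths are in Angstrom,
#' angles in degrees.
#'
#' @param nParticles number of particles to generate.
#' @param seed integer RNG seed.
#' @param mode \code{"separation_explicit"} or \code{"angular"}.
#' @param pTetradecamer 14-mer probability.
#' @param hubRadius hub-complex radius (A).
#' @param kinaseRadius kinase-domain radius (A).
#' @param pCompact per-subunit compact-component probability.
#' @param radiusExtended,radiusCompact,sepPaired,sepUnpaired truncated
#'   Gaussian component specs \code{c(mean, sd, lower, upper)}.
#' @param pairCountProbs categorical over 0..6 pairs per particle.
#' @param angularPairedGap \code{c(mean, sd)} degrees (angular mode).
#' @param angularUnpairedSd jitter s.d. (degrees) for unpaired gaps.
#' @return A validated \linkS4class{EnsembleConfig}.
#' @examples
#' cfg <- ensembleConfig(nParticles = 10, seed = 1)
#' cfg
#' @export
ensembleConfig <- function(nParticles = 1000L,
                           seed = 42L,
                           mode = c("separation_explicit", "angular"),
                           pTetradecamer = 0.035,
                           hubRadius = 55,
                           kinaseRadius = 22.5,
                           pCompact = 0.025,
                           radiusExtended = c(mean = 127, sd = 15, lower = 100, upper = 175),
                           radiusCompact = c(mean = 88, sd = 5, lower = 77, upper = 100),
                           pairCountProbs = c(0.10, 0.25, 0.20, 0.15, 0.165, 0.11, 0.025),
                           sepPaired = c(mean = 36, sd = 5, lower = 20, upper = 45),
                           sepUnpaired = c(mean = 62.5, sd = 11, lower = 45, upper = 110),
                           angularPairedGap = c(mean = 19.5, sd = 2.5),
                           angularUnpairedSd = 6) {
  mode <- match.arg(mode)
  if (!is.numeric(nParticles) || length(nParticles) != 1L || nParticles < 1)
    stop("'nParticles' must be a positive integer", call. = FALSE)
  new("EnsembleConfig",
      nParticles = as.integer(nParticles), seed = as.integer(seed),
      mode = mode, pTetradecamer = pTetradecamer, hubRadius = hubRadius,
      kinaseRadius = kinaseRadius, pCompact = pCompact,
      radiusExtended = radiusExtended, radiusCompact = radiusCompact,
      pairCountProbs = pairCountProbs, sepPaired = sepPaired,
      sepUnpaired = sepUnpaired, angularPairedGap = angularPairedGap,
      angularUnpairedSd = angularUnpairedSd)
}

setMethod("show", "EnsembleConfig", function(object) {
  cat("EnsembleConfig\n")
  cat("  particles:", object@nParticles, " seed:", object@seed,
      " mode:", object@mode, "\n")
  cat(sprintf("  hub %g A | kinase radius %g A | P(14-mer) %.3f | P(compact) %.3f\n",
              object@hubRadius, object@kinaseRadius,
              object@pTetradecamer, object@pCompact))
  cat(sprintf("  radius: extended N(%g, %g) on [%g, %g); compact N(%g, %g) on [%g, %g)\n",
              object@radiusExtended[["mean"]], object@radiusExtended[["sd"]],
              object@radiusExtended[["lower"]], object@radiusExtended[["upper"]],
              object@radiusCompact[["mean"]], object@radiusCompact[["sd"]],
              object@radiusCompact[["lower"]], object@radiusCompact[["upper"]]))
  cat("  pair-count probs (0..6):",
      paste(format(object@pairCountProbs), collapse = " "), "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## HoloEnsemble
## ---------------------------------------------------------------------------

#' HoloEnsemble: a generated collection of holoenzyme particles
#'
#' One row per kinase subunit, in a long-format table with columns
#' \code{particle_id}, \code{subunit_index}, \code{n_subunits},
#' \code{radius_A} (kinase radius of extension, to the outer edge),
#' \code{separation_A} (clockwise centre-to-centre neighbour distance),
#' \code{paired} (0/1: subunit's clockwise edge is a generated dimer pair)
#' and \code{compact} (0/1: radius below 100 A). Angular-mode ensembles
#' additionally carry per-subunit kinase-centre coordinates \code{x_A},
#' \code{y_A} (hub centre at origin, image convention with y down).
#'
#' @slot subunits long-format \code{data.frame}, one row per subunit.
#' @slot config the \linkS4class{EnsembleConfig} that generated it.
#' @seealso [generateEnsemble()], [particleTable()], [nParticles()]
#' @export
setClass("HoloEnsemble", representation(
  subunits = "data.frame",
  config = "EnsembleConfig"
))

validHoloEnsemble <- function(object) {
  msg <- character()
  need <- c("particle_id", "subunit_index", "n_subunits",
            "radius_A", "separation_A", "paired", "compact")
  if (!all(need %in% names(object@subunits)))
    msg <- c(msg, paste("subunits must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    tab <- table(object@subunits$particle_id)
    nsub <- tapply(object@subunits$n_subunits, object@subunits$particle_id,
                   function(x) x[1])
    if (!all(tab == nsub[names(tab)]))
      msg <- c(msg, "each particle must have exactly n_subunits rows")
    if (!all(object@subunits$n_subunits %in% c(12L, 14L)))
      msg <- c(msg, "n_subunits must be 12 or 14")
    if (any(object@subunits$radius_A <= 0) || any(object@subunits$separation_A <= 0))
      msg <- c(msg, "radii and separations must be positive")
  }
  if (length(msg)) msg else TRUE
}
setValidity("HoloEnsemble", validHoloEnsemble)

#' @rdname nParticles
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' Number of particles in an ensemble
#'
#' @param x a \linkS4class{HoloEnsemble}.
#' @return integer particle count.
#' @export
setMethod("nParticles", "HoloEnsemble", function(x) {
  length(unique(x@subunits$particle_id))
})

#' @rdname particleTable
#' @export
setGeneric("particleTable", function(x) standardGeneric("particleTable"))

#' Long-format subunit table of an ensemble
#'
#' @param x a \linkS4class{HoloEnsemble}.
#' @return \code{data.frame} with one row per kinase subunit.
#' @export
setMethod("particleTable", "HoloEnsemble", function(x) x@subunits)

#' @rdname ensembleConfigOf
#' @export
setGeneric("ensembleConfigOf", function(x) standardGeneric("ensembleConfigOf"))

#' Configuration that generated an ensemble
#'
#' @param x a \linkS4class{HoloEnsemble}.
#' @return the \linkS4class{EnsembleConfig}.
#' @export
setMethod("ensembleConfigOf", "HoloEnsemble", function(x) x@config)

setMethod("show", "HoloEnsemble", function(object) {
  tab <- object@subunits
  n <- length(unique(tab$particle_id))
  n14 <- sum(tapply(tab$n_subunits, tab$particle_id, function(x) x[1]) == 14L)
  cat("HoloEnsemble:", n, "particles (", nrow(tab), "subunits;",
      n14, "tetradecamers )\n")
  cat(sprintf("  mode: %s | radius mean %.1f A | separation mean %.1f A | paired %.1f%%\n",
              object@config@mode, mean(tab$radius_A), mean(tab$separation_A),
              100 * mean(tab$paired)))
  invisible(NULL)
})

#' Extract one particle from an ensemble
#'
#' @param x a \linkS4class{HoloEnsemble}.
#' @param id particle id.
#' @return list with elements \code{particle_id}, \code{n_subunits},
#'   \code{radii}, \code{separations}, \code{paired}, \code{compact} and,
#'   in angular mode, \code{coords} (n x 2 matrix, A).
#' @export
getParticle <- function(x, id) {
  stopifnot(is(x, "HoloEnsemble"))
  rows <- x@subunits[x@subunits$particle_id == id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no particle with id ", id, call. = FALSE)
  rows <- rows[order(rows$subunit_index), , drop = FALSE]
  out <- list(particle_id = id, n_subunits = rows$n_subunits[1],
              radii = rows$radius_A, separations = rows$separation_A,
              paired = as.logical(rows$paired),
              compact = as.logical(rows$compact))
  if (all(c("x_A", "y_A") %in% names(rows)))
    out$coords <- cbind(x = rows$x_A, y = rows$y_A)
  out
}
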