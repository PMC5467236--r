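## Synthetic holoenzyme conformational-ensemble generator.
##
## Two modes: "separation_explicit" samples the measured quantities (radii,
## clockwise separations) directly from calibrated truncated-Gaussian
## mixtures; "angular" realises full 2D kinase-centre coordinates with ring
## closure, from which separations are recomputed geometrically.

## Enumeration cache of k-matchings on the n-cycle (keyed "n:k").
.matchingCache <- new.env(parent = emptyenv())

#' Enumerate all matchings of a given size on a cycle graph
#'
#' The cycle \eqn{C_n} has vertices \code{1..n} and edges
#' \code{(i, i mod n + 1)}. A matching of size k is a set of k edges sharing
#' no vertex. For the holoenzyme ring sizes used here (n = 12 or 14) the
#' counts are small, so uniform sampling is done by explicit enumeration.
#'
#' @param n number of vertices (ring subunits).
#' @param k matching size (number of kinase-domain pairs).
#' @return list of integer vectors; each vector holds the edge indices
#'   \code{i} of the matching (edge \code{i} joins subunits \code{i} and
#'   \code{i mod n + 1}).
#' @examples
#' length(enumerateCycleMatchings(12, 6))  # the two alternating matchings
#' @export
enumerateCycleMatchings <- function(n, k) {
  stopifnot(n >= 3, k >= 0, k <= n %/% 2)
  key <- paste(n, k, sep = ":")
  if (!is.null(.matchingCache[[key]])) return(.matchingCache[[key]])
  if (k == 0L) {
    res <- list(integer(0))
  } else {
    combs <- utils::combn(n, k, simplify = FALSE)
    ok <- vapply(combs, function(e) {
      v <- c(e, e %% n + 1L)  # both endpoints of every chosen edge
      !anyDuplicated(v)
    }, logical(1))
    res <- combs[ok]
  }
  .matchingCache[[key]] <- res
  res
}

#' Sample a kinase-domain pair assignment for one particle
#'
#' Draws the number of pairs k from a categorical distribution over 0..6
#' (14-mers reuse the same categorical; a 7th pair is never generated), then
#' samples uniformly among all matchings of size k on the n-cycle, so every
#' admissible disjoint-pair arrangement of that size is equally likely.
#'
#' @param nSubunits 12 or 14.
#' @param probs categorical probabilities over pair counts 0..6.
#' @return integer matrix with columns \code{i}, \code{j}: each row one pair
#'   edge joining clockwise neighbours (j = i mod n + 1). Zero rows when no
#'   pairs are drawn. Uses the current RNG stream.
#' @examples
#' set.seed(1)
#' samplePairAssignment(12, c(0, 0, 1, 0, 0, 0, 0))  # always two pairs
#' @export
samplePairAssignment <- function(nSubunits, probs) {
  if (!nSubunits %in% c(12L, 14L))
    stop("nSubunits must be 12 or 14", call. = FALSE)
  if (length(probs) != 7L || any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("invalid pair-count categorical: need 7 non-negative probabilities summing to 1",
         call. = FALSE)
  k <- sample.int(7L, 1L, prob = probs) - 1L
  matchings <- enumerateCycleMatchings(nSubunits, k)
  edges <- matchings[[sample.int(length(matchings), 1L)]]
  cbind(i = edges, j = edges %% nSubunits + 1L)
}

#' Sample kinase radii of extension from the calibrated mixture
#'
#' Each radius is drawn from the compact truncated-Gaussian component with
#' probability \code{pCompact} and otherwise from the extended component.
#' Component supports are disjoint at the 100 A compact threshold, so the
#' compact flag equals component membership by construction.
#'
#' @param n number of subunit radii to draw.
#' @param cfg an \linkS4class{EnsembleConfig}.
#' @return list with \code{radii} (numeric, A) and \code{compact} (logical).
#' @export
sampleRadii <- function(n, cfg) {
  stopifnot(is(cfg, "EnsembleConfig"), n >= 0)
  compact <- runif(n) < cfg@pCompact
  radii <- numeric(n)
  if (any(compact))
    radii[compact] <- rtruncSpec(sum(compact), cfg@radiusCompact)
  if (any(!compact))
    radii[!compact] <- rtruncSpec(sum(!compact), cfg@radiusExtended)
  list(radii = radii, compact = compact)
}

#' Sample clockwise neighbour separations (separation-explicit mode)
#'
#' Separation i (between subunits i and i+1) is drawn from the paired
#' component when edge (i, i+1) is a generated dimer pair and from the
#' unpaired component otherwise. Component supports split exactly at the
#' 45 A pairing threshold, so threshold classification recovers the
#' generated pair labels with zero error.
#'
#' @param pairEdges integer matrix as returned by [samplePairAssignment()].
#' @param nSubunits ring size (12 or 14).
#' @param cfg an \linkS4class{EnsembleConfig}; must be in
#'   \code{"separation_explicit"} mode (in angular mode separations are
#'   computed from coordinates, not sampled).
#' @return numeric vector of \code{nSubunits} separations (A).
#' @export
sampleSeparations <- function(pairEdges, nSubunits, cfg) {
  stopifnot(is(cfg, "EnsembleConfig"))
  if (cfg@mode != "separation_explicit")
    stop("sampleSeparations applies only in separation_explicit mode; ",
         "angular-mode separations are computed from coordinates",
         call. = FALSE)
  paired <- logical(nSubunits)
  paired[pairEdges[, "i"]] <- TRUE
  sep <- numeric(nSubunits)
  if (any(paired)) sep[paired] <- rtruncSpec(sum(paired), cfg@sepPaired)
  if (any(!paired)) sep[!paired] <- rtruncSpec(sum(!paired), cfg@sepUnpaired)
  # paired support is [lower, 45): clamp any draw that rounds onto the bound
  sep[paired] <- pmin(sep[paired], cfg@sepPaired[["upper"]] - 1e-9)
  sep
}

#' Realise 2D kinase-centre coordinates for one particle (angular mode)
#'
#' Angular gaps across paired edges are drawn from the paired-gap spec;
#' unpaired gaps are drawn around the equal share of the residual angle and
#' rescaled so all gaps sum to exactly 360 degrees. Kinase centre i is
#' placed at polar radius \code{radii[i] - kinaseRadius} (the measured
#' radius refers to the domain's outer edge) and at the accumulated angle;
#' neighbour order i -> i+1 proceeds clockwise (decreasing mathematical
#' angle). Separations are recomputed from the coordinates by the law of
#' cosines.
#'
#' @param radii per-subunit kinase radii of extension (A).
#' @param pairEdges matrix from [samplePairAssignment()].
#' @param cfg an \linkS4class{EnsembleConfig}.
#' @param maxRetries resample attempts when rescaling yields a non-positive
#'   gap.
#' @return list with \code{coords} (n x 2 matrix, A, hub centre at origin),
#'   \code{separations} (A) and \code{gaps} (degrees, summing to 360).
#' @export
realizeCoordinates <- function(radii, pairEdges, cfg, maxRetries = 100L) {
  stopifnot(is(cfg, "EnsembleConfig"))
  n <- length(radii)
  paired <- logical(n)
  paired[pairEdges[, "i"]] <- TRUE
  k <- sum(paired)
  gm <- cfg@angularPairedGap[["mean"]]
  gs <- cfg@angularPairedGap[["sd"]]
  for (try in seq_len(maxRetries)) {
    gaps <- numeric(n)
    gaps[paired] <- rnorm(k, gm, gs)
    residual <- 360 - sum(gaps[paired])
    m <- n - k
    if (m > 0L && residual > 0) {
      raw <- rnorm(m, residual / m, cfg@angularUnpairedSd)
      gaps[!paired] <- raw * residual / sum(raw)
    } else if (m == 0L) {
      gaps <- gaps * 360 / sum(gaps)
    }
    if (all(gaps > 0)) {
      theta0 <- runif(1, 0, 360)
      # clockwise: accumulate with decreasing mathematical angle
      theta <- (theta0 - cumsum(c(0, gaps[-n]))) * pi / 180
      rho <- radii - cfg@kinaseRadius
      coords <- cbind(x = rho * cos(theta), y = rho * sin(theta))
      nxt <- c(2:n, 1L)
      gapRad <- gaps * pi / 180
      sep <- sqrt(rho^2 + rho[nxt]^2 - 2 * rho * rho[nxt] * cos(gapRad))
      return(list(coords = coords, separations = sep, gaps = gaps))
    }
  }
  stop("could not realise positive angular gaps after ", maxRetries,
       " attempts", call. = FALSE)
}

#' Generate a synthetic holoenzyme ensemble
#'
#' Draws \code{nParticles} holoenzymes under the configuration: per-particle
#' oligomer state (12-mer vs 14-mer, Bernoulli), a uniformly sampled
#' disjoint pair arrangement of categorical size, per-subunit radii from the
#' extended/compact mixture, and separations either sampled directly
#' (separation-explicit mode) or computed from realised ring coordinates
#' (angular mode). Fully reproducible for a fixed config (seed included).
#'
#' @param cfg an \linkS4class{EnsembleConfig}.
#' @return a \linkS4class{HoloEnsemble}.
#' @examples
#' ens <- generateEnsemble(ensembleConfig(nParticles = 50, seed = 1))
#' ens
#' head(particleTable(ens))
#' @export
generateEnsemble <- function(cfg) {
  stopifnot(is(cfg, "EnsembleConfig"))
  validObject(cfg)
  withSeed(cfg@seed, {
    nP <- cfg@nParticles
    angular <- cfg@mode == "angular"
    parts <- vector("list", nP)
    for (p in seq_len(nP)) {
      n <- if (runif(1) < cfg@pTetradecamer) 14L else 12L
      edges <- samplePairAssignment(n, cfg@pairCountProbs)
      rad <- sampleRadii(n, cfg)
      paired <- logical(n)
      paired[edges[, "i"]] <- TRUE
      if (angular) {
        geo <- realizeCoordinates(rad$radii, edges, cfg)
        sep <- geo$separations
        xy <- geo$coords
      } else {
        sep <- sampleSeparations(edges, n, cfg)
        xy <- NULL
      }
      df <- data.frame(
        particle_id = p, subunit_index = seq_len(n), n_subunits = n,
        radius_A = rad$radii, separation_A = sep,
        paired = as.integer(paired), compact = as.integer(rad$compact))
      if (angular) { df$x_A <- xy[, "x"]; df$y_A <- xy[, "y"] }
      parts[[p]] <- df
    }
    new("HoloEnsemble",
        subunits = do.call(rbind, parts), config = cfg)
  })
}
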