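## Single-particle measurement rules: kinase radius of extension and
## clockwise centre-to-centre neighbour separation.

#' Geometry constants of the holoenzyme measurement scheme
#'
#' The measured kinase radius appends the average kinase-domain radius
#' (22.5 A) to the hub-centre-to-density-centre distance, so that the value
#' represents the full extension of the domain. The kinase diameter (45 A)
#' doubles as the steric-contact pairing threshold on neighbour separations,
#' and 100 A (hub radius + kinase diameter) is the compact-conformation
#' threshold on radii.
#'
#' @param kinaseRadiusAppend appended kinase radius (A).
#' @param hubRadius hub-complex radius (A).
#' @param pairingThreshold centre-to-centre separation below which two
#'   neighbouring kinase domains are classified as a dimer pair (A).
#' @param compactThreshold kinase radius below which a subunit is classified
#'   as compact (A).
#' @return object of class \code{"GeometryConstants"} (a validated list,
#'   with derived \code{kinaseDiameter}).
#' @examples
#' geometryConstants()
#' @export
geometryConstants <- function(kinaseRadiusAppend = 22.5,
                              hubRadius = 55,
                              pairingThreshold = 45,
                              compactThreshold = 100) {
  stopifnot(kinaseRadiusAppend > 0, hubRadius > 0,
            pairingThreshold > 0, compactThreshold > 0)
  kinaseDiameter <- 2 * kinaseRadiusAppend
  if (abs(pairingThreshold - kinaseDiameter) > 1e-9)
    warning("pairingThreshold differs from the kinase diameter; ",
            "the steric-contact rationale assumes they are equal")
  structure(list(kinaseRadiusAppend = kinaseRadiusAppend,
                 hubRadius = hubRadius,
                 kinaseDiameter = kinaseDiameter,
                 pairingThreshold = pairingThreshold,
                 compactThreshold = compactThreshold),
            class = "GeometryConstants")
}

#' @export
print.GeometryConstants <- function(x, ...) {
  cat("GeometryConstants (A): kinase radius append", x$kinaseRadiusAppend,
      "| hub", x$hubRadius, "| pairing <", x$pairingThreshold,
      "| compact <", x$compactThreshold, "\n")
  invisible(x)
}

#' Kinase radius of extension
#'
#' Euclidean distance from the hub centre to the kinase-domain centre, plus
#' the appended average kinase radius (22.5 A), yielding the full extension
#' of the domain (to its outer edge).
#'
#' @param hubCentre,kinaseCentre 2D points (A); \code{kinaseCentre} may be
#'   an n x 2 matrix.
#' @param consts a [geometryConstants()] object.
#' @return radius (or vector of radii) of extension in A.
#' @examples
#' kinaseRadius(c(0, 0), c(104.5, 0))  # 127 A
#' @export
kinaseRadius <- function(hubCentre, kinaseCentre, consts = geometryConstants()) {
  stopifnot(all(is.finite(hubCentre)), all(is.finite(kinaseCentre)))
  kc <- if (is.matrix(kinaseCentre)) kinaseCentre else matrix(kinaseCentre, ncol = 2)
  d <- sqrt((kc[, 1] - hubCentre[1])^2 + (kc[, 2] - hubCentre[2])^2)
  if (any(d < .Machine$double.eps^0.5))
    stop("degenerate particle: kinase centre coincides with hub centre",
         call. = FALSE)
  unname(d + consts$kinaseRadiusAppend)
}

#' Clockwise centre-to-centre neighbour separations
#'
#' Orders the kinase-domain centres around their centroid and returns, for
#' each domain, the distance to its neighbour in the clockwise direction;
#' the ring closes, so exactly n separations are returned for n domains.
#' Coordinates follow image convention (y increasing downward); clockwise
#' on screen therefore corresponds to decreasing mathematical polar angle,
#' which is the ordering used. Angular ties are broken by radius (smaller
#' first).
#'
#' @param coords n x 2 matrix of kinase-centre coordinates (A), n >= 3.
#' @return numeric vector of n separations (A), in the clockwise order of
#'   the sorted domains; attribute \code{"order"} gives the row order used.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' ring <- cbind(104.5 * cos(th), 104.5 * sin(th))
#' clockwiseSeparations(ring)  # twelve equal chords, 2*104.5*sin(pi/12)
#' @export
clockwiseSeparations <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) stop("need at least 3 points", call. = FALSE)
  if (anyDuplicated(coords))
    stop("duplicate kinase positions: separations undefined", call. = FALSE)
  ctr <- colMeans(coords)
  dx <- coords[, 1] - ctr[1]
  dy <- coords[, 2] - ctr[2]
  ang <- atan2(dy, dx)
  rad <- sqrt(dx^2 + dy^2)
  ord <- order(-ang, rad)  # decreasing mathematical angle = clockwise
  pts <- coords[ord, , drop = FALSE]
  nxt <- c(2:nrow(pts), 1L)
  sep <- sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2))
  structure(sep, order = ord)
}

#' Measure one particle
#'
#' Applies the measurement rules to a single particle. Coordinate input (a
#' matrix, or a particle list carrying \code{coords}) yields radii via
#' [kinaseRadius()] and separations via [clockwiseSeparations()];
#' separation-explicit particle records pass through unchanged, so both
#' paths produce the same output format.
#'
#' @param x an n x 2 coordinate matrix, or a particle list as returned by
#'   [getParticle()].
#' @param consts a [geometryConstants()] object.
#' @param hubCentre hub-centre position used with coordinate input (A);
#'   defaults to the generated origin.
#' @return list with \code{radii}, \code{separations}, \code{n_subunits}.
#' @export
measureParticle <- function(x, consts = geometryConstants(),
                            hubCentre = c(0, 0)) {
  if (is.matrix(x) || is.data.frame(x)) {
    coords <- as.matrix(x)
    sep <- clockwiseSeparations(coords)
    ord <- attr(sep, "order")
    radii <- kinaseRadius(hubCentre, coords[ord, , drop = FALSE], consts)
    return(list(radii = radii, separations = as.numeric(sep),
                n_subunits = nrow(coords)))
  }
  if (is.list(x) && !is.null(x$radii) && !is.null(x$separations)) {
    if (!is.null(x$coords)) {
      sep <- clockwiseSeparations(x$coords)
      ord <- attr(sep, "order")
      radii <- kinaseRadius(hubCentre, x$coords[ord, , drop = FALSE], consts)
      return(list(radii = radii, separations = as.numeric(sep),
                  n_subunits = nrow(x$coords)))
    }
    if (length(x$radii) != length(x$separations))
      stop("invalid particle record: radii and separations differ in length",
           call. = FALSE)
    return(list(radii = x$radii, separations = x$separations,
                n_subunits = x$n_subunits))
  }
  stop("cannot measure: supply a coordinate matrix or a particle record",
       call. = FALSE)
}

#' Measure every particle of an ensemble
#'
#' Separation-explicit ensembles pass through unchanged (the generator
#' already holds the measured quantities); angular ensembles are re-measured
#' from their realised coordinates. An optional per-subunit dropout
#' probability emulates densities too poorly resolved to measure (the
#' corresponding rows are removed).
#'
#' @param ensemble a \linkS4class{HoloEnsemble}.
#' @param consts a [geometryConstants()] object.
#' @param dropout per-subunit probability of exclusion (default 0).
#' @param seed RNG seed used only when \code{dropout > 0}.
#' @return \code{data.frame} of per-subunit measurements with columns
#'   \code{particle_id}, \code{subunit_index}, \code{n_subunits},
#'   \code{radius_A}, \code{separation_A}, \code{paired}, \code{compact}.
#' @export
measureEnsemble <- function(ensemble, consts = geometryConstants(),
                            dropout = 0, seed = 1L) {
  stopifnot(is(ensemble, "HoloEnsemble"), dropout >= 0, dropout < 1)
  tab <- ensemble@subunits
  if (ensemble@config@mode == "angular") {
    # re-measure from coordinates, particle by particle
    res <- lapply(split(tab, tab$particle_id), function(rows) {
      rows <- rows[order(rows$subunit_index), , drop = FALSE]
      m <- measureParticle(cbind(rows$x_A, rows$y_A), consts)
      ord <- attr(clockwiseSeparations(cbind(rows$x_A, rows$y_A)), "order")
      data.frame(particle_id = rows$particle_id[1],
                 subunit_index = rows$subunit_index[ord],
                 n_subunits = rows$n_subunits[1],
                 radius_A = m$radii, separation_A = m$separations,
                 paired = rows$paired[ord], compact = rows$compact[ord])
    })
    tab <- do.call(rbind, res)
    rownames(tab) <- NULL
  } else {
    tab <- tab[, c("particle_id", "subunit_index", "n_subunits",
                   "radius_A", "separation_A", "paired", "compact")]
  }
  if (dropout > 0) {
    keep <- withSeed(seed, runif(nrow(tab)) >= dropout)
    tab <- tab[keep, , drop = FALSE]
  }
  tab
}
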