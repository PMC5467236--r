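## 2D particle rendering on the micrograph pixel scale, and hub/kinase-peak
## detection, giving the measurement pipeline an image-level round trip.

#' Rendering configuration
#'
#' Defaults follow the imaging geometry of the negative-stain data the
#' generator emulates: 4.37 A per pixel, 128 x 128 boxes, a 55 A hub with a
#' 12.5 A pore (~25 A diameter), kinase domains as Gaussian blobs.
#'
#' @param pixelSize A per pixel.
#' @param box image side length in pixels.
#' @param hubOuterRadius,hubPoreRadius hub annulus radii (A).
#' @param kinaseBlobSigma Gaussian blob s.d. (A).
#' @param noiseSigma additive Gaussian noise s.d. (relative intensity).
#' @param seed RNG seed for the noise field.
#' @return object of class \code{"RenderConfig"}.
#' @export
renderConfig <- function(pixelSize = 4.37, box = 128L,
                         hubOuterRadius = 55, hubPoreRadius = 12.5,
                         kinaseBlobSigma = 10, noiseSigma = 0.05,
                         seed = 1L) {
  stopifnot(pixelSize > 0, box >= 16, hubPoreRadius < hubOuterRadius,
            kinaseBlobSigma > 0, noiseSigma >= 0)
  structure(list(pixelSize = pixelSize, box = as.integer(box),
                 hubOuterRadius = hubOuterRadius,
                 hubPoreRadius = hubPoreRadius,
                 kinaseBlobSigma = kinaseBlobSigma,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "RenderConfig")
}

## A-coordinate of each pixel centre along one axis (origin at image centre).
.pixelAxis <- function(cfg) (seq_len(cfg$box) - (cfg$box + 1) / 2) * cfg$pixelSize

#' Render one holoenzyme particle as a single-channel image
#'
#' Bright protein on dark background: the hub complex is drawn as an
#' annulus (outer radius 55 A, pore 12.5 A), each kinase domain as an
#' isotropic Gaussian blob at its centre coordinates, plus additive
#' Gaussian noise. Image convention: origin top-left, row-major, y
#' increasing downward (the particle's y axis maps to image rows), hub
#' centre at the image centre. Intensities lie in [0, 1] before noise.
#'
#' @param particle particle list with \code{coords} (n x 2, A; from an
#'   angular-mode ensemble via [getParticle()]), or an n x 2 coordinate
#'   matrix.
#' @param cfg a [renderConfig()].
#' @param hubAmplitude,blobAmplitude intensities of the hub annulus and of
#'   an isolated blob peak.
#' @param seed noise seed; defaults to \code{cfg$seed}.
#' @return \code{box x box} numeric matrix with attribute
#'   \code{"pixelSize"}.
#' @export
renderParticle <- function(particle, cfg = renderConfig(),
                           hubAmplitude = 0.6, blobAmplitude = 0.8,
                           seed = cfg$seed) {
  coords <- if (is.matrix(particle)) particle else particle$coords
  if (is.null(coords))
    stop("particle has no coordinates: render requires an angular-mode particle",
         call. = FALSE)
  halfField <- cfg$box / 2 * cfg$pixelSize
  if (nrow(coords) > 0 &&
      max(sqrt(rowSums(coords^2))) + 3 * cfg$kinaseBlobSigma > halfField)
    stop("particle exceeds the field of view: increase box or pixelSize",
         call. = FALSE)
  ax <- .pixelAxis(cfg)
  X <- matrix(ax, cfg$box, cfg$box, byrow = TRUE)   # x along columns
  Y <- matrix(ax, cfg$box, cfg$box)                 # y down along rows
  rho <- sqrt(X^2 + Y^2)
  img <- hubAmplitude * (rho <= cfg$hubOuterRadius & rho > cfg$hubPoreRadius)
  s2 <- 2 * cfg$kinaseBlobSigma^2
  for (i in seq_len(nrow(coords)))
    img <- img + blobAmplitude *
      exp(-((X - coords[i, 1])^2 + (Y - coords[i, 2])^2) / s2)
  img <- pmin(img, 1)
  if (cfg$noiseSigma > 0)
    img <- img + withSeed(seed,
      matrix(rnorm(length(img), 0, cfg$noiseSigma), nrow(img)))
  attr(img, "pixelSize") <- cfg$pixelSize
  img
}

#' Detect hub centre and kinase-domain peaks in a rendered image
#'
#' The image is Gaussian-smoothed; the hub centre is the intensity-weighted
#' centroid of the central disc; kinase centres are local maxima outside an
#' inner exclusion radius (50 A), refined to sub-pixel position by a local
#' intensity-weighted centroid. Maxima closer than the merge radius
#' collapse to the brighter one (paired domains may fuse at high noise), so
#' fewer peaks than expected yields a flagged partial result rather than an
#' error.
#'
#' @param img matrix from [renderParticle()] (or read back from TIFF).
#' @param cfg the [renderConfig()] used to render it.
#' @param nExpected expected number of kinase domains (NA to skip the
#'   completeness check).
#' @param innerExclusion inner exclusion radius (A) around the hub centre.
#' @param mergeRadius peaks closer than this (A) are merged.
#' @param minPeakIntensity minimum smoothed intensity of an accepted peak.
#' @param smoothSigmaPx smoothing s.d. in pixels.
#' @return list with \code{hubCentre} (A, relative to image centre),
#'   \code{peaks} (n x 2 matrix, A, relative to the hub centre),
#'   \code{nPeaks} and \code{complete} (FALSE when fewer peaks than
#'   expected were found).
#' @export
detectParticle <- function(img, cfg = renderConfig(), nExpected = NA,
                           innerExclusion = 50, mergeRadius = 20,
                           minPeakIntensity = 0.3, smoothSigmaPx = 1.5) {
  img <- unclass(img)
  attr(img, "pixelSize") <- NULL
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                          sigma = smoothSigmaPx))
  ax <- .pixelAxis(cfg)
  X <- matrix(ax, cfg$box, cfg$box, byrow = TRUE)
  Y <- matrix(ax, cfg$box, cfg$box)
  rho <- sqrt(X^2 + Y^2)

  # hub centre: weighted centroid of the central disc (kept clear of the
  # blob ring so peripheral densities do not bias it)
  hubMask <- rho <= max(cfg$hubOuterRadius - 1.5 * cfg$kinaseBlobSigma,
                        cfg$hubPoreRadius + 5)
  w <- pmax(sm, 0) * hubMask
  hubCentre <- if (sum(w) > 0) c(sum(w * X), sum(w * Y)) / sum(w) else c(0, 0)

  # local maxima via greyscale dilation (max filter) over the merge window
  brushSize <- max(3L, 2L * as.integer(ceiling(mergeRadius / cfg$pixelSize / 2)) + 1L)
  mx <- EBImage::imageData(EBImage::dilate(EBImage::Image(sm),
                                           EBImage::makeBrush(brushSize, "disc")))
  dHub <- sqrt((X - hubCentre[1])^2 + (Y - hubCentre[2])^2)
  isPeak <- sm >= mx & sm > minPeakIntensity & dHub > innerExclusion
  idx <- which(isPeak, arr.ind = TRUE)

  peaks <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  if (nrow(idx) > 0) {
    w2 <- 2L  # half-width of the sub-pixel refinement window
    out <- matrix(NA_real_, nrow(idx), 2)
    for (j in seq_len(nrow(idx))) {
      r <- idx[j, 1]; c <- idx[j, 2]
      rr <- max(1, r - w2):min(nrow(sm), r + w2)
      cc <- max(1, c - w2):min(ncol(sm), c + w2)
      win <- sm[rr, cc] - min(sm[rr, cc])
      if (sum(win) == 0) win[] <- 1
      out[j, 1] <- sum(win * X[rr, cc]) / sum(win)
      out[j, 2] <- sum(win * Y[rr, cc]) / sum(win)
    }
    # deduplicate refined peaks that converged to the same blob
    keep <- !logical(nrow(out))
    if (nrow(out) > 1) {
      d <- as.matrix(dist(out))
      for (j in 2:nrow(out))
        if (any(d[j, seq_len(j - 1)][keep[seq_len(j - 1)]] < mergeRadius / 2))
          keep[j] <- FALSE
    }
    peaks <- out[keep, , drop = FALSE]
    peaks[, 1] <- peaks[, 1] - hubCentre[1]
    peaks[, 2] <- peaks[, 2] - hubCentre[2]
    colnames(peaks) <- c("x", "y")
  }
  list(hubCentre = hubCentre, peaks = peaks, nPeaks = nrow(peaks),
       complete = is.na(nExpected) || nrow(peaks) == nExpected)
}

#' Write / read a rendered particle image as 16-bit grayscale TIFF
#'
#' Intensities are clipped to [0, 1] on write (the TIFF stores 16-bit
#' unsigned samples).
#'
#' @param img matrix from [renderParticle()].
#' @param path file path.
#' @return \code{writeParticleTiff} returns \code{path} invisibly;
#'   \code{readParticleTiff} returns the image matrix.
#' @export
writeParticleTiff <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(unclass(img), 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeParticleTiff
#' @export
readParticleTiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}
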