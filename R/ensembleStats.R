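## Dataset-level statistics: histograms, moment-based Gaussian fits,
## five-number summaries, threshold fractions, pair-count classification,
## radius-separation correlation.

#' Moment-based Gaussian fit
#'
#' The descriptive Gaussian overlaid on the radius and separation histograms
#' is parameterised directly by the experimentally determined sample mean
#' and sample standard deviation (n-1 denominator); no optimisation is
#' involved.
#'
#' @param values numeric vector, length >= 2.
#' @return named numeric \code{c(mean, sd)} (A).
#' @examples
#' gaussianFitMoments(c(50, 60))  # mean 55, sd 7.071
#' @export
gaussianFitMoments <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("need at least 2 values for a moment fit", call. = FALSE)
  c(mean = mean(values), sd = sd(values))
}

#' Histogram in 5 A bins
#'
#' Bins are half-open on the right, \code{[5k, 5k + 5)}, anchored at 0 A
#' (the 5 A width corresponds approximately to the micrograph pixel size).
#'
#' @param values numeric vector (A), non-empty.
#' @param binWidth bin width in A (default 5).
#' @return list with \code{breaks}, \code{counts}, \code{mids}; counts sum
#'   to \code{length(values)}.
#' @export
histogram5A <- function(values, binWidth = 5) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  lo <- binWidth * floor(min(values) / binWidth)
  hi <- binWidth * (floor(max(values) / binWidth) + 1)
  breaks <- seq(lo, hi, by = binWidth)
  idx <- findInterval(values, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  list(breaks = breaks, counts = counts,
       mids = breaks[-length(breaks)] + binWidth / 2)
}

#' Fraction of values strictly below a threshold
#'
#' Strict inequality on both classification thresholds (45 A pairing,
#' 100 A compact) follows the operational definitions "separated by <45 A"
#' and "radius <100 A".
#'
#' @param values numeric vector, non-empty.
#' @param threshold positive threshold (A).
#' @return fraction in \code{[0, 1]}.
#' @examples
#' fractionBelow(c(44.9, 45, 45.1), 45)  # 1/3: 45.0 is not below
#' @export
fractionBelow <- function(values, threshold) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  stopifnot(threshold > 0)
  mean(values < threshold)
}

#' Count kinase-domain pairs in one particle
#'
#' Number of clockwise neighbour separations strictly below the pairing
#' threshold. Chains of consecutive close domains can make the raw count
#' exceed the maximum number of disjoint pairs, floor(n/2); the reported
#' count is capped there with a warning. (Generated separation-explicit
#' particles carry a proper matching, so the cap never engages on them.)
#'
#' @param separations numeric vector of neighbour separations (A).
#' @param threshold pairing threshold (A), default 45.
#' @return integer pair count.
#' @export
countPairs <- function(separations, threshold = 45) {
  separations <- separations[!is.na(separations)]
  raw <- sum(separations < threshold)
  cap <- length(separations) %/% 2L
  if (raw > cap) {
    warning("raw short-separation count ", raw, " exceeds the maximum of ",
            cap, " disjoint pairs (chained close domains); capped")
    raw <- cap
  }
  as.integer(raw)
}

#' Per-particle pair-count distribution
#'
#' Classifies every particle by its number of kinase-domain pairs
#' (separations below the threshold) and tabulates the categorical
#' frequencies, reported for 12-mers and 14-mers separately and combined.
#' Categories 0..7 are always present (7 can only occur for 14-mers).
#'
#' @param measurements per-subunit measurement \code{data.frame} (from
#'   [measureEnsemble()]) or a \linkS4class{HoloEnsemble}.
#' @param threshold pairing threshold (A), default 45.
#' @return object of class \code{"PairCountDistribution"}: list with
#'   \code{perParticle} (data.frame particle_id, n_subunits, pairs),
#'   \code{freq}, \code{freq12}, \code{freq14} (named numeric over "0".."7")
#'   and \code{nParticles}.
#' @export
pairCountDistribution <- function(measurements, threshold = 45) {
  if (is(measurements, "HoloEnsemble"))
    measurements <- measureEnsemble(measurements)
  if (nrow(measurements) == 0L) stop("no particles", call. = FALSE)
  sp <- split(measurements, measurements$particle_id)
  per <- do.call(rbind, lapply(sp, function(rows) {
    data.frame(particle_id = rows$particle_id[1],
               n_subunits = rows$n_subunits[1],
               pairs = countPairs(rows$separation_A, threshold))
  }))
  rownames(per) <- NULL
  tabFreq <- function(counts) {
    f <- tabulate(counts + 1L, nbins = 8L)
    names(f) <- as.character(0:7)
    if (length(counts)) f / length(counts) else f
  }
  structure(list(perParticle = per,
                 freq = tabFreq(per$pairs),
                 freq12 = tabFreq(per$pairs[per$n_subunits == 12L]),
                 freq14 = tabFreq(per$pairs[per$n_subunits == 14L]),
                 nParticles = nrow(per)),
            class = "PairCountDistribution")
}

#' @export
print.PairCountDistribution <- function(x, ...) {
  cat("PairCountDistribution over", x$nParticles, "particles\n")
  print(round(x$freq, 4))
  invisible(x)
}

#' Radius-separation correlation
#'
#' Pearson correlation between each subunit's kinase radius and its
#' clockwise neighbour separation, together with the scatter data used for
#' the correlation map.
#'
#' @param measurements per-subunit measurement \code{data.frame} or a
#'   \linkS4class{HoloEnsemble}.
#' @return list with \code{correlation}, \code{n} and \code{scatter}
#'   (data.frame radius_A, separation_A).
#' @export
radiusSeparationCorrelation <- function(measurements) {
  if (is(measurements, "HoloEnsemble"))
    measurements <- measureEnsemble(measurements)
  ok <- stats::complete.cases(measurements[, c("radius_A", "separation_A")])
  m <- measurements[ok, , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(m$radius_A) == 0 || sd(m$separation_A) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  list(correlation = cor(m$radius_A, m$separation_A),
       n = nrow(m),
       scatter = data.frame(radius_A = m$radius_A,
                            separation_A = m$separation_A))
}

#' Dataset-level geometry summary
#'
#' Moment-based Gaussian parameters, five-number (whisker) summary, 5 A
#' histogram and threshold fractions for one measured quantity.
#'
#' @param values numeric vector (A), length >= 2.
#' @param thresholds thresholds (A) at which strict below-fractions are
#'   reported.
#' @return object of class \code{"GeometrySummary"}: list with \code{n},
#'   \code{mean}, \code{sd}, \code{min}, \code{q25}, \code{median},
#'   \code{q75}, \code{max}, \code{histogram}, \code{fractionBelow}.
#' @examples
#' ens <- generateEnsemble(ensembleConfig(nParticles = 200, seed = 3))
#' geometrySummary(particleTable(ens)$radius_A, thresholds = 100)
#' @export
geometrySummary <- function(values, thresholds = numeric()) {
  values <- values[!is.na(values)]
  fit <- gaussianFitMoments(values)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75)))
  fb <- vapply(thresholds, function(t) fractionBelow(values, t), numeric(1))
  names(fb) <- as.character(thresholds)
  structure(list(n = length(values),
                 mean = unname(fit["mean"]), sd = unname(fit["sd"]),
                 min = min(values), q25 = q[1], median = q[2], q75 = q[3],
                 max = max(values),
                 histogram = histogram5A(values),
                 fractionBelow = fb),
            class = "GeometrySummary")
}

#' @export
print.GeometrySummary <- function(x, ...) {
  cat(sprintf("GeometrySummary: n=%d  mean=%.2f  sd=%.2f A\n", x$n, x$mean, x$sd))
  cat(sprintf("  whiskers: min %.1f | q25 %.1f | median %.1f | q75 %.1f | max %.1f\n",
              x$min, x$q25, x$median, x$q75, x$max))
  if (length(x$fractionBelow))
    cat("  fraction below", paste(names(x$fractionBelow), "A:",
        sprintf("%.2f%%", 100 * x$fractionBelow), collapse = "; "), "\n")
  invisible(x)
}
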