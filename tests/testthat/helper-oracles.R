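## Independent oracles used across tests. These deliberately avoid the
## package's own code paths: moments come from numeric integration, matching
## counts from the closed-form cycle formula, and volumes from rejection
## sampling.

# Moments of a truncated normal by numeric integration of the density.
truncNormMomentsOracle <- function(mean, sd, lower, upper) {
  Z <- integrate(function(x) dnorm(x, mean, sd), lower, upper)$value
  m1 <- integrate(function(x) x * dnorm(x, mean, sd), lower, upper)$value / Z
  m2 <- integrate(function(x) x^2 * dnorm(x, mean, sd), lower, upper)$value / Z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Mixture moments from component moments and weights.
mixtureMomentsOracle <- function(weights, means, sds) {
  mu <- sum(weights * means)
  m2 <- sum(weights * (sds^2 + means^2))
  c(mean = mu, sd = sqrt(m2 - mu^2))
}

# Closed-form count of k-matchings on the n-cycle: n/(n-k) * choose(n-k, k).
cycleMatchingCountOracle <- function(n, k) {
  if (k == 0) return(1)
  n / (n - k) * choose(n - k, k)
}

# Brute-force check that a set of cycle edges is a matching (no shared vertex).
isCycleMatching <- function(edgeStarts, n) {
  v <- c(edgeStarts, edgeStarts %% n + 1)
  !anyDuplicated(v)
}

# Torus volume by rejection sampling in the bounding box.
torusVolumeMC <- function(R, r, nSamples = 1e6, seed = 99) {
  set.seed(seed)
  x <- runif(nSamples, -(R + r), R + r)
  y <- runif(nSamples, -(R + r), R + r)
  z <- runif(nSamples, -r, r)
  inside <- (sqrt(x^2 + y^2) - R)^2 + z^2 <= r^2
  mean(inside) * (2 * (R + r))^2 * (2 * r)
}

# Default-config component specs, restated independently of the package for
# oracle computations.
defaultSpecs <- list(
  radiusExtended = c(mean = 127, sd = 15, lower = 100, upper = 175),
  radiusCompact = c(mean = 88, sd = 5, lower = 77, upper = 100),
  sepPaired = c(mean = 36, sd = 5, lower = 20, upper = 45),
  sepUnpaired = c(mean = 62.5, sd = 11, lower = 45, upper = 110),
  pairCountProbs = c(0.10, 0.25, 0.20, 0.15, 0.165, 0.11, 0.025),
  pCompact = 0.025
)

# Expected fraction of separations below 45 A implied by the categorical.
expectedPairedFraction <- function(probs = defaultSpecs$pairCountProbs,
                                   nSubunits = 12) {
  sum((0:6) * probs) / nSubunits
}
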