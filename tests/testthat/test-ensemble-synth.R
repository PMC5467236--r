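test_that("pair assignments are uniform matchings of the drawn size", {
  # degenerate categorical at k = 0 gives the empty edge set
  expect_identical(nrow(samplePairAssignment(12, c(1, rep(0, 6)))), 0L)

  # enumeration sizes agree with the closed-form cycle-matching count
  for (n in c(12L, 14L)) for (k in 0:6)
    expect_equal(length(enumerateCycleMatchings(n, k)),
                 cycleMatchingCountOracle(n, k))

  # k = 6 on the 12-cycle: exactly the two alternating perfect matchings,
  # each drawn with probability ~1/2
  probs6 <- c(rep(0, 6), 1)
  set.seed(11)
  draws <- replicate(400, {
    e <- samplePairAssignment(12, probs6)[, "i"]
    paste(sort(e), collapse = ",")
  })
  expect_setequal(unique(draws), c("1,3,5,7,9,11", "2,4,6,8,10,12"))
  expect_gt(mean(draws == "1,3,5,7,9,11"), 0.40)
  expect_lt(mean(draws == "1,3,5,7,9,11"), 0.60)

  # k = 1: uniform over the 12 edges
  probs1 <- c(0, 1, rep(0, 5))
  set.seed(12)
  edges <- replicate(1200, samplePairAssignment(12, probs1)[1, "i"])
  expect_setequal(unique(edges), 1:12)
  expect_gt(min(table(edges)), 1200 / 12 * 0.5)

  # every draw is a matching (no subunit in two pairs), 12- and 14-cycles
  set.seed(13)
  for (n in c(12L, 14L)) {
    ok <- replicate(300, {
      e <- samplePairAssignment(n, defaultSpecs$pairCountProbs)
      nrow(e) == 0L || isCycleMatching(e[, "i"], n)
    })
    expect_true(all(ok))
  }

  expect_error(samplePairAssignment(12, rep(0.2, 7)), "categorical")
  expect_error(samplePairAssignment(13, defaultSpecs$pairCountProbs), "12 or 14")
})

test_that("sampled radii follow the calibrated truncated-Gaussian mixture", {
  cfg <- ensembleConfig(nParticles = 1)

  # degenerate mixture: all compact draws land in [77, 100)
  cfgC <- ensembleConfig(nParticles = 1, pCompact = 1)
  set.seed(1)
  rc <- sampleRadii(2000, cfgC)
  expect_true(all(rc$radii >= 77 & rc$radii < 100))
  expect_true(all(rc$compact))

  # zero-variance extended component collapses to the mean
  cfg0 <- ensembleConfig(nParticles = 1, pCompact = 0,
                         radiusExtended = c(mean = 127, sd = 0,
                                            lower = 100, upper = 175))
  set.seed(2)
  expect_true(all(sampleRadii(50, cfg0)$radii == 127))

  # large-sample moments match the numeric-integration mixture oracle
  ext <- truncNormMomentsOracle(127, 15, 100, 175)
  comp <- truncNormMomentsOracle(88, 5, 77, 100)
  mix <- mixtureMomentsOracle(c(0.975, 0.025),
                              c(ext["mean"], comp["mean"]),
                              c(ext["sd"], comp["sd"]))
  set.seed(3)
  r <- sampleRadii(1e5, cfg)
  expect_equal(mean(r$radii), unname(mix["mean"]), tolerance = 0.005)
  expect_equal(sd(r$radii), unname(mix["sd"]), tolerance = 0.02)
  expect_true(all(r$radii >= 77 & r$radii <= 175))
  # compact flag is exactly the sub-100 A classification
  expect_identical(r$compact, r$radii < 100)
})

test_that("sampled separations follow the paired/unpaired mixture split at 45 A", {
  cfg <- ensembleConfig(nParticles = 1)
  onePair <- cbind(i = 3L, j = 4L)

  # construction: exactly the paired edge falls below threshold
  set.seed(4)
  sep <- sampleSeparations(onePair, 12L, cfg)
  expect_length(sep, 12)
  expect_identical(which(sep < 45), 3L)

  # zero-variance unpaired component, no pairs
  cfgU <- ensembleConfig(nParticles = 1,
                         sepUnpaired = c(mean = 62.5, sd = 0,
                                         lower = 45, upper = 110))
  noPairs <- cbind(i = integer(0), j = integer(0))
  expect_true(all(sampleSeparations(noPairs, 12L, cfgU) == 62.5))

  # paired and unpaired draws respect their supports around the threshold
  set.seed(5)
  manyPairs <- cbind(i = c(1L, 3L, 5L), j = c(2L, 4L, 6L))
  s <- sampleSeparations(manyPairs, 12L, cfg)
  expect_true(all(s[c(1, 3, 5)] < 45))
  expect_true(all(s[-c(1, 3, 5)] >= 45))
})

test_that("separation mixture moments match the analytic oracle at scale", {
  cfg <- ensembleConfig(nParticles = 1)
  fp <- expectedPairedFraction()
  pr <- truncNormMomentsOracle(36, 5, 20, 45)
  un <- truncNormMomentsOracle(62.5, 11, 45, 110)
  mix <- mixtureMomentsOracle(c(fp, 1 - fp),
                              c(pr["mean"], un["mean"]),
                              c(pr["sd"], un["sd"]))
  # one call per stratum, sizes at the expected mixture weights
  nP <- round(fp * 1e5); nU <- 1e5 - nP
  set.seed(7)
  sP <- sampleSeparations(cbind(i = seq_len(nP), j = seq_len(nP) + 1L),
                          2L * nP, cfg)[seq_len(nP)]
  sU <- sampleSeparations(cbind(i = integer(0), j = integer(0)), nU, cfg)
  pooled <- c(sP, sU)
  expect_equal(mean(pooled), unname(mix["mean"]), tolerance = 0.005)
  expect_equal(sd(pooled), unname(mix["sd"]), tolerance = 0.02)
  expect_true(all(sP < 45) && all(sU >= 45))

  # angular-mode usage error
  cfgA <- ensembleConfig(nParticles = 1, mode = "angular")
  expect_error(sampleSeparations(cbind(i = 1L, j = 2L), 12L, cfgA),
               "separation_explicit")
})

test_that("generateEnsemble is seed-deterministic and honours oligomer probabilities", {
  cfg <- ensembleConfig(nParticles = 60, seed = 21)
  e1 <- generateEnsemble(cfg)
  e2 <- generateEnsemble(cfg)
  expect_identical(particleTable(e1), particleTable(e2))
  expect_identical(nParticles(e1), 60L)

  # angular mode determinism too
  cfgA <- ensembleConfig(nParticles = 20, seed = 22, mode = "angular")
  expect_identical(particleTable(generateEnsemble(cfgA)),
                   particleTable(generateEnsemble(cfgA)))

  # p_tetradecamer = 0: all dodecamers
  e12 <- generateEnsemble(ensembleConfig(nParticles = 40, seed = 23,
                                         pTetradecamer = 0))
  expect_true(all(particleTable(e12)$n_subunits == 12L))

  # default 14-mer fraction ~3.5% (binomial sampling oracle, 2000 particles)
  eBig <- generateEnsemble(ensembleConfig(nParticles = 2000, seed = 24))
  tab <- particleTable(eBig)
  frac14 <- mean(tapply(tab$n_subunits, tab$particle_id,
                        function(x) x[1]) == 14L)
  expect_lt(abs(frac14 - 0.035), 0.015)

  expect_error(ensembleConfig(nParticles = 0), "positive")
})

test_that("separation-explicit ensembles admit exact threshold recovery of pairs", {
  ens <- generateEnsemble(ensembleConfig(nParticles = 300, seed = 31))
  tab <- particleTable(ens)
  expect_identical(tab$paired == 1L, tab$separation_A < 45)
  # matching property on every particle
  for (rows in split(tab, tab$particle_id)) {
    starts <- rows$subunit_index[rows$paired == 1L]
    expect_true(length(starts) == 0 ||
                isCycleMatching(starts, rows$n_subunits[1]))
  }
})

test_that("realizeCoordinates closes the ring and reproduces chord geometry", {
  cfgA <- ensembleConfig(nParticles = 1, mode = "angular")

  # gaps always sum to exactly 360 degrees
  set.seed(41)
  for (i in 1:25) {
    edges <- samplePairAssignment(12, defaultSpecs$pairCountProbs)
    radii <- sampleRadii(12, cfgA)$radii
    geo <- realizeCoordinates(radii, edges, cfgA)
    expect_equal(sum(geo$gaps), 360, tolerance = 1e-9)
    expect_true(all(geo$gaps > 0))
  }

  # zero variance, no pairs: regular 30-degree gaps, separations equal the
  # chord 2 (r - 22.5) sin(15 deg)
  cfg0 <- ensembleConfig(nParticles = 1, mode = "angular", pCompact = 0,
                         radiusExtended = c(mean = 127, sd = 0,
                                            lower = 100, upper = 175),
                         angularUnpairedSd = 0)
  set.seed(42)
  geo0 <- realizeCoordinates(rep(127, 12), cbind(i = integer(0), j = integer(0)),
                             cfg0)
  chord <- 2 * (127 - 22.5) * sin(pi / 12)
  expect_equal(unname(geo0$separations), rep(chord, 12), tolerance = 1e-9)
  # 12-fold symmetry up to global rotation: all centre radii equal
  expect_equal(sqrt(rowSums(geo0$coords^2)), rep(127 - 22.5, 12),
               tolerance = 1e-9)
})
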