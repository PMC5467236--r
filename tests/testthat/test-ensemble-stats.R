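test_that("moment-based Gaussian fit returns sample mean and n-1 sd", {
  expect_equal(gaussianFitMoments(c(10, 10, 10)), c(mean = 10, sd = 0))
  expect_equal(gaussianFitMoments(c(50, 60)),
               c(mean = 55, sd = sqrt(50)), tolerance = 1e-12)
  set.seed(61)
  x <- rnorm(1e5, 127, 16)
  fit <- gaussianFitMoments(x)
  expect_equal(unname(fit["mean"]), 127, tolerance = 0.2 / 127)
  expect_equal(unname(fit["sd"]), 16, tolerance = 0.2 / 16)
  expect_error(gaussianFitMoments(42), "at least 2")
})

test_that("5 A histogram uses right-open bins anchored at 0", {
  h <- histogram5A(77.0)
  expect_equal(h$breaks, c(75, 80))
  expect_equal(h$counts, 1L)
  # boundary value falls in the bin it opens, not the one it closes
  h2 <- histogram5A(c(100, 99.999, 104.9))
  i100 <- findInterval(100, h2$breaks)
  expect_equal(h2$breaks[i100], 100)
  expect_equal(h2$counts[i100], 2L)
  # conservation
  set.seed(62)
  x <- runif(777, 50, 200)
  expect_equal(sum(histogram5A(x)$counts), 777L)
})

test_that("fraction below is strict and matches the categorical oracle at scale", {
  expect_equal(fractionBelow(c(44.9, 45, 45.1), 45), 1 / 3)
  expect_equal(fractionBelow(c(50, 60), 45), 0)
  # large ensemble: separation fraction below 45 A ~ E[pairs]/12
  ens <- generateEnsemble(ensembleConfig(nParticles = 1000, seed = 63,
                                         pTetradecamer = 0))
  frac <- fractionBelow(particleTable(ens)$separation_A, 45)
  expect_lt(abs(frac - expectedPairedFraction()), 0.01)
  expect_error(fractionBelow(numeric(0), 45), "empty")
})

test_that("pair counting is strict, capped and chain-aware", {
  expect_identical(countPairs(c(40, seq(50, 150, by = 10))), 1L)
  expect_identical(countPairs(seq(50, 160, by = 10)), 0L)
  expect_warning(res <- countPairs(rep(40, 12)), "capped")
  expect_identical(res, 6L)
  # a chain of 2 short separations is 2 raw counts, below the cap: no warning
  expect_silent(expect_identical(countPairs(c(40, 40, rep(60, 10))), 2L))
})

test_that("pair-count distribution recovers generated categoricals", {
  # degenerate categorical at k = 2: every particle classified with 2 pairs
  cfg2 <- ensembleConfig(nParticles = 50, seed = 64,
                         pairCountProbs = c(0, 0, 1, 0, 0, 0, 0))
  pcd2 <- pairCountDistribution(generateEnsemble(cfg2))
  expect_equal(unname(pcd2$freq["2"]), 1)
  expect_length(pcd2$freq, 8)  # categories always present, zeros allowed

  # multinomial recovery of P(0) at 4000 12-mer particles
  ens <- generateEnsemble(ensembleConfig(nParticles = 4000, seed = 65,
                                         pTetradecamer = 0))
  pcd <- pairCountDistribution(ens)
  expect_lt(abs(pcd$freq12[["0"]] - 0.10), 0.015)
  # frequencies sum to one; per-particle counts within the matching bound
  expect_equal(sum(pcd$freq), 1)
  expect_true(all(pcd$perParticle$pairs <=
                  pcd$perParticle$n_subunits %/% 2))
})

test_that("radius-separation correlation separates the two generator modes", {
  # separation-explicit: radii and separations are independent by construction
  ens <- generateEnsemble(ensembleConfig(nParticles = 850, seed = 66))
  rs <- radiusSeparationCorrelation(ens)
  expect_lt(abs(rs$correlation), 0.05)
  expect_equal(rs$n, nrow(particleTable(ens)))

  # angular: mechanical coupling through shared radii gives a weak positive
  # correlation, in the (0, 0.35] band
  ensA <- generateEnsemble(ensembleConfig(nParticles = 500, seed = 67,
                                          mode = "angular"))
  rsA <- radiusSeparationCorrelation(ensA)
  expect_gt(rsA$correlation, 0)
  expect_lte(rsA$correlation, 0.35)

  # perfectly linear toy data
  toy <- data.frame(particle_id = 1, subunit_index = 1:5, n_subunits = 12,
                    radius_A = 1:5, separation_A = 2 * (1:5),
                    paired = 0L, compact = 0L)
  expect_equal(radiusSeparationCorrelation(toy)$correlation, 1)
  toy$separation_A <- 7
  expect_error(radiusSeparationCorrelation(toy), "zero variance")
})

test_that("geometry summary is conserved and ordered", {
  set.seed(68)
  x <- rnorm(500, 127, 16)
  gs <- geometrySummary(x, thresholds = c(100, 127))
  expect_equal(gs$n, 500L)
  expect_equal(sum(gs$histogram$counts), 500L)
  expect_true(gs$min <= gs$q25 && gs$q25 <= gs$median &&
              gs$median <= gs$q75 && gs$q75 <= gs$max)
  expect_equal(unname(gs$fractionBelow["100"]), mean(x < 100))
})
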