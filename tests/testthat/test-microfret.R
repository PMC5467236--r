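test_that("synthetic scenes are deterministic and linear in abundance", {
  sc1 <- synthFretScene(nCells = 4, seed = 81)
  sc2 <- synthFretScene(nCells = 4, seed = 81)
  expect_identical(sceneChannels(sc1), sceneChannels(sc2))

  # doubling acceptor abundance doubles pre-noise acceptor-channel signal
  ch <- sceneChannels(synthFretScene(nCells = 2, dim = 64, noiseSd = 0,
                                     ratioRange = c(5, 5), seed = 82))
  acc <- ch$acceptor - ch$background[["acceptor"]]
  don <- ch$donor - ch$background[["donor"]]
  for (cl in 1:2)
    expect_equal(mean(acc[ch$roi == cl]) / mean(don[ch$roi == cl]), 5,
                 tolerance = 1e-9)

  # efficiency 0 everywhere: raw FRET is bleed-through + background only
  ch0 <- sceneChannels(synthFretScene(nCells = 3, efficiency = 0,
                                      noiseSd = 0, seed = 83))
  predicted <- 0.02093 * (ch0$donor - ch0$background[["donor"]]) +
    0.09484 * (ch0$acceptor - ch0$background[["acceptor"]]) +
    ch0$background[["rawFret"]]
  expect_equal(ch0$rawFret, predicted, tolerance = 1e-9)
})

test_that("FRETc subtraction uses the printed coefficients exactly", {
  out <- correctFret(matrix(100), matrix(1000), matrix(500))
  expect_equal(out[1, 1], 100 - 20.93 - 47.42)
  expect_error(correctFret(matrix(1, 2, 2), matrix(1, 3, 3), matrix(1, 2, 2)),
               "mismatch")
  # negative pixels are retained, not clipped
  expect_lt(correctFret(matrix(0), matrix(1000), matrix(0))[1, 1], 0)
})

test_that("exact coefficients cancel zero-FRET scenes to numerical zero", {
  sc <- synthFretScene(nCells = 4, efficiency = 0, noiseSd = 0, seed = 84)
  ch <- sceneChannels(sc)
  fretc <- correctFret(ch$rawFret - ch$background[["rawFret"]],
                       ch$donor - ch$background[["donor"]],
                       ch$acceptor - ch$background[["acceptor"]])
  expect_lt(max(abs(fretc)), 1e-9 * max(ch$rawFret))
})

test_that("per-cell FRETc increases with true efficiency and rounded-up
           coefficients never overestimate", {
  # fixed expression level isolates the efficiency dependence of FRETc
  eff <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  sc <- synthFretScene(nCells = 6, efficiency = eff, noiseSd = 1,
                       donorRange = c(600, 600), seed = 85)
  res <- analyzeFretScene(sc)
  expect_true(all(diff(res$meanFretc[order(sc@truth$efficiency)]) > 0))

  # mixing with smaller true cross-bleed than the correction assumes can
  # only under-, never over-estimate the true FRET signal
  scU <- synthFretScene(nCells = 5, efficiency = 0.2, noiseSd = 0,
                        trueBleed = c(0.015, 0.07), seed = 86)
  chU <- sceneChannels(scU)
  fretcU <- correctFret(chU$rawFret - chU$background[["rawFret"]],
                        chU$donor - chU$background[["donor"]],
                        chU$acceptor - chU$background[["acceptor"]])
  for (cl in seq_len(5)) {
    trueSig <- 0.2 * scU@truth$donorAbundance[cl]
    expect_lte(mean(fretcU[chU$roi == cl]), trueSig + 1e-9)
  }
})

test_that("donor normalisation is expression- and illumination-invariant", {
  expect_equal(normalizedFret(matrix(10, 4, 4), matrix(100, 4, 4),
                              matrix(TRUE, 4, 4)), 0.1)
  # global illumination scaling cancels
  f <- matrix(rnorm(64, 10), 8); d <- matrix(runif(64, 80, 120), 8)
  roi <- matrix(TRUE, 8, 8)
  expect_equal(normalizedFret(3.7 * f, 3.7 * d, roi),
               normalizedFret(f, d, roi), tolerance = 1e-12)
  expect_error(normalizedFret(f, -d, roi), "donor")

  # equal efficiency across 5-fold expression range: normalised values agree
  sc <- synthFretScene(nCells = 6, efficiency = 0.2,
                       donorRange = c(200, 1000), noiseSd = 2, seed = 87)
  res <- analyzeFretScene(sc)
  expect_lt(sd(res$normalizedFret) / mean(res$normalizedFret), 0.10)
})

test_that("acceptor/donor gating applies the 4.8 factor and closed window", {
  # detected GFP 480 vs mCherry 100: abundance ratio 1 under GFP-as-acceptor
  expect_equal(acceptorDonorRatio(480, 100), 1)
  # role swap inverts the ratio
  expect_equal(acceptorDonorRatio(480, 100, gfpRole = "donor"), 1)
  expect_equal(acceptorDonorRatio(960, 100), 2)
  expect_error(acceptorDonorRatio(-1, 100), "excluded")

  # closed interval boundary rule
  expect_false(gateAcceptorExcess(3.9))
  expect_true(gateAcceptorExcess(4.0))
  expect_true(gateAcceptorExcess(11.0))
  expect_false(gateAcceptorExcess(11.01))

  # population with ratios spanning [2, 14]: gate keeps exactly [4, 11]
  sc <- synthFretScene(nCells = 9, ratioRange = c(2, 14), noiseSd = 0,
                       seed = 88)
  res <- analyzeFretScene(sc)
  expect_identical(res$gated,
                   sc@truth$acceptorDonorRatio >= 4 &
                   sc@truth$acceptorDonorRatio <= 11)
})

test_that("background subtraction uses the blank-region median", {
  img <- matrix(c(rep(5, 50), rep(100, 50)), 10)
  blank <- matrix(rep(c(TRUE, FALSE), each = 50), 10)
  out <- backgroundSubtract(img, blank)
  expect_equal(out[10, 10], 95)
  expect_equal(backgroundSubtract(img, 5)[1, 1], 0)
})
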