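test_that("planted covariance is PSD and degenerate targets are exact", {
  cfg <- timeSeriesSimConfig(nRois = 30, nVolumes = 100, hubSet = 5:10,
                             hubR = 0.5, hubClubR = 0.8, seed = 2)
  R <- plantedCorrelation(cfg)
  expect_true(isSymmetric(R))
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # noiseless pair at target r = 1 reproduces r = 1 exactly
  cfg1 <- timeSeriesSimConfig(nRois = 2, nVolumes = 50, nBlocks = 1,
                              blockR = 1 - 1e-12, noiseSd = 0,
                              driftAmplitude = 0, nuisanceAmplitude = 0,
                              seed = 3)
  x <- simulateRoiTimeSeries(cfg1)
  expect_equal(cor(signals(x)[1, ], signals(x)[2, ]), 1, tolerance = 1e-9)
})

test_that("sample correlations converge to planted block targets", {
  cfg <- timeSeriesSimConfig(nRois = 10, nVolumes = 3000, nBlocks = 1,
                             blockR = 0.6, noiseSd = 0.3,
                             driftAmplitude = 0, nuisanceAmplitude = 0,
                             seed = 7)
  x <- simulateRoiTimeSeries(cfg)
  r <- cor(t(signals(x)))
  # noise attenuates towards the theoretical attenuated target 0.6/(1+.09)
  expect_lt(abs(mean(r[upper.tri(r)]) - 0.6 / 1.09), 0.05)
  # pure latent draw hits the target itself
  cfg0 <- timeSeriesSimConfig(nRois = 10, nVolumes = 3000, nBlocks = 1,
                              blockR = 0.6, noiseSd = 0, driftAmplitude = 0,
                              nuisanceAmplitude = 0, seed = 8)
  r0 <- cor(t(signals(simulateRoiTimeSeries(cfg0))))
  expect_lt(abs(mean(r0[upper.tri(r0)]) - 0.6), 0.05)
  # error shrinks with series length
  cfgShort <- timeSeriesSimConfig(nRois = 10, nVolumes = 150, nBlocks = 1,
                                  blockR = 0.6, noiseSd = 0,
                                  driftAmplitude = 0,
                                  nuisanceAmplitude = 0, seed = 8)
  errAt <- function(cfg) {
    rs <- replicate(5, {
      cfg@seed <- cfg@seed + 1L; r <- cor(t(signals(simulateRoiTimeSeries(cfg))))
      mean(abs(r[upper.tri(r)] - 0.6))
    })
    mean(rs)
  }
  expect_lt(errAt(cfg0), errAt(cfgShort))
})

test_that("time-series generator is bit-reproducible and validates config", {
  cfg <- timeSeriesSimConfig(nRois = 12, nVolumes = 60, seed = 42)
  expect_identical(signals(simulateRoiTimeSeries(cfg)),
                   signals(simulateRoiTimeSeries(cfg)))
  expect_error(timeSeriesSimConfig(nRois = 10,
                                   blocks = list(1:5, 4:10)),
               "partition")
  expect_error(timeSeriesSimConfig(nRois = 10, nBlocks = 1, blockR = 1.2),
               "correlation targets")
})

test_that("simulated acquisitions carry confounds and study geometry", {
  cfg <- timeSeriesSimConfig(nRois = 6, nVolumes = 300, dt = 2, seed = 1)
  x <- simulateRoiTimeSeries(cfg)
  expect_equal(nVolumes(x) * samplingInterval(x) / 60, 10)  # 10 min
  conf <- S4Vectors::metadata(x)$confounds
  expect_equal(dim(conf), c(8L, 300L))  # 6 motion-like + 2 physiological
})

test_that("trial-log generator respects bias, WME and determinism contracts", {
  allLeft <- simulateTrialLog(behaviorSimConfig(sideBias = 1, seed = 5))
  expect_equal(responseBias(allLeft), 1)
  noWme <- simulateTrialLog(behaviorSimConfig(pWme = 0, seed = 5))
  expect_equal(sum(trialRecords(noWme)$kind == "wme"), 0L)
  # balanced choice probability: bias near 0 for a long session
  bal <- simulateTrialLog(behaviorSimConfig(nTrialsPerDay = 4000,
                                            sideBias = 0.5, seed = 6))
  expect_lt(responseBias(bal), 3 / sqrt(4000))  # ~3 SE of |L-R|/T
  # WME rows carry no choice; object-choice rows always do (validity holds)
  withWme <- simulateTrialLog(behaviorSimConfig(pWme = 0.3, seed = 7))
  expect_true(validObject(withWme))
  r <- trialRecords(withWme)
  expect_true(all(is.na(r$side[r$kind == "wme"])))
  expect_equal(sum(r$kind == "object_choice"), 32L)
  expect_identical(
    trialRecords(simulateTrialLog(behaviorSimConfig(seed = 9))),
    trialRecords(simulateTrialLog(behaviorSimConfig(seed = 9))))
})

test_that("cell-population generator plants recoverable ground truth", {
  cfg <- cellSimConfig(nCells = 2000, fracNuclear = 0.2,
                       fracCytoplasmic = 0.1, fracDouble = 0.05,
                       fracNegative = 0.65, edgeCutFraction = 0, seed = 11)
  pop <- simulateCellPopulation(cfg)
  inc <- inclusionFilter(pop)
  lab <- classifyCells(inc)
  truth <- cellTable(inc)$trueLabel
  expect_equal(mean(as.character(lab) == truth), 1)
  frac <- table(lab) / length(lab)
  expect_lt(abs(frac[["nuclear"]] - 0.2), 0.02)
  expect_lt(abs(frac[["cytoplasmic"]] - 0.1), 0.02)
  expect_lt(abs(frac[["double"]] - 0.05), 0.02)
  expect_lt(abs(frac[["negative"]] - 0.65), 0.02)
  # all-negative population recovers 0% positive
  neg <- simulateCellPopulation(cellSimConfig(nCells = 200, fracNuclear = 0,
                                              fracCytoplasmic = 0,
                                              fracDouble = 0,
                                              fracNegative = 1, seed = 2))
  expect_true(all(classifyCells(inclusionFilter(neg)) == "negative"))
  # determinism
  expect_identical(fociMatrix(simulateCellPopulation(cfg)),
                   fociMatrix(simulateCellPopulation(cfg)))
  # invalid fractions
  expect_error(cellSimConfig(fracNegative = 0.9), "sum to 1")
})
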