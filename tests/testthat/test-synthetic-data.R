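test_that("linear retinotopy ramps 0 to extent along columns", {
  sc <- makeLinearRetinotopy(70, c(64, 64))
  ph <- sc@phaseTruth
  expect_equal(ph[, 1], rep(0, 64))
  expect_equal(ph[, 64], rep(70, 64))
  expect_equal(ph[1, ], seq(0, 70, length.out = 64))
  expect_true(all(apply(ph, 2, function(col) length(unique(col)) == 1)))
  expect_true(all(ph >= 0 & ph <= 70))

  # binocular-zone-like span: constant per-pixel gradient extent/(cols-1)
  sc20 <- makeLinearRetinotopy(20, c(64, 64))
  grad <- diff(sc20@phaseTruth[1, ])
  expect_equal(grad, rep(20 / 63, 63))
})

test_that("linear retinotopy rejects degenerate inputs", {
  expect_error(makeLinearRetinotopy(0, c(64, 64)), "positive")
  expect_error(makeLinearRetinotopy(-5, c(64, 64)), "positive")
  expect_error(makeLinearRetinotopy(70, c(4, 64)), "5x5")
})

test_that("OD scene inverts the ODI formula exactly", {
  # symmetric: equal amplitudes
  sc0 <- makeOdScene(0, contraPeak = 2e-4)
  m <- sc0@v1Mask
  expect_equal(sc0@ampIpsi[m], sc0@ampContra[m])
  # fully contralateral: ipsi 0
  sc1 <- makeOdScene(1)
  expect_true(all(sc1@ampIpsi == 0))
  # (1.9 - 1.3)/(1.9 + 1.3) = 0.1875
  sc <- makeOdScene(0.1875, contraPeak = 1.9e-4)
  expect_equal(unique(sc@ampIpsi[sc@v1Mask]), 1.3e-4, tolerance = 1e-12)
  expect_equal(mean(odiTruth(sc)[sc@v1Mask]), 0.1875, tolerance = 1e-12)
  # amplitudes vanish outside the mask
  expect_true(all(sc@ampContra[!sc@v1Mask] == 0))
  expect_error(makeOdScene(1.5), "\\[-1, 1\\]")
})

test_that("rendered noiseless movie is the exact forward model", {
  ph <- matrix(0, 8, 8)
  sc <- uniformScene(ph, amp = 2e-4)
  acq <- acquisitionConfig(imageSize = c(8L, 8L), nCycles = 1L)
  st <- renderMovie(sc, "contra", acq, noiseModel())
  t <- (0:239) / 30
  expected <- 2e-4 * cos(2 * pi * 0.125 * t)
  for (px in list(c(1, 1), c(5, 7)))
    expect_equal(stackData(st)[, px[1], px[2]], expected, tolerance = 1e-12)
  # frame count: nCycles * rate / f
  expect_identical(dim(stackData(st))[1], 240L)
  # integer cycles: temporal mean is zero at every pixel
  expect_lt(max(abs(apply(stackData(st), c(2, 3), mean))), 1e-15)
})

test_that("movie rendering is deterministic under a fixed seed", {
  sc <- makeOdScene(0.3, shape = c(8, 8))
  acq <- acquisitionConfig(imageSize = c(8L, 8L), nCycles = 1L)
  nm <- noiseModel(gaussianSd = 1e-4, driftAmp = 5e-5, seed = 42L)
  a <- renderMovie(sc, "ipsi", acq, nm)
  b <- renderMovie(sc, "ipsi", acq, nm)
  expect_identical(stackData(a), stackData(b))
  # different seed differs
  c_ <- renderMovie(sc, "ipsi", acq, noiseModel(gaussianSd = 1e-4, seed = 43L))
  expect_false(identical(stackData(a), stackData(c_)))
  expect_error(renderMovie(sc, "binocular", acq, nm))
})

test_that("behavioral cohort generator honors its spec exactly", {
  flat <- behaviorCohortSpec(list(
    list(label = "ctrl", nAnimals = 3L, md = FALSE, day0Sf = 0.37,
         day7Sf = 0.37, csDay0 = rep(10, 6), csDay7 = rep(10, 6))))
  tab <- simulateBehaviorCohort(flat)
  sf <- tab[tab$measure == "sf_threshold", ]
  expect_equal(sf$value, rep(0.37, nrow(sf)))

  md <- behaviorCohortSpec(list(
    list(label = "md", nAnimals = 2L, md = TRUE, day0Sf = 0.37,
         day7Sf = 0.46, csDay0 = rep(10, 6), csDay7 = rep(20, 6))))
  tab <- simulateBehaviorCohort(md)
  sf <- tab[tab$measure == "sf_threshold", ]
  expect_equal(unique(sf$value[sf$day == 0]), 0.37)
  expect_equal(unique(sf$value[sf$day == 7]), 0.46)
  # monotone ramp in between
  one <- sf[sf$animal_id == sf$animal_id[1], ]
  expect_true(all(diff(one$value[order(one$day)]) > 0))

  noisy <- behaviorCohortSpec(list(
    list(label = "md", nAnimals = 2L, md = TRUE, day0Sf = 0.37,
         day7Sf = 0.46, csDay0 = rep(10, 6), csDay7 = rep(20, 6))),
    noiseSd = 0.01, seed = 7L)
  expect_identical(simulateBehaviorCohort(noisy), simulateBehaviorCohort(noisy))
  expect_error(behaviorCohortSpec(list()), "empty")
})

test_that("acquisition config enforces timing invariants", {
  expect_error(acquisitionConfig(stimFrequency = 0.11), "integer")
  expect_error(acquisitionConfig(acquisitionRate = 10, binnedRate = 7.5),
               "divide")
  expect_identical(framesPerRun(acquisitionConfig(nCycles = 1L)), 240L)
  expect_identical(framesPerRun(acquisitionConfig(nCycles = 1L), binned = TRUE),
                   60L)
})
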