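test_that("temporal binning averages consecutive frames", {
  st <- traceStack(c(1, 3, 5, 7), frameRate = 4, stimFrequency = 0.5)
  b <- binFrames(st, 2L)
  expect_equal(as.vector(stackData(b)), c(2, 6))
  expect_equal(frameRate(b), 2)
  # identity at factor 1
  expect_identical(stackData(binFrames(st, 1L)), stackData(st))
  # 240 frames at 30 Hz -> 60 frames at 7.5 Hz
  sc <- uniformScene(matrix(0, 8, 8))
  mov <- renderMovie(sc, "contra", acquisitionConfig(imageSize = c(8L, 8L),
                                                     nCycles = 1L))
  b4 <- binFrames(mov, 4L)
  expect_identical(dim(stackData(b4))[1], 60L)
  expect_equal(frameRate(b4), 7.5)
  expect_error(binFrames(st, 5L), "exceeds")
  expect_warning(binFrames(traceStack(1:5, 5, 0.5), 2L), "trailing")
})

test_that("pure sinusoid recovers amplitude and phase", {
  t <- (0:59) / 7.5
  for (phi in c(0, 0.7, -1.2)) {
    x <- 2e-4 * cos(2 * pi * 0.125 * t + phi)
    st <- stackFromArray(array(rep(x, each = 1), dim = c(60, 1, 1)), 7.5, 0.125)
    cm <- extractQuiet(st)
    expect_equal(Mod(responseCoef(cm))[1, 1], 2e-4, tolerance = 1e-10)
    phaseErr <- abs(Arg(responseCoef(cm))[1, 1] - phi) %% (2 * pi)
    expect_lt(min(phaseErr, 2 * pi - phaseErr), 1e-10)
  }
  # DC is rejected
  const <- traceStack(rep(3.3, 60), 7.5, 0.125)
  expect_lt(Mod(responseCoef(extractQuiet(const)))[1, 1], 1e-15)
})

test_that("extraction matches a brute-force DFT sum", {
  set.seed(101)
  arr <- array(rnorm(64 * 16 * 16, sd = 1e-4), dim = c(64, 16, 16))
  st <- stackFromArray(arr, frameRate = 8, stimFrequency = 0.125)
  got <- responseCoef(extractQuiet(st))
  want <- bruteForceCoef(arr, 8, 0.125)
  relErr <- max(Mod(got - want)) / max(Mod(want))
  expect_lt(relErr, 1e-10)
})

test_that("extraction is linear and bounded", {
  set.seed(11)
  a1 <- array(rnorm(60 * 4 * 4), dim = c(60, 4, 4))
  a2 <- array(rnorm(60 * 4 * 4), dim = c(60, 4, 4))
  c1 <- responseCoef(extractQuiet(stackFromArray(a1, 7.5, 0.125)))
  c2 <- responseCoef(extractQuiet(stackFromArray(a2, 7.5, 0.125)))
  c12 <- responseCoef(extractQuiet(stackFromArray(2 * a1 - 3 * a2,
                                                      7.5, 0.125)))
  expect_equal(c12, 2 * c1 - 3 * c2, tolerance = 1e-10)
  # |coef| <= 2 max |x|
  expect_true(all(Mod(c1) <= 2 * max(abs(a1))))
  expect_true(all(Mod(c2) <= 2 * max(abs(a2))))
})

test_that("extraction rejects unresolvable or truncated input", {
  st <- traceStack(rnorm(10), frameRate = 0.125, stimFrequency = 0.125)
  expect_error(extractComponent(st), "fewer than 2 samples")
  st2 <- traceStack(rnorm(30), frameRate = 7.5, stimFrequency = 0.125)
  expect_error(extractComponent(st2), "full stimulus cycle")
  # incomplete trailing cycle is dropped: result equals the truncated sum
  x <- rnorm(75)
  full <- extractQuiet(traceStack(x[1:60], 7.5, 0.125))
  trunc <- suppressWarnings(extractComponent(traceStack(x, 7.5, 0.125)))
  expect_equal(responseCoef(trunc), responseCoef(full), tolerance = 1e-12)
})

test_that("magnitude error scales roughly as sigma*sqrt(2/T)", {
  # strong sinusoid + noise: the magnitude error is dominated by the
  # in-phase quadrature, whose sd is sigma*sqrt(2/T)
  sigma <- 2e-5; A <- 2e-4
  rmsAt <- function(T, seed) {
    set.seed(seed)
    t <- (0:(T - 1)) / 7.5
    sig <- A * cos(2 * pi * 0.125 * t)
    arr <- array(rep(sig, 24 * 24), dim = c(T, 24, 24)) +
      array(rnorm(T * 24 * 24, sd = sigma), dim = c(T, 24, 24))
    cm <- extractQuiet(stackFromArray(arr, 7.5, 0.125))
    sqrt(mean((Mod(responseCoef(cm)) - A)^2))
  }
  r60 <- rmsAt(60, 5); r240 <- rmsAt(240, 6); r960 <- rmsAt(960, 7)
  expect_equal(r60 / (sigma * sqrt(2 / 60)), 1, tolerance = 0.15)
  expect_equal(r240 / (sigma * sqrt(2 / 240)), 1, tolerance = 0.15)
  expect_equal(r960 / (sigma * sqrt(2 / 960)), 1, tolerance = 0.15)
  expect_equal(r60 / r240, 2, tolerance = 0.2)
})

test_that("magnitude and retinotopy conversions follow their formulas", {
  coefs <- matrix(3e-4 * exp(1i * pi / 3), 2, 2)
  cm <- new("ComplexResponseMap", coef = coefs, stimFrequency = 0.125,
            eye = "contra")
  expect_equal(mapValues(toMagnitude(cm))[1, 1], 3e-4)
  expect_equal(displayMagnitude(toMagnitude(cm))[1, 1], 3.0)
  expect_equal(mapValues(toMagnitude(
    new("ComplexResponseMap", coef = matrix(0i, 1, 1),
        stimFrequency = 0.125, eye = "ipsi")))[1, 1], 0)

  phaseMap <- function(phi) new("ComplexResponseMap",
    coef = matrix(1e-4 * exp(1i * phi), 1, 1),
    stimFrequency = 0.125, eye = "contra")
  expect_equal(mapValues(toRetinotopy(phaseMap(pi), 70))[1, 1], 35)
  expect_equal(mapValues(toRetinotopy(phaseMap(0), 70))[1, 1], 0)
  expect_equal(mapValues(toRetinotopy(phaseMap(-pi / 2), 70))[1, 1], 52.5)
  expect_error(toRetinotopy(phaseMap(0), -70), "positive")
})
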