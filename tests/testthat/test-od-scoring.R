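test_that("uniform smoothing behaves as a box filter", {
  const <- matrix(3.7, 10, 10)
  expect_equal(smoothUniform(const, 5L), const)
  # impulse of 25 spreads to a 5x5 plateau of 1 in the interior
  imp <- matrix(0, 11, 11); imp[6, 6] <- 25
  sm <- smoothUniform(imp, 5L)
  expect_equal(sm[4:8, 4:8], matrix(1, 5, 5))
  expect_equal(sum(sm), 25)
  # k = 1 is the identity
  m <- matrix(rnorm(36), 6, 6)
  expect_equal(smoothUniform(m, 1L), m)
  expect_error(smoothUniform(m, 4L), "odd")
})

test_that("responsive mask keeps pixels above the fractional peak", {
  m <- matrix(c(10, 4, 2, 1), 2, 2)
  expect_identical(responsiveMask(m, 0.30), matrix(c(TRUE, TRUE, FALSE, FALSE),
                                                   2, 2))
  expect_true(all(responsiveMask(matrix(5, 3, 3), 0.30)))
  distinct <- matrix(1:9, 3, 3)
  expect_identical(sum(responsiveMask(distinct, 0.999)), 1L)
  expect_error(responsiveMask(matrix(0, 3, 3)), "no responsive")
})

test_that("pixel ODI follows (C-I)/(C+I) with its invariants", {
  mask <- matrix(TRUE, 4, 4)
  C <- matrix(1.9e-4, 4, 4); I <- matrix(1.3e-4, 4, 4)
  expect_equal(mapValues(odiMap(C, I, mask))[mask], rep(0.1875, 16))
  expect_equal(mapValues(odiMap(C, C, mask))[mask], rep(0, 16))
  expect_equal(mapValues(odiMap(C, 0 * C, mask))[mask], rep(1, 16))

  set.seed(21)
  for (rep_ in 1:20) {
    Cr <- matrix(runif(25, 0, 4e-4), 5, 5)
    Ir <- matrix(runif(25, 0, 4e-4), 5, 5)
    msk <- matrix(runif(25) > 0.3, 5, 5)
    v <- mapValues(odiMap(Cr, Ir, msk))
    vm <- v[!is.na(v)]
    expect_true(all(vm >= -1 & vm <= 1))
    # scale invariance and antisymmetry
    expect_equal(mapValues(odiMap(3.7 * Cr, 3.7 * Ir, msk)), v)
    expect_equal(mapValues(odiMap(Ir, Cr, msk)), -v)
    # monotonic: increasing I strictly decreases every masked ODI
    v2 <- mapValues(odiMap(Cr, Ir + 1e-5, msk))
    expect_true(all(v2[!is.na(v2)] < vm))
  }
  expect_message(odiMap(0 * C, 0 * C, mask), "dropped")
  expect_error(odiMap(C, I[1:2, 1:2, drop = FALSE], mask), "shape")
})

test_that("mean ODI averages responsive pixels only", {
  mask <- matrix(TRUE, 2, 2)
  expect_equal(meanOdi(odiMap(matrix(2.5e-4, 2, 2), matrix(1.5e-4, 2, 2),
                              mask)), 0.25)
  v <- matrix(c(1, -1, 1, -1), 2, 2)
  om <- new("OdiMap", values = v, mask = mask)
  expect_equal(meanOdi(om), 0)
  empty <- new("OdiMap", values = v, mask = matrix(FALSE, 2, 2))
  expect_error(meanOdi(empty), "empty")
})

test_that("run-block inclusion applies the response-magnitude rule", {
  mk <- function(level, eye) new("MagnitudeMap",
                                 values = matrix(level, 12, 12), eye = eye)
  weak <- new("RunBlock", contraMap = mk(2e-4, "contra"),
              ipsiMap = mk(0.5e-4, "ipsi"), nRuns = 4L, included = NA,
              blockOdi = NA_real_)
  expect_message(weak <- blockOdi(weak), "excluded")
  expect_false(isIncluded(weak))
  expect_true(is.na(weak@blockOdi))

  ok <- new("RunBlock", contraMap = mk(2e-4, "contra"),
            ipsiMap = mk(2e-4, "ipsi"), nRuns = 4L, included = NA,
            blockOdi = NA_real_)
  ok <- blockOdi(ok)
  expect_true(isIncluded(ok))
  expect_equal(ok@blockOdi, 0)
})

test_that("block assembly groups runs in fours and drops remainders", {
  maps <- lapply(1:9, function(i) new("MagnitudeMap",
                                      values = matrix(i * 1e-4, 6, 6),
                                      eye = "contra"))
  imaps <- lapply(1:9, function(i) new("MagnitudeMap",
                                       values = matrix(1e-4, 6, 6),
                                       eye = "ipsi"))
  expect_warning(blocks <- makeRunBlocks(maps, imaps, 4L), "trailing")
  expect_length(blocks, 2)
  # block averages: runs 1-4 mean 2.5e-4, runs 5-8 mean 6.5e-4
  expect_equal(blocks[[1]]@contraMap@values[1, 1], 2.5e-4)
  expect_equal(blocks[[2]]@contraMap@values[1, 1], 6.5e-4)
  expect_error(makeRunBlocks(maps[1:2], imaps[1:2], 4L), "fewer runs")
})

test_that("animal summary averages included blocks only", {
  blk <- function(odi, inc) new("RunBlock",
    contraMap = new("MagnitudeMap", values = matrix(2e-4, 2, 2), eye = "contra"),
    ipsiMap = new("MagnitudeMap", values = matrix(2e-4, 2, 2), eye = "ipsi"),
    nRuns = 4L, included = inc, blockOdi = if (inc) odi else NA_real_)
  s <- animalSummary(list(blk(0.2, TRUE), blk(0.3, TRUE)))
  expect_equal(s@odi, 0.25)
  expect_equal(animalSummary(list(blk(0.27, TRUE)))@odi, 0.27)
  s2 <- animalSummary(list(blk(0.2, TRUE), blk(0.2, TRUE), blk(0.2, TRUE),
                           blk(0.9, FALSE)))
  expect_equal(s2@odi, 0.2)
  expect_message(s3 <- animalSummary(list(blk(0.9, FALSE))), "unscorable")
  expect_false(s3@scorable)
  expect_true(is.na(s3@odi))
})

test_that("noiseless pipeline recovers a designed ODI to 1e-6", {
  sc <- makeOdScene(0.1875, contraPeak = 1.9e-4, shape = c(32, 32))
  a <- simulateOdAnimal(sc, binnedRateAcq(c(32L, 32L), nCycles = 2L),
                        noiseSd = 0, seed = 1L)
  expect_true(a@scorable)
  expect_equal(a@odi, 0.1875, tolerance = 1e-6)
})
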