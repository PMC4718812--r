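test_that("significance stars match the conventional thresholds", {
  expect_identical(starsForP(c(0.04, 0.009, 0.0009, 0.06, 0.05, 0.01, 0.001)),
                   c("*", "**", "***", "", "", "*", "**"))
  expect_true(is.na(starsForP(NA_real_)))
})

test_that("assumption checks report normality and variance ratios", {
  set.seed(71)
  a <- rnorm(20); b <- rnorm(20, sd = 1)
  rep_ <- assumptionChecks(list(g1 = a, g2 = a))
  # identical samples: variance ratio F = 1, p = 1
  expect_equal(rep_$varianceRatio$F, 1)
  expect_equal(rep_$varianceRatio$p, 1)
  # heavily skewed sample is rejected at 0.05
  skew <- rlnorm(50, sdlog = 1.2)
  rep2 <- assumptionChecks(list(skewed = skew, normal = rnorm(50)))
  expect_lt(rep2$normality$p[rep2$normality$group == "skewed"], 0.05)
  expect_gt(rep2$normality$p[rep2$normality$group == "normal"], 0.001)
  # degenerate and tiny samples are flagged, not crashed
  rep3 <- assumptionChecks(list(const = rep(2, 5), tiny = c(1, 2)))
  expect_match(rep3$normality$flag[1], "constant")
  expect_match(rep3$normality$flag[2], "n < 3")
})

test_that("two-tailed t-test handles identical and degenerate samples", {
  x <- c(1, 2, 3, 4)
  res <- statsTable(twoTailedT(x, x))
  expect_equal(res$p.value, 1)
  expect_equal(res$statistic, 0)
  # zero pooled variance flags
  resEq <- twoTailedT(rep(2, 3), rep(2, 4))
  expect_match(resEq@notes, "zero pooled variance")
  expect_equal(statsTable(resEq)$p.value, 1)
  resNe <- twoTailedT(rep(2, 3), rep(5, 4))
  expect_equal(statsTable(resNe)$p.value, 0)
  expect_error(twoTailedT(1, c(1, 2)), "n >= 2")
})

test_that("t-test and one-way ANOVA agree for two groups", {
  set.seed(72)
  a <- rnorm(6, 1); b <- rnorm(5, 1.5)
  tt <- statsTable(twoTailedT(a, b))
  an <- statsTable(onewayAnovaBonferroni(list(a = a, b = b)))
  omni <- an[an$test == "one-way ANOVA", ]
  expect_equal(omni$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(omni$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("Bonferroni adjustment multiplies raw p by the comparison count", {
  set.seed(73)
  gs <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  res <- statsTable(onewayAnovaBonferroni(gs))
  pw <- res[res$test == "pairwise t", ]
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p.adjusted, pmin(1, pw$p.value * 3))
  # identical groups: omnibus F = 0, p = 1
  x <- c(1, 2, 3)
  resId <- statsTable(onewayAnovaBonferroni(list(a = x, b = x, c = x)))
  expect_equal(resId$p.value[resId$test == "one-way ANOVA"], 1)
  expect_error(onewayAnovaBonferroni(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("paper-scale ODI contrast is detected in nearly every replicate", {
  # group dispersions like imaged ODI data: 0.27 +/- 0.07 (n=6)
  # vs 0.02 +/- 0.02 (n=5), sd scale chosen so SEMs match the reported ones
  hits <- 0L
  nRep <- 50L
  set.seed(74)
  for (r in seq_len(nRep)) {
    a <- rnorm(6, 0.27, 0.07)
    b <- rnorm(5, 0.02, 0.02)
    p <- statsTable(twoTailedT(a, b))$p.value
    hits <- hits + (p < 0.001)
  }
  expect_gte(hits / nRep, 0.95)
})

test_that("repeated-measures ANOVA separates ramping from flat cohorts", {
  mkCohort <- function(seed) {
    set.seed(seed)
    days <- 0:7
    do.call(rbind, lapply(1:10, function(s) {
      md <- s <= 5
      mu <- if (md) 0.37 + (0.46 - 0.37) * days / 7 else rep(0.37, 8)
      data.frame(subject = sprintf("s%02d", s),
                 group = if (md) "MD" else "noMD", day = days,
                 value = mu + rnorm(8, sd = 0.005))
    }))
  }
  res <- statsTable(rmTwowayAnovaBonferroni(mkCohort(75)))
  expect_lt(res$p.value[res$comparison == "group:day"], 0.001)
  expect_lt(res$p.value[res$comparison == "day (within)"], 0.001)
  # day-7 cellwise contrast is Bonferroni-significant
  d7 <- res[res$comparison == "day 7: MD vs noMD", ]
  expect_lt(d7$p.adjusted, 0.001)
  expect_identical(d7$stars, "***")
})

test_that("repeated-measures ANOVA rejects unbalanced grids and handles degenerate days", {
  tab <- data.frame(subject = rep(c("s1", "s2"), each = 3),
                    group = "g", day = rep(0:2, 2),
                    value = rnorm(6))
  bad <- tab[-2, ]
  expect_error(rmTwowayAnovaBonferroni(bad), "unbalanced")
  # single group, two identical days: no day effect at all
  same <- data.frame(subject = rep(c("s1", "s2", "s3"), each = 2),
                     group = "g", day = rep(0:1, 3),
                     value = rep(c(1.0, 1.2, 0.9), each = 2))
  res <- statsTable(rmTwowayAnovaBonferroni(same))
  expect_equal(res$p.value[res$comparison == "day (within)"], 1)
})
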