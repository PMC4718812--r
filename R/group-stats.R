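#' Significance stars
#'
#' The conventional star code: `***` p < 0.001, `**` p < 0.01, `*`
#' p < 0.05, `""` otherwise (ns).
#'
#' @param p numeric p-values
#' @return character vector of stars
#' @export
starsForP <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

.statsRow <- function(test, comparison, statistic, df, p, pAdj = NA_real_,
                      method = "none") {
  data.frame(test = test, comparison = comparison, statistic = statistic,
             df = df, p.value = p, p.adjusted = pAdj, adjust.method = method,
             stars = starsForP(if (is.na(pAdj)) p else pAdj),
             stringsAsFactors = FALSE)
}

#' Distributional assumption checks
#'
#' Advisory checks run before the main battery: Shapiro-Wilk normality
#' per group (needs n >= 3 and non-constant data, otherwise flagged and
#' skipped) and the pairwise F-test for equality of variances. The
#' battery does not branch on the outcomes; the results are reported
#' as-is.
#'
#' @param samples named list of numeric vectors, one per group
#' @return list with data.frames `normality` (group, n, W, p, flag) and
#'   `varianceRatio` (group1, group2, F, p)
#' @export
assumptionChecks <- function(samples) {
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group", seq_along(samples))
  normality <- do.call(rbind, lapply(names(samples), function(g) {
    x <- samples[[g]]
    if (length(x) < 3L)
      return(data.frame(group = g, n = length(x), W = NA_real_, p = NA_real_,
                        flag = "n < 3: normality not testable"))
    if (stats::sd(x) == 0)
      return(data.frame(group = g, n = length(x), W = NA_real_, p = NA_real_,
                        flag = "constant sample: degenerate"))
    sw <- stats::shapiro.test(x)
    data.frame(group = g, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, flag = "")
  }))
  pairs <- if (length(samples) >= 2) utils::combn(names(samples), 2) else
    matrix(character(0), nrow = 2)
  varianceRatio <- if (ncol(pairs)) do.call(rbind, lapply(seq_len(ncol(pairs)),
    function(j) {
      a <- samples[[pairs[1, j]]]; b <- samples[[pairs[2, j]]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0)
        return(data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
                          F = NA_real_, p = NA_real_))
      vt <- stats::var.test(a, b)
      data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
                 F = unname(vt$statistic), p = vt$p.value)
    })) else data.frame(group1 = character(0), group2 = character(0),
                        F = numeric(0), p = numeric(0))
  list(normality = normality, varianceRatio = varianceRatio)
}

#' Two-tailed two-sample t-test
#'
#' Classical pooled-variance two-sample t-test (two-tailed). A zero
#' pooled variance is flagged: equal means give t = 0, p = 1;
#' different means give an infinite statistic and p = 0.
#'
#' @param a,b numeric samples (each n >= 2)
#' @param labels comparison labels
#' @return a [StatsResult-class]
#' @export
twoTailedT <- function(a, b, labels = c("a", "b")) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  cmp <- paste(labels, collapse = " vs ")
  notes <- character(0)
  pooledVar <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooledVar == 0) {
    notes <- "zero pooled variance"
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      row <- .statsRow("t-test", cmp, 0, length(a) + length(b) - 2, 1)
    } else {
      row <- .statsRow("t-test", cmp, Inf, length(a) + length(b) - 2, 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    row <- .statsRow("t-test", cmp, unname(tt$statistic),
                     unname(tt$parameter), tt$p.value)
  }
  new("StatsResult", results = row,
      method = "Two-tailed two-sample t-test (pooled variance)",
      notes = notes)
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus one-way ANOVA across the groups followed by all pairwise
#' two-sample t-tests whose p-values are Bonferroni-adjusted (raw p
#' times the number of comparisons, capped at 1). With two groups the
#' omnibus F equals the squared pooled t statistic.
#'
#' @param groups named list of numeric samples (>= 2 groups, each
#'   n >= 2)
#' @return a [StatsResult-class]: first row the omnibus F, then one row
#'   per pairwise comparison
#' @export
onewayAnovaBonferroni <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("every group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 1L))))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  omni <- .statsRow("one-way ANOVA", paste(names(groups), collapse = ", "),
                    an[1, "F value"], an[1, "Df"], an[1, "Pr(>F)"])
  pairs <- utils::combn(names(groups), 2)
  k <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(k), function(j) {
    r <- statsTable(twoTailedT(groups[[pairs[1, j]]], groups[[pairs[2, j]]],
                               labels = pairs[, j]))
    r$p.adjusted <- min(1, r$p.value * k)
    r$adjust.method <- "bonferroni"
    r$test <- "pairwise t"
    r$stars <- starsForP(r$p.adjusted)
    r
  }))
  new("StatsResult", results = rbind(omni, pw),
      method = sprintf(
        "One-way ANOVA + %d pairwise comparisons, Bonferroni correction", k),
      notes = character(0))
}

#' Repeated-measures two-way ANOVA with Bonferroni correction
#'
#' The time-course analysis: a two-way ANOVA with repeated measures on
#' day (between-subject factor `group`, within-subject factor `day`,
#' subject as the blocking factor), reporting the group and day main
#' effects and their interaction, followed by Bonferroni-corrected
#' between-group comparisons at each day (correction over all
#' day-by-pair cells). Requires a complete, balanced day grid per
#' subject. Sphericity is not corrected; this is flagged in the notes.
#'
#' @param table long-format data.frame with columns subject, group,
#'   day, value
#' @return a [StatsResult-class]
#' @export
rmTwowayAnovaBonferroni <- function(table) {
  need <- c("subject", "group", "day", "value")
  if (!all(need %in% names(table))) stop("table needs subject, group, day, value")
  table$subject <- factor(table$subject)
  table$group <- factor(table$group)
  table$dayF <- factor(table$day)
  grid <- table(table$subject, table$dayF)
  if (any(grid != 1L)) {
    bad <- which(grid != 1L, arr.ind = TRUE)
    stop("unbalanced day grid; offending subject x day cells: ",
         paste(sprintf("%s@day%s", rownames(grid)[bad[, 1]],
                       colnames(grid)[bad[, 2]]), collapse = ", "))
  }
  pick <- function(tab, name, col) {
    tab[match(name, trimws(rownames(tab))), col]
  }
  nGroups <- nlevels(table$group)
  if (nGroups > 1) {
    fit <- stats::aov(value ~ group * dayF + Error(subject), data = table)
    sfit <- summary(fit)
    between <- sfit[["Error: subject"]][[1]]
    within <- sfit[["Error: Within"]][[1]]
    rows <- rbind(
      .statsRow("RM ANOVA", "group (between)", pick(between, "group", "F value"),
                pick(between, "group", "Df"), pick(between, "group", "Pr(>F)")),
      .statsRow("RM ANOVA", "day (within)", pick(within, "dayF", "F value"),
                pick(within, "dayF", "Df"), pick(within, "dayF", "Pr(>F)")),
      .statsRow("RM ANOVA", "group:day", pick(within, "group:dayF", "F value"),
                pick(within, "group:dayF", "Df"), pick(within, "group:dayF", "Pr(>F)")))
    days <- levels(table$dayF)
    pairs <- utils::combn(levels(table$group), 2)
    k <- length(days) * ncol(pairs)
    cellRows <- do.call(rbind, lapply(days, function(d) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        a <- table$value[table$dayF == d & table$group == pairs[1, j]]
        b <- table$value[table$dayF == d & table$group == pairs[2, j]]
        r <- statsTable(twoTailedT(a, b, labels = pairs[, j]))
        r$comparison <- sprintf("day %s: %s", d, r$comparison)
        r$p.adjusted <- min(1, r$p.value * k)
        r$adjust.method <- "bonferroni"
        r$test <- "cellwise t"
        r$stars <- starsForP(r$p.adjusted)
        r
      }))
    }))
    rows <- rbind(rows, cellRows)
  } else {
    # degenerate: no within-subject variation across days at all
    scale <- max(abs(table$value), 1e-300)
    flat <- all(abs(stats::ave(table$value, table$subject) - table$value) <
                  1e-12 * scale)
    if (flat) {
      rows <- .statsRow("RM ANOVA", "day (within)", 0, nlevels(table$dayF) - 1, 1)
    } else {
      fit <- stats::aov(value ~ dayF + Error(subject), data = table)
      within <- summary(fit)[["Error: Within"]][[1]]
      rows <- .statsRow("RM ANOVA", "day (within)", pick(within, "dayF", "F value"),
                        pick(within, "dayF", "Df"), pick(within, "dayF", "Pr(>F)"))
    }
  }
  new("StatsResult", results = rows,
      method = "Two-way repeated-measures ANOVA + Bonferroni cellwise comparisons",
      notes = "sphericity not corrected")
}
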