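test_that("identical pre and post measurements mean no change", {
  tab <- tinyCohort(shift = 0, noiseSd = 0)
  res <- pairedPrePostTest(tab, "EDmw", "g1")
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_true(is.na(res$statistic))
})

test_that("a large systematic shift is detected", {
  tab <- tinyCohort(shift = 10, noiseSd = 0.5)
  res <- pairedPrePostTest(tab, "EDmw", "g1")
  expect_lt(res$p_value, 0.01)
  expect_true(res$significant)
})

test_that("missing timepoints are reported with the animal ids", {
  tab <- tinyCohort()
  tab <- tab[!(tab$animal_id == "a2" & tab$timepoint == "post"), ]
  expect_error(pairedPrePostTest(tab, "EDbv", "g1"), "a2")
})

test_that("the paired test agrees with exact sign-flip enumeration", {
  set.seed(61)
  for (i in 1:5) {
    d <- round(stats::rnorm(8, mean = stats::runif(1, 0, 1.5)), 2)
    pT <- stats::t.test(d)$p.value
    ids <- paste0("m", seq_along(d))
    tab <- rbind(
      data.frame(animal_id = ids, group = "g", timepoint = "pre",
                 EDbv = 40, ESbv = 10, EDmv = 80, EDmw = 50, LVWT = 700,
                 EF = 70, HW = 1, BW = 1, CSA = 1),
      data.frame(animal_id = ids, group = "g", timepoint = "post",
                 EDbv = 40, ESbv = 10, EDmv = 80, EDmw = 50 + d, LVWT = 700,
                 EF = 70, HW = 1, BW = 1, CSA = 1))
    res <- pairedPrePostTest(tab, "EDmw", "g")
    expect_equal(res$p_value, pT, tolerance = 1e-12)
    expect_lt(abs(res$p_value - signFlipP(d)), 0.02)
  }
})

test_that("the four-group ANOVA agrees with a label-permutation oracle", {
  set.seed(62)
  values <- round(c(stats::rnorm(6, 10), stats::rnorm(6, 10.8),
                    stats::rnorm(6, 9.6), stats::rnorm(6, 10.4)), 2)
  groups <- rep(c("A", "B", "C", "D"), each = 6)
  res <- groupwiseAnova(values = values, groups = groups)
  pAnova <- res$p_value[res$kind == "anova"]
  expect_lt(abs(pAnova - permAnovaP(values, factor(groups))), 0.02)
})

test_that("Bonferroni adjustment multiplies by the pair count and caps at 1", {
  set.seed(63)
  values <- stats::rnorm(24)
  groups <- rep(c("A", "B", "C", "D"), each = 6)
  res <- groupwiseAnova(values = values, groups = groups)
  pw <- res[res$kind == "between_groups", ]
  expect_equal(nrow(pw), 6L)
  expect_equal(pw$adjusted_p, pmin(1, pw$p_value * 6), tolerance = 1e-12)
  expect_true(all(pw$adjusted_p >= pw$p_value))
  expect_true(all(pw$adjusted_p <= 1))
  # 0.02 raw with 6 pairs -> 0.12, not significant
  expect_false(min(1, 0.02 * 6) < 0.05)
})

test_that("duplicated identical groups give a null ANOVA result", {
  set.seed(64)
  base <- stats::rnorm(8, 10)
  values <- c(base, base)
  groups <- rep(c("A", "B"), each = 8)
  res <- groupwiseAnova(values = values, groups = groups)
  expect_gt(res$p_value[res$kind == "anova"], 0.99)
  expect_false(any(res$significant))
})

test_that("zero deltas yield no significance anywhere", {
  tab <- tinyCohort(shift = 0, noiseSd = 0)
  res <- deltaAnalysis(tab, "EDmw")
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
})

test_that("group relabeling permutes comparisons without changing p values", {
  tab <- simulateCohort(cohortSpec(groupSizes = c(saline = 5L, AngII = 5L,
                                                  sRAGE = 5L), seed = 65L))
  res1 <- deltaAnalysis(tab, "EDmw")
  relabeled <- tab
  map <- c(saline = "zz", AngII = "aa", sRAGE = "mm")
  relabeled$group <- unname(map[tab$group])
  res2 <- deltaAnalysis(relabeled, "EDmw")
  key1 <- res1[res1$kind != "anova", ]
  key2 <- res2[res2$kind != "anova", ]
  canon <- function(g, m) {
    parts <- sort(unname(m[strsplit(g, "|", fixed = TRUE)[[1]]]))
    paste(parts, collapse = "|")
  }
  key1$groups <- vapply(key1$groups, canon, "", m = map)
  key2$groups <- vapply(key2$groups, canon, "",
                        m = stats::setNames(unname(map), unname(map)))
  ord1 <- order(key1$groups); ord2 <- order(key2$groups)
  expect_equal(key1$p_value[ord1], key2$p_value[ord2], tolerance = 1e-12)
})

test_that("collinear points give a perfect fit with collapsed bands", {
  x <- 1:6
  res <- olsWithBands(x, 2.5 * x + 1)
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_equal(res$rSquared, 1, tolerance = 1e-9)
  expect_equal(res$bands$confLo, res$bands$fit, tolerance = 1e-6)
  expect_equal(res$bands$predHi, res$bands$fit, tolerance = 1e-6)
  expect_error(olsWithBands(rep(2, 5), stats::rnorm(5)), "constant")
})

test_that("prediction bands contain confidence bands, narrowest at the mean", {
  set.seed(66)
  x <- stats::runif(25, 0, 10)
  y <- 1.5 * x + stats::rnorm(25, 0, 2)
  newx <- seq(-5, 15, length.out = 101)
  res <- olsWithBands(x, y, newx = newx)
  b <- res$bands
  expect_true(all(b$predLo < b$confLo))
  expect_true(all(b$predHi > b$confHi))
  # symmetric about the fitted line
  expect_equal(b$confHi - b$fit, b$fit - b$confLo, tolerance = 1e-9)
  expect_equal(b$predHi - b$fit, b$fit - b$predLo, tolerance = 1e-9)
  width <- b$confHi - b$confLo
  expect_equal(newx[which.min(width)], newx[which.min(abs(newx - mean(x)))])
  # closed-form check of the band half-widths
  n <- res$n; s <- sqrt(sum((y - (res$intercept + res$slope * x))^2) / (n - 2))
  sxx <- sum((x - mean(x))^2)
  tq <- stats::qt(0.975, n - 2)
  half <- tq * s * sqrt(1 / n + (newx - mean(x))^2 / sxx)
  expect_equal(b$confHi - b$fit, half, tolerance = 1e-9)
  halfP <- tq * s * sqrt(1 + 1 / n + (newx - mean(x))^2 / sxx)
  expect_equal(b$predHi - b$fit, halfP, tolerance = 1e-9)
})

test_that("95 percent prediction bands cover fresh observations", {
  set.seed(67)
  inside <- 0L; total <- 0L
  for (i in 1:40) {
    x <- stats::runif(39, 80, 130)
    y <- 1.2 * x + stats::rnorm(39, 0, 8)
    res <- olsWithBands(x, y, newx = x)
    yNew <- 1.2 * x + stats::rnorm(39, 0, 8)
    inside <- inside + sum(yNew >= res$bands$predLo &
                           yNew <= res$bands$predHi)
    total <- total + 39L
  }
  expect_equal(inside / total, 0.95, tolerance = 0.02)
})

test_that("regression recovers a programmed correlation at the study size", {
  set.seed(68)
  rs <- replicate(60, {
    x <- stats::rnorm(39)
    y <- 0.79 * x + sqrt(1 - 0.79^2) * stats::rnorm(39)
    olsWithBands(x, y)$r
  })
  expect_lt(abs(mean(rs) - 0.79), 0.05)
  expect_true(all(abs(rs - 0.79) < 0.3))
})

test_that("cohort summaries report mean and SD in the canonical layout", {
  gs <- referenceGroupStats(); gs$sd <- 0
  tab <- simulateCohort(cohortSpec(groupStats = gs, seed = 69L))
  sm <- summarizeCohort(tab)
  expect_identical(
    names(sm),
    c("group", "timepoint", "n",
      as.vector(rbind(paste0(lvParameterNames(), "_mean"),
                      paste0(lvParameterNames(), "_sd")))))
  expect_true(all(sm[paste0(lvParameterNames(), "_sd")] == 0))
  angII <- sm[sm$group == "AngII" & sm$timepoint == "post", ]
  expect_equal(angII$EDmw_mean, 118.0)
  expect_equal(angII$LVWT_mean, 813.5)
  expect_equal(sm$timepoint[1:2], c("pre", "post"))
})

test_that("the unpaired variant compares the two timepoint sets", {
  tab <- tinyCohort(shift = 10, noiseSd = 0.5)
  res <- pairedPrePostTest(tab, "EDmw", "g1", paired = FALSE)
  pre <- tab[tab$timepoint == "pre" & tab$group == "g1", "EDmw"]
  post <- tab[tab$timepoint == "post" & tab$group == "g1", "EDmw"]
  expect_equal(res$p_value, stats::t.test(post, pre)$p.value,
               tolerance = 1e-12)
})
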