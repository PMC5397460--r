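test_that("confusion metrics at the score >= 3 cutoff behave at the extremes", {
  perfect <- ordinalCounts(c(0, 0, 0, 50), c(80, 0, 0, 0))
  cm <- confusionMetrics(perfect)
  expect_equal(unname(cm$percent), c(100, 100, 100, 100))
  # zero denominators flag NaN instead of erroring
  noneg <- ordinalCounts(c(0, 0, 10, 10), c(0, 0, 0, 0))
  cm2 <- confusionMetrics(noneg)
  expect_true(is.nan(cm2$fraction[["specificity"]]))
  expect_equal(cm2$percent[["sensitivity"]], 100)
})

test_that("the cutoff is inclusive and respects the four-point scale", {
  cnt <- ordinalCounts(c(5, 5, 5, 5), c(5, 5, 5, 5))
  cm <- confusionMetrics(cnt, cutoff = 3)
  expect_equal(unname(cm$counts), c(TP = 10, FP = 10, TN = 10, FN = 10),
               ignore_attr = TRUE)
  cm4 <- confusionMetrics(cnt, cutoff = 4)
  expect_equal(cm4$counts[["TP"]], 5)
})

test_that("empirical AUC equals brute-force pairwise comparison", {
  set.seed(41)
  for (i in 1:50) {
    cnt <- randomCountTable()
    expect_equal(empiricalAuc(cnt)$auc, bruteForceAuc(cnt),
                 tolerance = 1e-12)
  }
})

test_that("AUC is 0.5 for exchangeable classes and errors on empty ones", {
  same <- ordinalCounts(c(3, 7, 5, 1), c(6, 14, 10, 2))
  expect_equal(empiricalAuc(same)$auc, 0.5)
  expect_error(empiricalAuc(ordinalCounts(c(0, 0, 0, 0), c(1, 2, 3, 4))),
               "empty")
})

test_that("AUC equals the trapezoidal area under its own ROC points", {
  set.seed(42)
  for (i in 1:25) {
    cnt <- randomCountTable()
    res <- empiricalAuc(cnt)
    roc <- res$roc
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                 utils::tail(roc$tpr, -1)) / 2)
    expect_equal(res$auc, trap, tolerance = 1e-12)
    expect_equal(roc$fpr[c(1, 5)], c(0, 1))
    expect_equal(roc$tpr[c(1, 5)], c(0, 1))
  }
})

test_that("equivocal judgments count scores 2 and 3 over both classes", {
  cnt <- ordinalCounts(c(10, 20, 30, 40), c(1, 2, 3, 4))
  eq <- equivocalSummary(cnt)
  expect_equal(eq$count, 20 + 30 + 2 + 3)
  expect_equal(eq$percent, round(100 * 55 / 110))
  none <- equivocalSummary(ordinalCounts(c(5, 0, 0, 5), c(7, 0, 0, 3)))
  expect_equal(none$count, 0)
  expect_equal(none$percent, 0)
})

test_that("weighted kappa: perfect agreement, chance agreement, bounds", {
  diagTab <- diag(c(10, 20, 30, 40))
  k <- weightedKappa(diagTab)
  expect_equal(k$kappa, 1)
  expect_identical(k$band, "almost perfect agreement")
  # a table equal to its own margin product has kappa exactly 0
  p <- c(0.1, 0.2, 0.3, 0.4)
  chance <- outer(p, p) * 100
  expect_equal(weightedKappa(chance)$kappa, 0, tolerance = 1e-12)
  expect_true(is.nan(weightedKappa(diag(c(50, 0, 0, 0)))$kappa))
})

test_that("weighted kappa matches the direct double sum on random tables", {
  set.seed(43)
  for (i in 1:40) {
    tab <- matrix(rpois(16, 4), 4, 4)
    if (sum(tab) == 0) next
    expect_equal(weightedKappa(tab, "linear")$kappa, doubleSumKappa(tab),
                 tolerance = 1e-12)
    expect_equal(weightedKappa(tab, "quadratic")$kappa,
                 doubleSumKappa(tab, quadratic = TRUE), tolerance = 1e-12)
    expect_lte(weightedKappa(tab)$kappa, 1)
  }
})

test_that("weighted kappa is invariant under reversing the scale for both readers", {
  set.seed(44)
  tab <- matrix(rpois(16, 5) + 1, 4, 4)
  rev2 <- tab[4:1, 4:1]
  expect_equal(weightedKappa(tab)$kappa, weightedKappa(rev2)$kappa,
               tolerance = 1e-12)
})

test_that("kappa interpretation bands partition [0,1]", {
  expect_identical(kappaAgreementBand(0), "poor agreement")
  expect_identical(kappaAgreementBand(0.15), "slight agreement")
  expect_identical(kappaAgreementBand(0.30), "fair agreement")
  expect_identical(kappaAgreementBand(0.50), "moderate agreement")
  expect_identical(kappaAgreementBand(0.72), "substantial agreement")
  expect_identical(kappaAgreementBand(0.90), "almost perfect agreement")
})

test_that("paired t test matches the closed form and flags degeneracy", {
  a <- c(241, 250, 230, 260, 245)
  b <- c(225, 240, 228, 250, 230)
  d <- a - b
  tManual <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  pManual <- 2 * stats::pt(-abs(tManual), df = length(d) - 1)
  res <- pairedTBonferroni(a, b, nComparisons = 3)
  expect_equal(res$t, tManual, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, pManual, tolerance = 1e-12)
  expect_equal(res$pAdjusted, min(1, 3 * pManual), tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  same <- pairedTBonferroni(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant nonzero shift has zero variance: flagged, not crashed
  shift <- pairedTBonferroni(a, a + 5)
  expect_true(shift$degenerate)
  expect_true(is.nan(shift$t))
})

test_that("AUC comparison: identical paired scores give p = 1, bootstrap is seeded", {
  set.seed(45)
  truth <- syntheticTruth(40, 60)
  s <- simulateReaders(truth, c(m = 1), nReaders = 1, seed = 9)
  p1 <- compareAuc(s, s, paired = TRUE, nBoot = 200, seed = 3)
  expect_equal(p1$p, 1)
  s2 <- simulateReaders(truth, c(m = 2), nReaders = 1, seed = 10)
  r1 <- compareAuc(s, s2, paired = TRUE, nBoot = 200, seed = 3)
  r2 <- compareAuc(s, s2, paired = TRUE, nBoot = 200, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_error(compareAuc(scoresToCounts(s), scoresToCounts(s2),
                          paired = TRUE), "per-lesion")
})

test_that("widely separated AUCs at large n give a tiny unpaired p", {
  weak <- ordinalCounts(c(200, 200, 200, 200), c(220, 200, 190, 190))
  strong <- ordinalCounts(c(10, 30, 260, 500), c(700, 80, 15, 5))
  res <- compareAuc(weak, strong)
  expect_lt(res$p, 0.001)
  expect_match(res$method, "tie-corrected")
  # equal counts: p = 1 under the normal test too
  eq <- compareAuc(weak, weak)
  expect_equal(eq$p, 1)
})

test_that("score CSV validation names the offending row", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(lesion_id = 1:3, truth = c("malignant", "benign", "benign"),
                   reader = 1, modality = "m", score = c(1, 5, 2))
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(readScores(f), "row 2")
  df$score <- c(1, 4, 2)
  df$truth[3] <- "unsure"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(readScores(f), "row 3")
  utils::write.csv(df[0, ], f, row.names = FALSE)
  expect_error(readScores(f), "empty")
})

test_that("scores collapse to counts and cross-tabs correctly", {
  truth <- syntheticTruth(30, 50)
  s <- simulateReaders(truth, c(a = 1, b = 2), nReaders = 2, seed = 11)
  cnt <- scoresToCounts(s, reader = 1, modality = "a")
  expect_equal(sum(cnt@malignant), 30)
  expect_equal(sum(cnt@benign), 50)
  xt <- readerCrossTab(s, "b")
  expect_equal(sum(xt), 80)
  # margins match the per-reader score tallies
  s1 <- s[s$modality == "b" & s$reader == 1, ]
  expect_equal(rowSums(xt), unname(table(factor(s1$score, 1:4))),
               ignore_attr = TRUE)
})
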