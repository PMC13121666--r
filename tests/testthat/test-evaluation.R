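# ROC/AUROC, DeLong variance/test, threshold metrics, Hosmer-Lemeshow
# calibration and decision curves — against hand-computed values, an O(n^2)
# pairwise oracle, pROC as an independent library cross-check, and the
# documented algebraic identities.

test_that("AUROC matches the hand-enumerated example and its edge cases", {
  out <- roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(out$auc, 0.75)                 # 3 of 4 positive-negative pairs
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  # curve endpoints
  expect_equal(out$roc$sensitivity[1], 0)
  expect_equal(out$roc$specificity[1], 1)
})

test_that("AUROC equals the pairwise-count oracle and is monotone invariant", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(8:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), sample(0:2, 1))      # rounding induces ties
    expect_equal(roc_auc(s, y)$auc, oracle_auc(s, y), label = sprintf("seed %d", seed))
    expect_equal(roc_auc(exp(2 * s) + 1, y)$auc, roc_auc(s, y)$auc)
  }
})

test_that("AUROC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rbinom(120, 1, 0.4)
  s <- rnorm(120) + y
  ours <- delong_variance_ci(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci, ref_ci[c(1, 3)], tolerance = 1e-9)
})

test_that("DeLong variance shrinks under duplication and the CI clips at 1", {
  set.seed(3)
  y <- rep(c(1, 0), each = 20)
  s <- c(rnorm(20, 2), rnorm(20, 0))
  v1 <- delong_variance_ci(s, y)
  v2 <- delong_variance_ci(c(s, s), c(y, y))
  expect_lt(v2$variance, v1$variance)

  sep <- delong_variance_ci(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(sep$ci[2], 1)
  expect_true(sep$degenerate)
})

test_that("the paired DeLong test honors its identities and matches pROC", {
  set.seed(4)
  y <- rbinom(60, 1, 0.5)
  a <- rnorm(60) + y
  expect_equal(delong_test(a, a, y)$p, 1)
  expect_equal(delong_test(a, plogis(3 * a - 1), y)$p, 1)  # monotone transform

  skip_if_not_installed("pROC")
  b <- rnorm(60) + 0.5 * y
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(ours$z), unname(as.numeric(ref$statistic)), tolerance = 1e-9)
})

test_that("paired DeLong p stays within 0.05 of a stratified bootstrap oracle", {
  set.seed(5)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  a <- rnorm(n) + 0.8 * y
  b <- 0.6 * a + rnorm(n) * 0.8
  p_delong <- delong_test(a, b, y)$p
  p_boot <- oracle_bootstrap_delong_p(a, b, y, B = 4000, seed = 6)
  expect_lt(abs(p_delong - p_boot), 0.05)
})

test_that("threshold metrics reproduce the hand confusion matrix", {
  scores <- c(rep(0.9, 8), rep(0.1, 2),    # positives: 8 TP / 2 FN
              rep(0.2, 9), 0.8)            # negatives: 9 TN / 1 FP
  labels <- rep(c("GB", "SBM"), each = 10)
  m <- threshold_metrics(scores, labels, 0.5)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["ppv"]), 8 / 9)
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.9)

  hi <- threshold_metrics(scores, labels, 2)   # above every score
  expect_equal(unname(hi["sensitivity"]), 0)
  expect_equal(unname(hi["specificity"]), 1)
  expect_true(is.na(hi["ppv"]))                # zero denominator -> NA

  perfect <- threshold_metrics(c(1, 1, 0, 0), c("GB", "GB", "SBM", "SBM"), 0.5)
  expect_true(all(perfect == 1))
})

test_that("Hosmer-Lemeshow matches the two-bin hand computation and is order invariant", {
  hl <- calibration_hosmer_lemeshow(c(0.2, 0.2, 0.8, 0.8), c(0, 0, 1, 1), g = 2)
  expect_equal(hl$statistic, 1.0)              # 0.5 + 0.5 by hand

  set.seed(6)
  p <- runif(300); yy <- rbinom(300, 1, p)
  h1 <- calibration_hosmer_lemeshow(p, yy)
  o <- sample(300)
  h2 <- calibration_hosmer_lemeshow(p[o], yy[o])
  expect_equal(h1$statistic, h2$statistic)
  expect_equal(h1$p, h2$p)
})

test_that("the HL statistic has its chi-squared null under perfect calibration", {
  # for exogenous (not refitted) probabilities the grouped Pearson statistic
  # is asymptotically chi-squared on g degrees of freedom; the reported
  # p-value keeps the standard in-sample g-2 convention
  set.seed(7)
  stats_g <- vapply(1:150, function(i) {
    p <- runif(2000, 0.05, 0.95)
    y <- rbinom(2000, 1, p)
    h <- calibration_hosmer_lemeshow(p, y)
    pchisq(h$statistic, df = nrow(h$bins), lower.tail = FALSE)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(stats_g, "punif")$p.value), 0.01)
  # and HL/n vanishes for a calibrated model at large n
  p <- runif(10000, 0.05, 0.95); y <- rbinom(10000, 1, p)
  expect_lt(calibration_hosmer_lemeshow(p, y)$statistic / 10000, 0.005)
})

test_that("decision curves satisfy the treat-all/treat-none identities", {
  set.seed(8)
  y <- rep(c("GB", "SBM"), c(30, 70))
  p <- ifelse(y == "GB", 1, 0)     # perfect classifier, probs in {0, 1}
  dc <- decision_curve(p, y, thresholds = c(0.1, 0.3, 0.5, 0.7))
  expect_true(all(abs(dc$nb_model - 0.3) < 1e-12))   # NB = prevalence, all t < 1
  expect_true(all(dc$nb_none == 0))
  # treat-all crosses zero at the prevalence
  dc2 <- decision_curve(runif(100), y, thresholds = 0.3)
  expect_equal(dc2$nb_all, 0, tolerance = 1e-12)   # pi = 0.3 exactly

  # uninformative constant classifier: equals treat-all below 0.5, none above
  pc <- rep(0.5, 100)
  dc3 <- decision_curve(pc, y, thresholds = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(dc3$nb_model[dc3$threshold < 0.5], dc3$nb_all[dc3$threshold < 0.5])
  expect_equal(dc3$nb_model[dc3$threshold > 0.5], c(0, 0))
})

test_that("evaluate_models emits the full table schema for the fixture run", {
  res <- fixture_pipeline()
  tab <- res$evaluation$table
  expect_equal(nrow(tab), 7 * 3)               # 7 models x 3 datasets
  expect_setequal(unique(tab$model),
                  c("habitat_h1", "habitat_h2", "habitat_h3", "habitat",
                    "radiomics", "clinical", "combined"))
  expect_setequal(unique(tab$dataset), c("training", "validation", "test"))
  expect_named(tab, c("model", "dataset", "accuracy", "auroc", "ci_lower",
                      "ci_upper", "sensitivity", "specificity", "ppv", "npv"))
  expect_true(all(tab$ci_lower <= tab$auroc + 1e-9))
  expect_true(all(tab$auroc <= tab$ci_upper + 1e-9))
  ok <- !is.na(tab$sensitivity)
  expect_true(all(tab$sensitivity[ok] >= 0 & tab$sensitivity[ok] <= 1))
  # DeLong matrix per dataset is symmetric with unit diagonal convention
  dl <- res$evaluation$delong$validation
  expect_equal(dim(dl), c(7, 7))
  expect_equal(dl, t(dl))
})
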