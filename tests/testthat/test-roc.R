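test_that("AUC is the Mann-Whitney pair-counting estimator", {
  s <- c(1, 2, 3, 2.5, 4)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(roc_auc(s, lab, direction = "higher_is_case"), 5 / 6)
  expect_equal(roc_auc(-s, lab, direction = "lower_is_case"), 5 / 6)
  # perfectly separated
  expect_equal(roc_auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE),
                       direction = "higher_is_case"), 1)
  # all ties
  expect_equal(roc_auc(rep(3, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                       direction = "higher_is_case"), 0.5)
  # invariance under strictly monotone transforms; direction reversal
  set.seed(4)
  x <- rnorm(30)
  lab <- rep(c(TRUE, FALSE), 15)
  a <- roc_auc(x, lab, direction = "higher_is_case")
  expect_equal(roc_auc(exp(x), lab, direction = "higher_is_case"), a)
  expect_equal(roc_auc(x, lab, direction = "lower_is_case"), 1 - a)
  expect_error(roc_auc(x, rep(TRUE, 30)), "case and one control")
})

test_that("AUC and DeLong agree with the pROC reference on random data", {
  set.seed(12)
  for (k in 1:5) {
    n <- 50L
    lab <- c(rep(TRUE, 20), rep(FALSE, 30))
    s1 <- rnorm(n) + lab * runif(1, 0, 2)
    s2 <- 0.7 * s1 + rnorm(n) * 0.5
    r1 <- pROC::roc(lab, s1, direction = "<", quiet = TRUE)
    expect_equal(roc_auc(s1, lab, direction = "higher_is_case"),
                 as.numeric(pROC::auc(r1)), tolerance = 1e-12)
    r2 <- pROC::roc(lab, s2, direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    ours <- delong_paired_test(s1, s2, lab, direction = "higher_is_case")
    expect_equal(ours$z, as.numeric(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-9)
    # partial AUC over specificity 0.9-1, unnormalized
    pref <- as.numeric(pROC::auc(r1, partial.auc = c(1, 0.9),
                                 partial.auc.focus = "specificity",
                                 partial.auc.correct = FALSE))
    expect_equal(partial_auc(s1, lab, 0.9, 1, direction = "higher_is_case"),
                 pref, tolerance = 1e-9)
  }
})

test_that("identical or rank-equivalent markers give a null DeLong test", {
  set.seed(5)
  s <- rnorm(40)
  lab <- rep(c(TRUE, FALSE), 20)
  r <- delong_paired_test(s, s, lab)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  # monotone transform: identical AUCs, z = 0
  r2 <- delong_paired_test(s, exp(s) + 5, lab)
  expect_equal(r2$auc1, r2$auc2)
  expect_equal(r2$z, 0)
})

test_that("partial AUC has the stated analytic values and bounds", {
  # perfect classifier: full box over the range
  lab <- c(rep(TRUE, 5), rep(FALSE, 5))
  s <- c(6:10, 1:5)
  expect_equal(partial_auc(s, lab, 0.9, 1, direction = "higher_is_case"), 0.1)
  # uninformative (all tied): diagonal, integral of x over [0, 0.1]
  expect_equal(partial_auc(rep(1, 10), lab, 0.9, 1, direction = "higher_is_case"),
               0.005)
  # bounds and full-range consistency on random data
  set.seed(8)
  for (k in 1:10) {
    x <- rnorm(40)
    l <- rep(c(TRUE, FALSE), 20)
    p <- partial_auc(x, l, 0.9, 1, direction = "higher_is_case")
    a <- roc_auc(x, l, direction = "higher_is_case")
    expect_gte(p, 0)
    expect_lte(p, 0.1 + 1e-12)
    expect_lte(p, a + 1e-12)
    expect_equal(partial_auc(x, l, 0, 1, direction = "higher_is_case"), a,
                 tolerance = 1e-12)
  }
  expect_error(partial_auc(x, l, 0.95, 0.9), "spec_lo < spec_hi")
})

test_that("bootstrap pAUC comparison is seeded and null for identical markers", {
  set.seed(2)
  lab <- rep(c(TRUE, FALSE), 20)
  s1 <- rnorm(40) + lab
  s2 <- 0.8 * s1 + 0.3 * rnorm(40)
  expect_equal(bootstrap_pauc_test(s1, s1, lab, B = 200,
                                   direction = "higher_is_case")$p, 1)
  b1 <- bootstrap_pauc_test(s1, s2, lab, B = 300, seed = 99,
                            direction = "higher_is_case")
  b2 <- bootstrap_pauc_test(s1, s2, lab, B = 300, seed = 99,
                            direction = "higher_is_case")
  expect_identical(b1$p, b2$p)
  expect_error(bootstrap_pauc_test(s1, s2, lab, B = 50), "at least 100")
})

test_that("sensitivity at fixed specificity uses the conservative threshold", {
  # perfectly separated: sensitivity 1 at both levels
  lab <- c(rep(TRUE, 4), rep(FALSE, 6))
  s <- c(11:14, 1:6)
  expect_equal(sensitivity_at_specificity(s, lab, 0.90,
                                          direction = "higher_is_case"), 1)
  expect_equal(sensitivity_at_specificity(s, lab, 0.95,
                                          direction = "higher_is_case"), 1)
  # hand-enumerated empirical ROC
  s2 <- c(5.5, 20, 1:10)
  lab2 <- c(TRUE, TRUE, rep(FALSE, 10))
  expect_equal(sensitivity_at_specificity(s2, lab2, 0.90,
                                          direction = "higher_is_case"), 0.5)
  # all scores equal: no threshold separates
  expect_equal(sensitivity_at_specificity(rep(2, 10), lab, 0.90,
                                          direction = "higher_is_case"), 0)
})

test_that("Spearman correlation handles ranks, ties and degenerate input", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  # direct rank computation: d = (-1, 1, -1, 1, 0), sum d^2 = 4
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 1 - 6 * 4 / (5 * 24))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("correlation comparison bootstrap is seeded, null-safe and powered", {
  set.seed(31)
  x <- rnorm(60)
  y1 <- x + rnorm(60, sd = 0.4)
  expect_equal(compare_correlations_bootstrap(x, y1, y1, B = 200)$p, 1)
  r1 <- compare_correlations_bootstrap(x, y1, rnorm(60), B = 300, seed = 8)
  r2 <- compare_correlations_bootstrap(x, y1, rnorm(60) * 2, B = 300, seed = 8)
  expect_identical(r1$B, 300L)
  expect_error(compare_correlations_bootstrap(x[1:5], y1[1:5], y1[1:5], B = 200),
               "at least 10")
  # power: strongly vs weakly correlated markers, n = 200
  hits <- 0L
  for (k in 1:20) {
    set.seed(1000 + k)
    x <- rnorm(200)
    ya <- x + rnorm(200, sd = 0.5)
    yb <- x + rnorm(200, sd = 3)
    p <- compare_correlations_bootstrap(x, ya, yb, B = 300, seed = k)$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("Benjamini-Hochberg matches the step-up hand computation", {
  r <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(r$adjusted, rep(0.05, 5))
  expect_equal(r$threshold, 0.05)
  expect_equal(benjamini_hochberg(0.03)$adjusted, 0.03)
  expect_equal(benjamini_hochberg(rep(1, 4))$threshold, 0)
  # monotone in the raw p-values
  set.seed(14)
  p <- runif(20)
  adj <- benjamini_hochberg(p)$adjusted
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})
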