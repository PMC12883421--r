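# Evaluation formulas: OvR AUC, weighted AUC, micro metrics, K-S
# comparison and concordance rules.

test_that("one-vs-rest AUC handles perfect ranking and full ties", {
  y <- c("PV", "PV", "ET", "ET")
  expect_equal(ovr_auc(c(0.9, 0.8, 0.2, 0.1), y, "PV"), 1)
  expect_equal(ovr_auc(rep(0.5, 4), y, "PV"), 0.5)
  expect_error(ovr_auc(1:3, rep("PV", 3), "PV"), "positive and negative")
})

test_that("one-vs-rest AUC equals exhaustive pair counting", {
  set.seed(41)
  for (i in 1:120) {
    n <- sample(4:12, 1)
    y <- sample(c("pre-PMF", "PV", "ET"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(n), sample(1:3, 1))
    pos <- sample(unique(y), 1)
    if (all(y == pos)) next
    expect_equal(ovr_auc(s, y, pos), oracle_auc(s, y, pos), tolerance = 1e-12)
  }
})

test_that("weighted AUC is the prevalence-weighted convex combination", {
  expect_equal(round(weighted_auc(c(0.50, 0.80, 0.73), c(19, 30, 39)), 2), 0.70)
  expect_equal(weighted_auc(c(0.6, 0.6, 0.6), c(5, 50, 1)), 0.6)
  expect_equal(weighted_auc(0.81, 7), 0.81)
  expect_error(weighted_auc(c(0.5, 0.6), 1), "mismatched")
  set.seed(6)
  for (i in 1:50) {
    a <- stats::runif(3); n <- sample(1:40, 3, replace = TRUE)
    w <- weighted_auc(a, n)
    expect_gte(w, min(a)); expect_lte(w, max(a))
  }
})

test_that("micro metrics are exact on perfect and degenerate predictors", {
  perfect <- diag(c(10, 20, 30))
  m <- micro_metrics(perfect)
  expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
  expect_equal(m$micro_f1, 1); expect_equal(m$micro_gmean, 1)
  # everything predicted as the first class on a balanced set
  allone <- matrix(0, 3, 3); allone[, 1] <- 10
  m1 <- micro_metrics(allone)
  expect_equal(m1$sensitivity, 1 / 3)
  expect_equal(m1$accuracy, 1 / 3)
  expect_error(micro_metrics(matrix(0, 3, 3)), "empty")
})

test_that("micro precision = micro sensitivity = accuracy on any confusion", {
  set.seed(51)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    m <- matrix(stats::rpois(k * k, 4), k, k)
    if (sum(m) == 0 || sum(diag(m)) == 0) next
    # independent per-class one-vs-rest summation oracle
    tp <- sum(diag(m))
    fn <- sum(rowSums(m) - diag(m))
    fp <- sum(colSums(m) - diag(m))
    res <- micro_metrics(m)
    expect_identical(res$precision, tp / (tp + fp))
    expect_identical(res$sensitivity, tp / (tp + fn))
    expect_identical(res$precision, res$sensitivity)
    expect_identical(res$precision, res$accuracy)
  }
})

test_that("the G-mean follows the printed product with a sqrt option", {
  m <- matrix(c(8, 2, 3, 7), 2, 2)
  a <- micro_metrics(m); b <- micro_metrics(m, gmean_sqrt = TRUE)
  expect_equal(a$micro_gmean, a$sensitivity * a$specificity)
  expect_equal(b$micro_gmean, sqrt(a$sensitivity * a$specificity))
})

test_that("K-S comparison flags identical and disjoint distributions", {
  a <- seq(0.3, 0.8, length.out = 20)
  r <- ks_compare(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$mean_abs_diff, 0)
  expect_equal(r$diff_histogram$count[1], 20)
  d <- ks_compare(seq(0.1, 0.3, length.out = 10), seq(0.6, 0.9, length.out = 10))
  expect_equal(d$statistic, 1)
  expect_error(ks_compare(numeric(), 1), "empty")
  expect_error(ks_compare(1:3 / 10, 1:4 / 10), "paired")
})

test_that("the K-S test holds its nominal size under the null", {
  # the exact two-sample p-value is discrete at small n, so the check is on
  # the rejection rate rather than on p-value uniformity
  set.seed(61)
  ps <- replicate(200, suppressWarnings(
    ks_compare(stats::rnorm(30, 0.6, 0.1), stats::rnorm(30, 0.6, 0.1))$p_value))
  rate <- mean(ps < 0.05)
  expect_lte(rate, stats::qbinom(0.995, 200, 0.05) / 200)
  expect_gt(stats::median(ps), 0.2)
})

test_that("follow-up concordance reproduces the published 50% rate", {
  nos <- nos_validation_scores()
  pred <- assign_subtype(as.matrix(nos[c("score_prePMF", "score_PV", "score_ET")]))
  fu <- concordance(pred, nos$followup, rule = "followup")
  expect_equal(fu$n_eligible, 8)
  expect_equal(fu$n_concordant, 4)
  expect_equal(fu$rate, 0.5)
})

test_that("histology concordance exposes both overlap policies", {
  nos <- nos_validation_scores()
  pred <- assign_subtype(as.matrix(nos[c("score_prePMF", "score_PV", "score_ET")]))
  strict <- concordance(pred, nos$histology, "histology", policy = "strict")
  generous <- concordance(pred, nos$histology, "histology", policy = "generous")
  expect_equal(strict$n_eligible, 7)
  expect_equal(generous$n_eligible, 13)
  expect_gte(generous$n_concordant, strict$n_concordant)
})

test_that("concordance validates its reference tokens", {
  expect_equal(concordance(c("PV", "ET"), c("PV", "PV"))$rate, 0.5)
  expect_error(concordance("PV", "WEIRD-LIKE", rule = "histology"), "unknown")
  expect_error(concordance(c("PV", "ET"), c(NA, "UNCHANGED")), "no eligible")
})
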