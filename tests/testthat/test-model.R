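# Feature screening, standardization, the calibrated linear SVM and
# repeated cross-validation.

test_that("Kruskal-Wallis H matches a hand-rank oracle on small groups", {
  set.seed(31)
  for (i in 1:40) {
    g <- rep(c("a", "b", "c"), each = 3)
    v <- round(stats::rnorm(9), sample(0:1, 1)) # rounding induces ties
    if (length(unique(v)) < 2) next
    res <- kruskal_wallis_select(data.frame(f = v), g)
    expect_equal(res$table$statistic, oracle_kw_h(v, g), tolerance = 1e-12)
  }
})

test_that("constant features are never selected and degenerate groups error", {
  X <- data.frame(flat = rep(1, 12), good = c(1:4, 11:14, 21:24))
  y <- rep(c("a", "b", "c"), each = 4)
  sel <- kruskal_wallis_select(X, y)
  expect_false("flat" %in% sel$selected)
  expect_true("good" %in% sel$selected)
  expect_error(kruskal_wallis_select(X, rep("a", 12)), "two groups")
  expect_error(kruskal_wallis_select(X[1:3, ], c("a", "b", "b")), "observations")
})

test_that("null features are selected at the nominal rate", {
  set.seed(5)
  y <- rep(c("a", "b", "c"), c(19, 30, 39))
  p <- replicate(400, kruskal_wallis_select(
    data.frame(f = stats::rnorm(88)), y)$table$p_value)
  rate <- mean(p < 0.05)
  ci <- stats::qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
})

test_that("standardization round-trips and flags zero-variance columns", {
  set.seed(2)
  X <- matrix(stats::rnorm(60, 5, 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_equal(unname(apply(Z, 2, stats::sd)), rep(1, 3))
  expect_equal(destandardize(std, Z), X, tolerance = 1e-12)
  Xz <- cbind(X, dead = rep(2, 20))
  expect_error(fit_standardizer(Xz), "dead")
})

test_that("the linear SVM separates a separable 3-class problem", {
  set.seed(7)
  X <- rbind(matrix(stats::rnorm(40, 0), 20, 2),
             matrix(stats::rnorm(40, 6), 20, 2),
             cbind(stats::rnorm(20, 0), stats::rnorm(20, 6)))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("pre-PMF", "PV", "ET"), each = 20),
              levels = c("pre-PMF", "PV", "ET"))
  m <- train_svm(X, y)
  sc <- predict(m, X)
  expect_equal(mean(sc$predicted == as.character(y)), 1)
  sums <- rowSums(as.matrix(sc[paste0("score_", levels(y))]))
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("training and scoring are deterministic and reject bad input", {
  X <- as.data.frame(generate_feature_cohort(make_default_profiles(), 8, seed = 4))
  fc <- feature_columns()
  std <- fit_standardizer(X[fc])
  Z <- apply_standardizer(std, X[fc])
  m1 <- train_svm(Z, X$label); m2 <- train_svm(Z, X$label)
  expect_identical(predict(m1, Z), predict(m2, Z))
  expect_error(train_svm(Z, rep("PV", nrow(Z))), "two classes")
  Zbad <- Z[, rev(colnames(Z))]
  expect_error(predict(m1, Zbad), "feature columns")
})

test_that("argmax assignment uses the last-maximal tie rule", {
  s <- rbind(c(0.13, 0.76, 0.11), c(0.30, 0.35, 0.35), c(1, 0, 0),
             c(1 / 3, 1 / 3, 1 / 3))
  expect_identical(assign_subtype(s), c("PV", "ET", "pre-PMF", "ET"))
})

test_that("repeated CV covers every patient once per repeat, reproducibly", {
  X <- generate_feature_cohort(make_default_profiles(), c(10, 12, 15), seed = 2)
  fc <- c("cellularity", "density_mean", "area_mean")
  cv1 <- repeated_cv(X[fc], X$label, k = 5, repeats = 3, seed = 99)
  cv2 <- repeated_cv(X[fc], X$label, k = 5, repeats = 3, seed = 99)
  expect_identical(cv1, cv2)
  for (r in 1:3) {
    pr <- cv1$predictions[cv1$predictions$repeat_id == r, ]
    expect_setequal(pr$index, seq_len(nrow(X)))
    expect_equal(anyDuplicated(pr$index), 0)
  }
  expect_equal(nrow(cv1$fold_metrics), 15)
})

test_that("classes smaller than k are rejected", {
  X <- generate_feature_cohort(make_default_profiles(), c(3, 12, 15), seed = 2)
  expect_error(repeated_cv(X[c("cellularity")], X$label, k = 5), "choose k")
})

test_that("nested selection uses training folds only", {
  X <- generate_feature_cohort(make_default_profiles(), 10, seed = 8)
  fc <- feature_columns()
  cv <- repeated_cv(X[fc], X$label, k = 5, repeats = 1, seed = 3,
                    nested_selection = TRUE)
  for (fd in unique(cv$predictions$fold)) {
    pr <- cv$predictions[cv$predictions$fold == fd, ]
    tr <- setdiff(seq_len(nrow(X)), pr$index)
    sel <- kruskal_wallis_select(X[tr, fc], X$label[tr])
    feats <- sel$selected
    if (length(feats) == 0)
      feats <- sel$table$feature[which.min(sel$table$p_value)]
    expect_identical(unique(pr$selected_features), paste(feats, collapse = ";"))
  }
})

test_that("NOS prediction reproduces the published argmax column", {
  nos <- nos_validation_scores()
  pred <- assign_subtype(as.matrix(nos[c("score_prePMF", "score_PV", "score_ET")]))
  expect_identical(pred, nos$published_prediction)
})
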