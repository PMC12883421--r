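# Feature screening, standardization, linear-SVM classification with
# calibrated class scores, repeated stratified cross-validation and
# score-based MPN-NOS assignment.
#
# Class scores: e1071/libsvm's built-in probability estimates are not
# reproducible under a fixed R seed (the internal Platt cross-validation
# uses its own RNG), so the calibration is done here deterministically:
# Platt sigmoids with regularized targets fitted on the training decision
# values of each class pair (no inner CV), combined by Wu-Lin-Weng
# pairwise coupling into a probability simplex.

MPN_CLASS_ORDER <- c("pre-PMF", "PV", "ET")

#' Kruskal-Wallis feature screening
#'
#' Runs the rank-based Kruskal-Wallis test (tie-corrected H, chi-square
#' p-value, via [stats::kruskal.test()]) for every feature column against
#' the class labels and selects features with `p < alpha`.
#'
#' @param X data frame or matrix of features (columns = features).
#' @param y class labels (>= 2 groups, each with >= 2 observations).
#' @param alpha selection level (default 0.05).
#' @return a `kw_selection`: list with `table` (feature, statistic,
#'   p_value, selected), `selected` (character) and `alpha`.
#' @export
kruskal_wallis_select <- function(X, y, alpha = 0.05) {
  X <- as.data.frame(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("kruskal_wallis_select(): need at least two groups")
  if (any(table(droplevels(y)) < 2))
    stop("kruskal_wallis_select(): every group needs at least two observations")
  res <- lapply(names(X), function(f) {
    kt <- stats::kruskal.test(X[[f]], y)
    tibble::tibble(feature = f, statistic = unname(kt$statistic),
                   p_value = unname(kt$p.value))
  })
  tab <- do.call(rbind, res)
  tab$selected <- tab$p_value < alpha
  structure(list(table = tab, selected = tab$feature[tab$selected],
                 alpha = alpha), class = "kw_selection")
}

#' Column standardizer
#'
#' `fit_standardizer()` learns per-column means and SDs on the training
#' set; `apply_standardizer()` z-scores new data with the training
#' parameters; `destandardize()` inverts the transform.
#'
#' @param X training feature table (data frame or matrix).
#' @return a `standardizer` with `center`, `scale` and `features`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zero <- names(scl)[scl == 0 | !is.finite(scl)]
  if (length(zero))
    stop("fit_standardizer(): zero-variance column(s): ",
         paste(zero, collapse = ", "))
  structure(list(center = ctr, scale = scl, features = colnames(X)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std a fitted `standardizer`.
#' @export
apply_standardizer <- function(std, X) {
  X <- as.matrix(X)[, std$features, drop = FALSE]
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' @rdname fit_standardizer
#' @export
destandardize <- function(std, X) {
  X <- as.matrix(X)[, std$features, drop = FALSE]
  sweep(sweep(X, 2, std$scale, "*"), 2, std$center, "+")
}

#' Train a linear SVM with calibrated class scores
#'
#' One-vs-one linear SVM (e1071/libsvm) with deterministic score
#' calibration: a Platt sigmoid per class pair fitted on the training
#' decision values, combined by pairwise coupling so that every
#' prediction is a probability simplex over the classes.
#'
#' @param X standardized feature matrix.
#' @param y class labels; factor levels define the class (and tie-break)
#'   order — by default `pre-PMF, PV, ET`.
#' @param cost SVM regularization constant C (default 1).
#' @param seed kept for interface symmetry; the fit itself is
#'   deterministic.
#' @return an `mpn_svm` model.
#' @export
train_svm <- function(X, y, cost = 1, seed = 1) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) droplevels(y) else
    factor(y, levels = intersect(MPN_CLASS_ORDER, unique(y)))
  if (nlevels(y) < 2) stop("train_svm(): need at least two classes")
  set.seed(as.integer(seed))
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  dv <- attr(stats::predict(fit, X, decision.values = TRUE), "decision.values")
  platt <- lapply(colnames(dv), function(pair) {
    ab <- strsplit(pair, "/", fixed = TRUE)[[1]]
    rows <- y %in% ab
    platt_fit(dv[rows, pair], y[rows] == ab[1])
  })
  names(platt) <- colnames(dv)
  structure(list(fit = fit, levels = levels(y), platt = platt,
                 features = colnames(X), cost = cost),
            class = "mpn_svm")
}

# Platt sigmoid P(positive | d) = plogis(a*d + b), fitted by ML with the
# regularized targets (N+ + 1)/(N+ + 2), 1/(N- + 2) so separable pairs
# stay finite. Deterministic.
platt_fit <- function(d, pos) {
  np <- sum(pos); nn <- sum(!pos)
  t <- ifelse(pos, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    p <- stats::plogis(par[1] * d + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  opt <- stats::optim(c(1, 0), nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  c(a = opt$par[1], b = opt$par[2])
}

# Wu-Lin-Weng pairwise coupling (the estimate used by libsvm): solves for
# the simplex p minimizing sum_(i!=j) (r_ji p_i - r_ij p_j)^2.
pairwise_couple <- function(R) {
  k <- nrow(R)
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(R[-t, t]^2)
    for (j in seq_len(k)) if (j != t) Q[t, j] <- -R[j, t] * R[t, j]
  }
  p <- rep(1 / k, k)
  for (it in 1:100) {
    pQp <- drop(t(p) %*% Q %*% p)
    stop_ok <- TRUE
    for (t in seq_len(k)) {
      diff <- abs(drop(Q[t, ] %*% p) - pQp)
      if (diff > 1e-10) stop_ok <- FALSE
      p[t] <- (-drop(Q[t, -t] %*% p[-t]) + pQp) / Q[t, t]
      p <- p / sum(p)
      pQp <- drop(t(p) %*% Q %*% p)
    }
    if (stop_ok) break
  }
  p
}

#' Predict calibrated class scores
#'
#' @param object an `mpn_svm` model.
#' @param newdata standardized feature matrix with the training columns.
#' @param ... unused.
#' @return tibble with one `score_<class>` column per class (each row sums
#'   to 1) and the `predicted` label under the argmax/tie rule of
#'   [assign_subtype()].
#' @export
predict.mpn_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$features))
    stop("predict.mpn_svm(): feature columns do not match the training set")
  dv <- attr(stats::predict(object$fit, newdata, decision.values = TRUE),
             "decision.values")
  lv <- object$levels
  k <- length(lv)
  scores <- matrix(NA_real_, nrow(newdata), k, dimnames = list(NULL, lv))
  for (row in seq_len(nrow(newdata))) {
    R <- matrix(0.5, k, k)
    for (pair in colnames(dv)) {
      ab <- strsplit(pair, "/", fixed = TRUE)[[1]]
      i <- match(ab[1], lv); j <- match(ab[2], lv)
      co <- object$platt[[pair]]
      rij <- stats::plogis(co["a"] * dv[row, pair] + co["b"])
      rij <- min(max(rij, 1e-7), 1 - 1e-7)
      R[i, j] <- rij; R[j, i] <- 1 - rij
    }
    scores[row, ] <- if (k == 2) {
      c(R[1, 2], R[2, 1]) / (R[1, 2] + R[2, 1])
    } else pairwise_couple(R)
  }
  out <- tibble::as_tibble(as.data.frame(scores, check.names = FALSE))
  names(out) <- paste0("score_", lv)
  out$predicted <- assign_subtype(scores, class_order = lv)
  out
}

#' Argmax class assignment with the fixed tie rule
#'
#' Assigns each row to the class with the highest score; exact ties are
#' broken by taking the *last* maximal class in `class_order`
#' (pre-PMF, PV, ET), so a pre-PMF/PV/ET score row of (0.30, 0.35, 0.35)
#' is assigned ET.
#'
#' @param scores numeric matrix (rows = patients, columns = classes in
#'   `class_order`) or a tibble of `score_*` columns.
#' @param class_order class order used for argmax tie-breaking.
#' @param tol tolerance within which scores count as tied.
#' @return character vector of assigned labels.
#' @export
assign_subtype <- function(scores, class_order = MPN_CLASS_ORDER, tol = 1e-9) {
  m <- as.matrix(scores)
  stopifnot(ncol(m) == length(class_order))
  apply(m, 1, function(s) {
    class_order[max(which(s >= max(s) - tol))]
  })
}

#' Repeated stratified k-fold cross-validation
#'
#' Stratified fold assignment per repeat from a single master seed; the
#' standardizer (and, with `nested_selection`, the Kruskal-Wallis screen)
#' is fitted on the training folds only. Per-fold test scores feed the
#' one-vs-rest AUCs; per-repeat aggregated predictions feed accuracy and
#' the micro-averaged metrics.
#'
#' @param X feature table (unstandardized; columns = features).
#' @param y class labels; every class needs at least `k` members.
#' @param k folds (default 5); `repeats` repeats (default 5).
#' @param seed master seed driving all fold assignments.
#' @param cost SVM cost.
#' @param nested_selection run the KW screen inside each training fold
#'   (leakage-free variant) instead of using the columns of `X` as given.
#' @param alpha selection level for the nested screen.
#' @param gmean_sqrt report the conventional sqrt G-mean instead of the
#'   plain sensitivity x specificity product.
#' @return an `mpn_cv_report`: list with `predictions` (per repeat/fold),
#'   `fold_metrics`, `summary` (weighted AUC mean/sd over folds, per-class
#'   AUC mean/sd, accuracy mean/sd over repeats, micro metrics) and the
#'   configuration.
#' @export
repeated_cv <- function(X, y, k = 5, repeats = 5, seed = 1, cost = 1,
                        nested_selection = FALSE, alpha = 0.05,
                        gmean_sqrt = FALSE) {
  X <- as.data.frame(X)
  y <- if (is.factor(y)) droplevels(y) else
    factor(y, levels = intersect(c(MPN_CLASS_ORDER, unique(y)), unique(y)))
  counts <- table(y)
  if (any(counts < k))
    stop(sprintf("repeated_cv(): class '%s' has %d members; choose k <= %d",
                 names(counts)[which.min(counts)], min(counts), min(counts)))
  set.seed(as.integer(seed))
  lv <- levels(y)
  preds <- list(); foldm <- list()
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(y))
    for (cl in lv) {
      idx <- which(y == cl)
      fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    for (fd in seq_len(k)) {
      te <- which(fold_of == fd); tr <- which(fold_of != fd)
      feats <- names(X)
      if (nested_selection) {
        sel <- kruskal_wallis_select(X[tr, , drop = FALSE], y[tr], alpha)
        feats <- sel$selected
        if (length(feats) == 0) # degenerate fold: fall back to the best single feature
          feats <- sel$table$feature[which.min(sel$table$p_value)]
      }
      std <- fit_standardizer(X[tr, feats, drop = FALSE])
      model <- train_svm(apply_standardizer(std, X[tr, feats, drop = FALSE]),
                         y[tr], cost = cost)
      sc <- predict(model, apply_standardizer(std, X[te, feats, drop = FALSE]))
      preds[[length(preds) + 1]] <- tibble::tibble(
        repeat_id = r, fold = fd, index = te, truth = as.character(y[te]), sc,
        selected_features = paste(feats, collapse = ";")
      )
      smat <- as.matrix(sc[paste0("score_", lv)])
      auc_c <- vapply(lv, function(cl)
        ovr_auc(smat[, paste0("score_", cl)], y[te], cl), numeric(1))
      wts <- as.numeric(table(y[te])[lv])
      fm <- tibble::tibble(
        repeat_id = r, fold = fd,
        accuracy = mean(sc$predicted == as.character(y[te])),
        auc_weighted = weighted_auc(auc_c, wts)
      )
      for (cl in lv) fm[[paste0("auc_", cl)]] <- auc_c[[cl]]
      foldm[[length(foldm) + 1]] <- fm
    }
  }
  predictions <- do.call(rbind, preds)
  fold_metrics <- do.call(rbind, foldm)

  # fold invariants
  for (r in seq_len(repeats)) {
    pr <- predictions[predictions$repeat_id == r, ]
    stopifnot(identical(sort(pr$index), seq_along(y)))
  }

  conf_by_round <- lapply(seq_len(repeats), function(r) {
    pr <- predictions[predictions$repeat_id == r, ]
    table(factor(pr$truth, lv), factor(pr$predicted, lv))
  })
  micro <- micro_metrics(conf_by_round, gmean_sqrt = gmean_sqrt)
  acc_round <- vapply(conf_by_round, function(m) sum(diag(m)) / sum(m), numeric(1))

  summary <- list(
    auc_weighted_mean = mean(fold_metrics$auc_weighted),
    auc_weighted_sd = stats::sd(fold_metrics$auc_weighted),
    auc_per_class = stats::setNames(
      colMeans(fold_metrics[paste0("auc_", lv)]), lv),
    auc_per_class_sd = stats::setNames(
      apply(fold_metrics[paste0("auc_", lv)], 2, stats::sd), lv),
    accuracy_mean = mean(acc_round), accuracy_sd = stats::sd(acc_round),
    micro_f1 = micro$micro_f1, micro_gmean = micro$micro_gmean,
    micro_sensitivity = micro$sensitivity,
    micro_specificity = micro$specificity, micro_precision = micro$precision
  )
  structure(list(predictions = predictions, fold_metrics = fold_metrics,
                 confusions = conf_by_round, summary = summary,
                 k = k, repeats = repeats, seed = seed, cost = cost,
                 nested_selection = nested_selection, levels = lv),
            class = "mpn_cv_report")
}

#' @export
print.mpn_cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Repeated stratified CV: %d folds x %d repeats (seed %s)\n",
              x$k, x$repeats, format(x$seed)))
  cat(sprintf("  weighted multiclass AUC: %.2f +/- %.2f\n",
              s$auc_weighted_mean, s$auc_weighted_sd))
  for (cl in x$levels)
    cat(sprintf("  AUC %-8s %.2f +/- %.2f\n", paste0(cl, ":"),
                s$auc_per_class[cl], s$auc_per_class_sd[cl]))
  cat(sprintf("  accuracy: %.2f +/- %.2f\n", s$accuracy_mean, s$accuracy_sd))
  cat(sprintf("  micro F1: %.2f   micro G-mean: %.2f\n", s$micro_f1, s$micro_gmean))
  invisible(x)
}

#' Score-based assignment of MPN-NOS patients
#'
#' Applies a classifier trained on the three confirmed subtypes to
#' unclassified (MPN-NOS) patients; each patient is assigned to the
#' subtype with the highest calibrated score (ties resolved by
#' [assign_subtype()]'s last-maximal rule).
#'
#' @param classifier an `mpn_svm` trained on the full 3-class cohort
#'   (standardized features).
#' @param X_nos standardized feature matrix of the NOS patients with the
#'   training feature columns.
#' @param patient_ids optional identifiers.
#' @return tibble of per-class scores and the `predicted` label.
#' @export
predict_nos <- function(classifier, X_nos, patient_ids = NULL) {
  stopifnot(inherits(classifier, "mpn_svm"))
  sc <- predict(classifier, X_nos)
  if (!is.null(patient_ids)) sc <- tibble::tibble(patient_id = patient_ids, sc)
  sc
}
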