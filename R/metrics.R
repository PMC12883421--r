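# Evaluation formulas: one-vs-rest AUC, label-weighted multiclass AUC,
# micro-averaged sensitivity/specificity/precision/F1/G-mean, the K-S
# comparison of automatic vs pathologist cellularity, and concordance
# rates for the NOS validation cohort.

#' One-vs-rest AUC
#'
#' Rank-based (Mann-Whitney) AUC of the positive-class score against all
#' other classes pooled; ties contribute 1/2. Identical to trapezoidal ROC
#' integration in exact arithmetic but with explicit tie handling.
#'
#' @param scores numeric score of the positive class per observation.
#' @param y true labels.
#' @param positive_class the label treated as positive.
#' @return AUC in `[0, 1]`.
#' @export
ovr_auc <- function(scores, y, positive_class) {
  pos <- as.character(y) == as.character(positive_class)
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    stop("ovr_auc(): need both positive and negative observations")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Label-weighted multiclass AUC
#'
#' \eqn{AUC_{tot} = \sum_c AUC_c \, n_c / N}: the sum of the per-class
#' one-vs-rest AUCs weighted by class prevalence.
#'
#' @param per_class_auc numeric vector of one-vs-rest AUCs.
#' @param class_counts positive class sizes, same length and order.
#' @return the weighted AUC.
#' @examples
#' weighted_auc(c(0.50, 0.80, 0.73), c(19, 30, 39)) # 0.704...
#' @export
weighted_auc <- function(per_class_auc, class_counts) {
  if (length(per_class_auc) != length(class_counts))
    stop("weighted_auc(): mismatched lengths")
  stopifnot(all(class_counts > 0))
  sum(per_class_auc * class_counts / sum(class_counts))
}

#' Micro-averaged multiclass metrics
#'
#' For each round (e.g. CV repeat), tp/fp/fn/tn are summed over the
#' per-class one-vs-rest confusions; sensitivity, specificity and
#' precision are computed per round, their means over rounds are the final
#' estimates, and F1 and G-mean are composed from the means:
#' `F1 = 2 * sens * prec / (sens + prec)` and, following the published
#' formula, `G-mean = sens * spec` (set `gmean_sqrt = TRUE` for the
#' conventional square-root form).
#'
#' @param confusions a square confusion matrix (rows = truth, columns =
#'   prediction) or a list of them, one per round.
#' @param gmean_sqrt use `sqrt(sens * spec)`.
#' @return list with `per_round` (tibble), the mean `sensitivity`,
#'   `specificity`, `precision`, `accuracy`, and `micro_f1`,
#'   `micro_gmean`.
#' @export
micro_metrics <- function(confusions, gmean_sqrt = FALSE) {
  if (is.table(confusions) || is.matrix(confusions)) confusions <- list(confusions)
  rows <- lapply(seq_along(confusions), function(i) {
    m <- as.matrix(confusions[[i]])
    stopifnot(nrow(m) == ncol(m), all(m >= 0))
    k <- nrow(m); N <- sum(m)
    if (N == 0) stop("micro_metrics(): empty confusion matrix (round ", i, ")")
    tp <- sum(diag(m))
    fn <- N - tp
    fp <- N - tp
    tn <- k * N - 2 * N + tp
    if (tp + fn == 0) stop("micro_metrics(): sensitivity undefined (no positives)")
    if (tn + fp == 0) stop("micro_metrics(): specificity undefined (no negatives)")
    if (tp + fp == 0) stop("micro_metrics(): precision undefined (no predicted positives)")
    tibble::tibble(round = i, tp = tp, fp = fp, fn = fn, tn = tn,
                   sensitivity = tp / (tp + fn),
                   specificity = tn / (tn + fp),
                   precision = tp / (tp + fp),
                   accuracy = tp / N)
  })
  per_round <- do.call(rbind, rows)
  sens <- mean(per_round$sensitivity)
  spec <- mean(per_round$specificity)
  prec <- mean(per_round$precision)
  list(per_round = per_round,
       sensitivity = sens, specificity = spec, precision = prec,
       accuracy = mean(per_round$accuracy),
       micro_f1 = 2 * sens * prec / (sens + prec),
       micro_gmean = if (gmean_sqrt) sqrt(sens * spec) else sens * spec)
}

#' Kolmogorov-Smirnov comparison of automatic vs reference cellularity
#'
#' Two-sample K-S test of the paired automatic and reference cellularity
#' values (when the reference is a range, resolve it to its upper bound
#' before calling, see [load_manifest()]), plus the mean absolute
#' per-patient difference and a binned difference histogram (0-0.4 in 0.1
#' steps, with an overflow bin).
#'
#' @param auto_cellularity,reference_cellularity paired numeric vectors.
#' @return list with `statistic` (D), `p_value`, `mean_abs_diff` and
#'   `diff_histogram` (tibble of bins and counts).
#' @export
ks_compare <- function(auto_cellularity, reference_cellularity) {
  if (length(auto_cellularity) == 0 || length(reference_cellularity) == 0)
    stop("ks_compare(): empty input")
  if (length(auto_cellularity) != length(reference_cellularity))
    stop("ks_compare(): per-patient comparison needs paired vectors")
  kt <- suppressWarnings(stats::ks.test(auto_cellularity, reference_cellularity))
  d <- abs(auto_cellularity - reference_cellularity)
  breaks <- c(seq(0, 0.4, by = 0.1), Inf)
  cnt <- tabulate(findInterval(d, breaks, rightmost.closed = FALSE,
                               all.inside = TRUE), nbins = 5)
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       mean_abs_diff = mean(d),
       diff_histogram = tibble::tibble(
         bin = c("0-0.1", "0.1-0.2", "0.2-0.3", "0.3-0.4", ">0.4"),
         count = cnt))
}

# Reference-token parsing for concordance: returns the set of classes a
# token names, or NULL for NA/UNCHANGED.
parse_reference_token <- function(token) {
  if (is.na(token) || token == "" || toupper(token) == "NA") return(NULL)
  if (startsWith(toupper(token), "UNCHANGED")) return("UNCHANGED")
  t <- gsub("-?LIKE$", "", trimws(token))
  parts <- trimws(unlist(strsplit(t, "/", fixed = TRUE)))
  parts <- sub("-$", "", parts)
  parts[parts == "PMF"] <- "pre-PMF"
  if (!all(parts %in% MPN_CLASS_ORDER))
    stop("concordance(): unknown reference token: '", token, "'")
  parts
}

#' Concordance between model predictions and a reference classification
#'
#' Rule `"followup"`: drop `NA` and `UNCHANGED` entries and count exact
#' label matches (a bare `PMF` reference maps to pre-PMF). Rule
#' `"histology"`: the reference may name overlap morphologies such as
#' `pre-PMF-/PV-LIKE`; under `policy = "strict"` only single-class tokens
#' are eligible and must match exactly, under `policy = "generous"` every
#' case is eligible and a prediction inside the named set counts as
#' concordant. No single policy reproduces every published histology
#' concordance figure; both are exposed.
#'
#' @param predictions character vector of predicted class labels.
#' @param reference character vector of reference tokens (class labels,
#'   overlap tokens, `UNCHANGED*`, `NA`).
#' @param rule `"followup"` or `"histology"`.
#' @param policy overlap-matching policy for the histology rule.
#' @return list with `n_eligible`, `n_concordant`, `rate`, `rule`.
#' @export
concordance <- function(predictions, reference,
                        rule = c("followup", "histology"),
                        policy = c("generous", "strict")) {
  rule <- match.arg(rule); policy <- match.arg(policy)
  stopifnot(length(predictions) == length(reference))
  sets <- lapply(reference, parse_reference_token)
  if (rule == "followup") {
    elig <- vapply(sets, function(s)
      !is.null(s) && !identical(s, "UNCHANGED"), logical(1))
    if (any(vapply(sets[elig], length, 1L) != 1))
      stop("concordance(): follow-up entries must be single class labels")
  } else if (policy == "strict") {
    elig <- vapply(sets, function(s)
      !is.null(s) && !identical(s, "UNCHANGED") && length(s) == 1, logical(1))
  } else {
    elig <- vapply(sets, function(s)
      !is.null(s) && !identical(s, "UNCHANGED"), logical(1))
  }
  if (!any(elig)) stop("concordance(): no eligible cases")
  hit <- mapply(function(p, s) p %in% s, predictions[elig], sets[elig])
  list(n_eligible = sum(elig), n_concordant = sum(hit),
       rate = sum(hit) / sum(elig), rule = rule,
       policy = if (rule == "histology") policy else NA_character_)
}
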