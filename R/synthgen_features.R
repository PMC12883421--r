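# Direct feature-table generator: bypasses imaging to exercise the
# selection/classification stages on cohorts with known class structure.

# Per-column noise standard deviations (one patient-level draw per column).
# The informative columns (nuclear area/perimeter/circularity means, cell
# density mean, cellularity) are separated across the default class profiles
# by roughly one to two of these SDs, mirroring the published cellularity
# pattern (class means 0.55/0.67/0.65 against SDs 0.12-0.14); the remaining
# summary-statistic columns share their means across classes and act as
# null features for the Kruskal-Wallis screen.
feature_noise_template <- function() {
  c(
    area_mean = 25, area_sd = 12, area_skewness = 0.15, area_kurtosis = 0.3,
    area_entropy = 0.15,
    perimeter_mean = 6, perimeter_sd = 4, perimeter_skewness = 0.15,
    perimeter_kurtosis = 0.3, perimeter_entropy = 0.15,
    circularity_mean = 0.04, circularity_sd = 0.02, circularity_skewness = 0.15,
    circularity_kurtosis = 0.3, circularity_entropy = 0.15,
    density_mean = 0.03, density_sd = 0.015, density_skewness = 0.2,
    density_kurtosis = 0.3, density_entropy = 0.12,
    cellularity = NA # per class: the profile's cellularity_sd
  )
}

#' Analytic per-class feature means implied by a generator profile
#'
#' The informative columns derive from the profile parameters: nuclear area
#' from the megakaryocyte area distribution, perimeter and circularity from
#' area and lobe count (a lobed nucleus has a longer boundary than a disc of
#' equal area), cell density from the megakaryocyte area fraction, and
#' cellularity from the cellularity mean. The remaining columns are fixed
#' across classes.
#'
#' @param profile a [class_profile()].
#' @return named numeric vector over [feature_columns()] (`full21` order).
#' @export
feature_class_means <- function(profile) {
  A <- profile$mk_area_mean_um2
  L <- profile$mk_lobulation
  perim <- 2 * sqrt(pi * A) * (1 + 0.12 * (L - 1))
  circ <- 4 * pi * A / perim^2
  c(
    area_mean = A, area_sd = profile$mk_area_sd_um2,
    area_skewness = 0.25, area_kurtosis = 0.1, area_entropy = 1.9,
    perimeter_mean = perim, perimeter_sd = 11,
    perimeter_skewness = 0.2, perimeter_kurtosis = 0.1, perimeter_entropy = 1.9,
    circularity_mean = circ, circularity_sd = 0.08,
    circularity_skewness = -0.1, circularity_kurtosis = 0.1,
    circularity_entropy = 1.8,
    density_mean = profile$mk_fraction_mean, density_sd = 0.035,
    density_skewness = 0.1, density_kurtosis = -0.5, density_entropy = 0.9,
    cellularity = profile$cellularity_mean
  )
}

#' Generate a per-patient feature cohort directly from class profiles
#'
#' Each patient row is drawn from a class-conditional Gaussian around the
#' analytic feature means of its profile ([feature_class_means()]), with
#' per-column SDs scaled by `noise_scale`. With `noise_scale = 0` the class
#' means are recovered exactly.
#'
#' @param profiles list of [class_profile()]s (one per class).
#' @param n_per_class patients per class; either a single count or one per
#'   profile. Must be >= 2.
#' @param noise_scale multiplier on the per-column noise SDs (default 1).
#' @param seed integer seed.
#' @return tibble with `patient_id`, `label` and the `full21` feature
#'   columns.
#' @export
generate_feature_cohort <- function(profiles, n_per_class, noise_scale = 1,
                                    seed = 1) {
  if (inherits(profiles, "class_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1, all(n_per_class >= 2), noise_scale >= 0)
  n_per_class <- rep_len(n_per_class, length(profiles))
  set.seed(as.integer(seed))
  tmpl <- feature_noise_template()
  cols <- feature_columns("full21")
  out <- list()
  pid <- 0L
  for (ci in seq_along(profiles)) {
    p <- profiles[[ci]]
    mu <- feature_class_means(p)[cols]
    sdv <- tmpl[cols]
    sdv["cellularity"] <- p$cellularity_sd
    n <- n_per_class[ci]
    X <- matrix(stats::rnorm(n * length(cols)), n, length(cols))
    X <- sweep(sweep(X, 2, noise_scale * sdv, "*"), 2, mu, "+")
    colnames(X) <- cols
    if (noise_scale > 0) {
      X[, "cellularity"] <- pmin(pmax(X[, "cellularity"], 0.01), 0.99)
      X[, "density_mean"] <- pmin(pmax(X[, "density_mean"], 0.01), 0.99)
    }
    out[[ci]] <- tibble::tibble(
      patient_id = sprintf("SYN%03d", pid + seq_len(n)),
      label = p$label,
      tibble::as_tibble(X)
    )
    pid <- pid + n
  }
  do.call(rbind, out)
}
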