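# Per-patient feature vectors: five summary statistics of each nuclear
# feature over megakaryocyte-filtered nuclei pooled across the ROIs, the
# same statistics of the per-ROI cell density, and the area-weighted
# cellularity.

#' Fixed feature-column order
#'
#' `full21` is the default: 5 statistics (mean, sd, skewness, kurtosis,
#' entropy) for each of the three nuclear features (area, perimeter,
#' circularity), 5 for cell density, plus cellularity. `paper17` drops the
#' four entropy columns, yielding the 17-column variant (3x4 + 4 + 1)
#' consistent with the published feature count.
#'
#' @param feature_set `"full21"` or `"paper17"`.
#' @return character vector of column names in fixed order.
#' @export
feature_columns <- function(feature_set = c("full21", "paper17")) {
  feature_set <- match.arg(feature_set)
  stats5 <- c("mean", "sd", "skewness", "kurtosis", "entropy")
  cols <- c(
    paste0("area_", stats5), paste0("perimeter_", stats5),
    paste0("circularity_", stats5), paste0("density_", stats5),
    "cellularity"
  )
  if (feature_set == "paper17") cols <- cols[!grepl("_entropy$", cols)]
  cols
}

#' Five summary statistics of a numeric sample
#'
#' Sample mean; sample SD (n-1 denominator); moment-based skewness
#' \eqn{g_1 = m_3 / m_2^{3/2}} and excess kurtosis \eqn{g_2 = m_4/m_2^2 - 3}
#' (0 for a Gaussian); Shannon entropy (natural log) of an equal-width
#' histogram between the sample min and max. Degenerate samples (n = 1 or
#' zero variance) return 0 for sd, skewness, kurtosis and entropy.
#'
#' @param values numeric vector, length >= 1.
#' @param entropy_bins histogram bin count; default `min(10, length(values))`
#'   so that e.g. three per-ROI density values use three bins.
#' @return named numeric vector `c(mean, sd, skewness, kurtosis, entropy)`.
#' @export
summary_stats <- function(values, entropy_bins = NULL) {
  if (length(values) == 0) stop("summary_stats(): empty sample")
  stopifnot(is.numeric(values), all(is.finite(values)))
  n <- length(values)
  mu <- mean(values)
  if (n == 1) return(c(mean = mu, sd = 0, skewness = 0, kurtosis = 0, entropy = 0))
  s <- stats::sd(values)
  m2 <- mean((values - mu)^2)
  if (m2 == 0) {
    return(c(mean = mu, sd = 0, skewness = 0, kurtosis = 0, entropy = 0))
  }
  skew <- mean((values - mu)^3) / m2^1.5
  kurt <- mean((values - mu)^4) / m2^2 - 3
  bins <- if (is.null(entropy_bins)) min(10L, n) else as.integer(entropy_bins)
  breaks <- seq(min(values), max(values), length.out = bins + 1)
  cnt <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / n
  ent <- -sum(p * log(p))
  c(mean = mu, sd = s, skewness = skew, kurtosis = kurt, entropy = ent)
}

#' Build the per-patient feature vector
#'
#' Nuclear-feature statistics are computed over the megakaryocyte-filtered
#' nuclei pooled across the ROIs (values are sorted before aggregation so
#' the vector is exactly invariant to ROI permutation); density statistics
#' over the per-ROI cell-density values; cellularity is the
#' nucleated-area-weighted combination of the per-ROI cellularities.
#'
#' @param shapes_by_roi list (one element per ROI) of nuclear-shape tibbles
#'   as returned by [region_shapes()] — *all* detected nuclei, unfiltered.
#' @param cellularity_by_roi numeric vector of per-ROI cellularities.
#' @param patient_id patient identifier.
#' @param label optional diagnosis label.
#' @param n_rois_expected required ROI count (default 3); a different count
#'   is an error under the strict study design.
#' @param feature_set see [feature_columns()].
#' @param mk_only compute nuclear statistics over megakaryocyte-filtered
#'   nuclei (default) or over all nuclei.
#' @param ecc_min,caliper_min_um megakaryocyte filter thresholds.
#' @return one-row tibble: `patient_id`, `label`, then [feature_columns()].
#' @export
patient_vector <- function(shapes_by_roi, cellularity_by_roi,
                           patient_id = "patient", label = NA_character_,
                           n_rois_expected = 3,
                           feature_set = c("full21", "paper17"),
                           mk_only = TRUE, ecc_min = 0.8, caliper_min_um = 20) {
  feature_set <- match.arg(feature_set)
  if (length(shapes_by_roi) != n_rois_expected)
    stop(sprintf("patient_vector(): expected %d ROIs, got %d",
                 n_rois_expected, length(shapes_by_roi)))
  stopifnot(length(cellularity_by_roi) == length(shapes_by_roi))

  mk_by_roi <- lapply(shapes_by_roi, filter_megakaryocytes,
                      ecc_min = ecc_min, caliper_min_um = caliper_min_um)
  densities <- vapply(seq_along(shapes_by_roi), function(i)
    cell_density(shapes_by_roi[[i]], mk_by_roi[[i]]), numeric(1))

  pool_src <- if (mk_only) mk_by_roi else shapes_by_roi
  pooled <- do.call(rbind, pool_src)
  if (is.null(pooled) || nrow(pooled) == 0)
    stop("patient_vector(): no megakaryocyte-filtered nuclei; ",
         "the patient cannot be featurized")

  nuclear <- unlist(lapply(c("area_um2", "perimeter_um", "circularity"),
                           function(f) summary_stats(sort(pooled[[f]]), entropy_bins = 10)))
  names(nuclear) <- paste0(rep(c("area", "perimeter", "circularity"), each = 5),
                           "_", rep(c("mean", "sd", "skewness", "kurtosis", "entropy"), 3))

  dens <- summary_stats(sort(densities))
  names(dens) <- paste0("density_", names(dens))

  w <- vapply(shapes_by_roi, function(s) sum(s$area_um2), numeric(1))
  ord <- order(cellularity_by_roi, w)
  cellularity <- sum(w[ord] * cellularity_by_roi[ord]) / sum(w)

  vec <- c(nuclear, dens, cellularity = cellularity)[feature_columns(feature_set)]
  tibble::tibble(patient_id = patient_id, label = label,
                 tibble::as_tibble(as.list(vec)))
}
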