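# Per-nucleus shape descriptors, the megakaryocyte filter and the
# megakaryocyte cell-density statistic.
#
# Circularity is threshold-sensitive to the perimeter estimator, so the
# estimator is fixed and documented here: the 8-connected boundary chain
# (EBImage::ocontour) scored with the corner-corrected chain-code formula
# P = 0.980 n_even + 1.406 n_diag - 0.091 n_corner, which is unbiased to
# ~1% on rasterized discs (plain chain length overestimates by ~5% and
# pushes disc circularity down to ~0.91).

#' Shape descriptors of a single segmented region
#'
#' Computes the nuclear morphometry record used throughout the pipeline:
#' area, perimeter, circularity \eqn{4\pi A / P^2}, ellipse-equivalent
#' eccentricity from pixel-extent-corrected central second moments, and the
#' maximum caliper (Feret) diameter from the convex hull of the boundary.
#'
#' @param mask logical or 0/1 matrix containing a single region, or an
#'   integer label matrix together with `label`.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param label region label to extract when `mask` is a label matrix.
#' @return a one-row [tibble::tibble] with columns `area_um2`,
#'   `perimeter_um`, `circularity`, `eccentricity`, `max_caliper_um`.
#' @examples
#' m <- matrix(FALSE, 40, 40)
#' m[10:30, 15:25] <- TRUE
#' shape_descriptors(m, pixel_size_um = 0.5)
#' @export
shape_descriptors <- function(mask, pixel_size_um, label = NULL) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  m <- if (is.null(label)) mask != 0 else mask == label
  n <- sum(m)
  if (n == 0) stop("shape_descriptors(): region is empty")

  area <- n * pixel_size_um^2
  per_px <- chain_perimeter(m)
  if (per_px <= 0) per_px <- 4 # degenerate (single-pixel) region: unit square
  perimeter <- per_px * pixel_size_um
  circ <- 4 * pi * area / perimeter^2

  idx <- which(m, arr.ind = TRUE)
  x <- idx[, 1]; y <- idx[, 2]
  # central second moments with the 1/12 per-pixel extent term, so a
  # one-pixel-wide line has eccentricity < 1 as required of an ellipse fit
  mu20 <- mean((x - mean(x))^2) + 1 / 12
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))

  caliper <- (max_pairwise_distance(idx) + 1) * pixel_size_um

  tibble::tibble(
    area_um2 = area, perimeter_um = perimeter, circularity = circ,
    eccentricity = ecc, max_caliper_um = caliper
  )
}

# Corner-corrected chain-code perimeter (pixels) of a binary mask; sums over
# connected components so fragmented regions are still scored.
chain_perimeter <- function(m) {
  oc <- EBImage::ocontour(EBImage::bwlabel(EBImage::Image(m * 1)))
  total <- 0
  for (pts in oc) {
    if (nrow(pts) < 2) next
    d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
    steps <- sqrt(rowSums(d^2))
    keep <- steps > 0
    d <- d[keep, , drop = FALSE]; steps <- steps[keep]
    if (length(steps) < 2) next
    ne <- sum(steps < 1.1)
    nd <- sum(steps >= 1.1)
    dirs <- atan2(d[, 2], d[, 1])
    nc <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
    total <- total + 0.980 * ne + 1.406 * nd - 0.091 * nc
  }
  total
}

# Maximum pairwise distance between pixel centres, via the convex hull
# (falls back to all pairs for degenerate point sets).
max_pairwise_distance <- function(idx) {
  if (nrow(idx) == 1) return(0)
  pts <- unique(idx)
  if (nrow(pts) > 3) {
    h <- tryCatch(grDevices::chull(pts[, 1], pts[, 2]), error = function(e) NULL)
    if (!is.null(h) && length(h) >= 2) pts <- pts[h, , drop = FALSE]
  }
  d2 <- as.matrix(stats::dist(pts))
  max(d2)
}

#' Measure every region of a label matrix
#'
#' Applies [shape_descriptors()] to each labelled region, returning one row
#' per region in label order.
#'
#' @param labels integer label matrix (0 = background) or a `region_set` as
#'   returned by the detectors.
#' @param pixel_size_um pixel size in micrometres (taken from the
#'   `region_set` when omitted).
#' @return tibble with a `label` column plus the descriptor columns.
#' @export
region_shapes <- function(labels, pixel_size_um = NULL) {
  if (inherits(labels, "region_set")) {
    if (is.null(pixel_size_um)) pixel_size_um <- labels$pixel_size_um
    labels <- labels$labels
  }
  stopifnot(!is.null(pixel_size_um))
  labs <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(labs) == 0) {
    return(tibble::tibble(
      label = integer(), area_um2 = numeric(), perimeter_um = numeric(),
      circularity = numeric(), eccentricity = numeric(), max_caliper_um = numeric()
    ))
  }
  rows <- lapply(labs, function(l) shape_descriptors(labels, pixel_size_um, label = l))
  out <- do.call(rbind, rows)
  tibble::tibble(label = labs, out)
}

#' Megakaryocyte filter on nuclear shapes
#'
#' Keeps nuclei with eccentricity strictly above `ecc_min` *and* maximum
#' caliper strictly above `caliper_min_um`: the large, elongated/lobulated
#' nuclei characteristic of megakaryocytes. Row order is preserved and the
#' filter is idempotent.
#'
#' @param shapes tibble of nuclear shapes (needs `eccentricity` and
#'   `max_caliper_um` columns).
#' @param ecc_min eccentricity threshold (default 0.8).
#' @param caliper_min_um caliper threshold in micrometres (default 20; the
#'   threshold is unitless in some descriptions, but 20 um matches
#'   megakaryocyte nuclear biology at the 0.5 um working pixel size).
#' @return the subset of `shapes` passing both thresholds.
#' @export
filter_megakaryocytes <- function(shapes, ecc_min = 0.8, caliper_min_um = 20) {
  stopifnot(all(c("eccentricity", "max_caliper_um") %in% names(shapes)))
  shapes[shapes$eccentricity > ecc_min & shapes$max_caliper_um > caliper_min_um, , drop = FALSE]
}

#' Megakaryocyte cell density of an ROI
#'
#' Ratio of total megakaryocyte nuclear area to total nuclear area of all
#' detected cells; quantifies the megakaryocyte load relative to the small
#' erythroid/myeloid background population.
#'
#' @param all_shapes shapes of all nuclei in the ROI.
#' @param mk_shapes shapes of the megakaryocyte-filtered subset.
#' @return a fraction in `[0, 1]`.
#' @export
cell_density <- function(all_shapes, mk_shapes) {
  tot <- sum(all_shapes$area_um2)
  if (!is.finite(tot) || tot <= 0) stop("cell_density(): total nuclear area is zero")
  mk <- if (nrow(mk_shapes) == 0) 0 else sum(mk_shapes$area_um2)
  mk / tot
}
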