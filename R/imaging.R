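# The three-step automatic detection algorithm behind the cellularity
# measurement: background calibration, adipocyte detection and watershed
# nucleated-cell detection, all driven by EBImage.

#' Construct an ROI image
#'
#' @param pixels numeric matrix of 8-bit intensities (0-255), indexed
#'   `[x, y]`, nuclei dark on a light background.
#' @param pixel_size_um physical pixel size, > 0.
#' @param tissue_polygon two-column (x, y) vertex matrix delimiting the
#'   hematopoietic tissue; defaults to the full frame.
#' @param background_polygon vertex matrix over pure background (required
#'   for calibration).
#' @return an object of class `roi_image`.
#' @export
roi_image <- function(pixels, pixel_size_um, tissue_polygon = NULL,
                      background_polygon = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixel_size_um), pixel_size_um > 0)
  dims <- dim(pixels)
  if (is.null(tissue_polygon))
    tissue_polygon <- rect_polygon(1, dims[1], 1, dims[2])
  for (poly in list(tissue_polygon, background_polygon)) {
    if (!is.null(poly) && !polygon_in_grid(poly, dims))
      stop("roi_image(): polygon vertices fall outside the pixel grid")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 tissue_polygon = tissue_polygon,
                 background_polygon = background_polygon),
            class = "roi_image")
}

#' Detection parameters
#'
#' Defaults are the published settings: adipocyte minimum circularity 0.3
#' and minimum size 5 px, dilation of 50 iterations repeated 5 times; cell
#' detection at 0.5 um working pixel size, 8.0 um background radius, 0 um
#' median radius, 1.5 um Gaussian sigma, 10-400 um^2 area gate, intensity
#' threshold 0.1, maximum background intensity 2.0 and 5.0 um cell
#' expansion. `cell_watershed_tolerance` (px, on the distance map) controls
#' how aggressively touching nuclei are split: the default 2.5 splits
#' distinct touching nuclei (deeply necked) while keeping lobed
#' megakaryocyte nuclei (shallow necks) whole.
#'
#' @param ... overrides for any of the defaults.
#' @return a named list of class `detection_params`.
#' @export
detection_params <- function(...) {
  p <- list(
    adip_min_circularity = 0.3, adip_min_size_px = 5,
    adip_dilate_iters = 50, adip_dilate_repeats = 5,
    cell_pixel_size_um = 0.5, cell_background_radius_um = 8.0,
    cell_median_radius_um = 0.0, cell_gaussian_sigma_um = 1.5,
    cell_min_area_um2 = 10, cell_max_area_um2 = 400,
    cell_intensity_threshold = 0.1, cell_max_background_intensity = 2.0,
    cell_expansion_um = 5.0, cell_watershed_tolerance = 2.5, tile_px = 64
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("detection_params(): unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$cell_min_area_um2 < p$cell_max_area_um2,
            p$cell_median_radius_um >= 0)
  structure(p, class = "detection_params")
}

#' Background intensity calibration (Step 1)
#'
#' Mean and SD of the pixels inside the background annotation; used to
#' classify near-background pixels inside the tissue as candidate adipocyte
#' space (dissolved fat leaves holes at background intensity).
#'
#' @param image a `roi_image` with a non-empty `background_polygon`.
#' @return list with `mean`, `sd` and `n_pixels`.
#' @export
calibrate_background <- function(image) {
  stopifnot(inherits(image, "roi_image"))
  if (is.null(image$background_polygon))
    stop("calibrate_background(): missing background annotation")
  mask <- rasterize_polygon(image$background_polygon, dim(image$pixels))
  if (!any(mask))
    stop("calibrate_background(): background polygon covers no pixels")
  v <- image$pixels[mask]
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n_pixels = length(v))
}

# Empty region set helper.
empty_region_set <- function(dims, pixel_size_um) {
  structure(list(
    labels = matrix(0L, dims[1], dims[2]), pixel_size_um = pixel_size_um,
    regions = tibble::tibble(label = integer(), area_um2 = numeric(),
                             perimeter_um = numeric(), centroid_x = numeric(),
                             centroid_y = numeric())
  ), class = "region_set")
}

# Region set from a label matrix: areas/centroids vectorized, perimeters by
# contour tracing.
region_set_from_labels <- function(labels, pixel_size_um, with_perimeter = TRUE) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  labs <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(labs) == 0) return(empty_region_set(dim(labels), pixel_size_um))
  # relabel 1..n
  map <- integer(max(labs)); map[labs] <- seq_along(labs)
  labels[labels > 0] <- map[labels[labels > 0]]
  idx <- which(labels > 0, arr.ind = TRUE)
  l <- labels[labels > 0]
  npx <- tabulate(l, nbins = length(labs))
  cx <- tapply(idx[, 1], l, mean)
  cy <- tapply(idx[, 2], l, mean)
  per <- if (with_perimeter) {
    vapply(seq_along(labs), function(k)
      chain_perimeter(labels == k) * pixel_size_um, numeric(1))
  } else rep(NA_real_, length(labs))
  structure(list(
    labels = labels, pixel_size_um = pixel_size_um,
    regions = tibble::tibble(label = seq_along(labs),
                             area_um2 = npx * pixel_size_um^2,
                             perimeter_um = per,
                             centroid_x = as.numeric(cx),
                             centroid_y = as.numeric(cy))
  ), class = "region_set")
}

#' Adipocyte detection (Step 2)
#'
#' Tissue pixels within a tolerance of the calibrated background intensity
#' (max(2 bg-SD, 4 grey levels)) are binarized, split with a distance-map
#' watershed, consolidated by geodesic dilation (each pass applies
#' `adip_dilate_iters` single-pixel cross dilations constrained to the
#' candidate pixels, interleaved with re-splitting, repeated
#' `adip_dilate_repeats` times; the pass exits early once converged), and
#' finally filtered by minimum circularity and minimum pixel size.
#'
#' @param image a `roi_image`.
#' @param params a [detection_params()].
#' @param bg_stats output of [calibrate_background()].
#' @return a `region_set` of surviving adipocyte regions (possibly empty).
#' @export
detect_adipocytes <- function(image, params = detection_params(),
                              bg_stats = calibrate_background(image)) {
  stopifnot(inherits(image, "roi_image"))
  dims <- dim(image$pixels)
  tissue <- rasterize_polygon(image$tissue_polygon, dims)
  tol <- max(2 * bg_stats$sd, 4)
  candidate <- tissue & abs(image$pixels - bg_stats$mean) <= tol
  if (!any(candidate)) return(empty_region_set(dims, image$pixel_size_um))

  kern <- EBImage::makeBrush(3, shape = "diamond")
  # speckle noise in the near-background window punches pixel holes into
  # the candidate blobs; a one-step closing plus hole filling restores
  # solid regions before splitting
  candidate <- EBImage::imageData(EBImage::fillHull(EBImage::closing(
    EBImage::Image(candidate * 1), kern))) > 0
  candidate <- candidate & tissue
  mask <- candidate
  seg <- EBImage::watershed(EBImage::distmap(EBImage::Image(mask * 1)))
  for (rep_i in seq_len(params$adip_dilate_repeats)) {
    m0 <- mask
    for (it in seq_len(params$adip_dilate_iters)) {
      grown <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), kern)) > 0
      grown <- grown & candidate
      if (identical(grown, mask)) break
      mask <- grown
    }
    seg <- EBImage::watershed(EBImage::distmap(EBImage::Image(mask * 1)))
    if (identical(mask, m0)) break
  }
  seg <- EBImage::imageData(seg)

  rs <- region_set_from_labels(seg, image$pixel_size_um)
  if (nrow(rs$regions) == 0) return(rs)
  keep <- vapply(rs$regions$label, function(l) {
    npx <- sum(rs$labels == l)
    if (npx < params$adip_min_size_px) return(FALSE)
    sh <- shape_descriptors(rs$labels, rs$pixel_size_um, label = l)
    sh$circularity >= params$adip_min_circularity
  }, logical(1))
  drop <- rs$regions$label[!keep]
  if (length(drop)) {
    rs$labels[rs$labels %in% drop] <- 0L
    rs <- region_set_from_labels(rs$labels, rs$pixel_size_um)
  }
  rs
}

#' Nucleated-cell detection (Step 3)
#'
#' Resamples the image to the working pixel size and estimates the local
#' background of the inverted signal by grey-scale opening (same contract
#' as rolling-ball subtraction: structures larger than the background
#' radius survive). Before the opening, pixels outside the tissue
#' annotation and pixels at near-background intensity (adipocyte space,
#' recognised via the Step-1 calibration) are imputed with the median
#' tissue intensity — otherwise every background-level "valley" would
#' depress the estimated background in the surrounding tissue and narrow
#' tissue corridors between adipocytes would surface as fake detections.
#' The residual signal is then optionally median filtered,
#' Gaussian-smoothed, thresholds at `cell_intensity_threshold`
#' (rejecting tiles whose residual background exceeds
#' `cell_max_background_intensity`), splits touching nuclei with a
#' tolerance-controlled distance-map watershed, refines each candidate to
#' the half-maximum contour of its smoothed signal, and keeps regions whose
#' area lies inside the configured gate. The `cell_expansion_um`-dilated
#' cell labels are recorded in the `cell_labels` attribute but unused by
#' the downstream morphometry (all features are nuclear).
#'
#' @param image a `roi_image` with known `pixel_size_um`.
#' @param params a [detection_params()].
#' @param bg_stats optional [calibrate_background()] output; computed from
#'   the image's background annotation when present.
#' @return a `region_set` of nucleus regions at the working pixel size.
#' @export
detect_nucleated_cells <- function(image, params = detection_params(),
                                   bg_stats = NULL) {
  stopifnot(inherits(image, "roi_image"))
  if (is.null(image$pixel_size_um) || !is.finite(image$pixel_size_um))
    stop("detect_nucleated_cells(): pixel_size_um is missing")
  if (is.null(bg_stats) && !is.null(image$background_polygon))
    bg_stats <- calibrate_background(image)
  wps <- params$cell_pixel_size_um
  f <- image$pixel_size_um / wps
  dims <- dim(image$pixels)
  nw <- max(8L, round(dims[1] * f)); nh <- max(8L, round(dims[2] * f))

  x <- EBImage::Image(image$pixels / 255)
  if (abs(f - 1) > 1e-9) x <- EBImage::resize(x, w = nw, h = nh)
  inv <- 1 - x

  tissue <- rasterize_polygon(image$tissue_polygon * f, c(nw, nh))
  near_bg <- matrix(FALSE, nw, nh)
  if (!is.null(bg_stats)) {
    tol <- max(2 * bg_stats$sd, 4)
    near_bg <- abs(EBImage::imageData(x) * 255 - bg_stats$mean) <= tol
  }
  outside <- !tissue | near_bg
  inv_fill <- EBImage::imageData(inv)
  fill_val <- stats::median(inv_fill[!outside])
  if (!is.finite(fill_val)) fill_val <- 0
  inv_fill[outside] <- fill_val

  r_px <- max(1L, round(params$cell_background_radius_um / wps))
  bg <- EBImage::opening(EBImage::Image(inv_fill),
                         EBImage::makeBrush(2 * r_px + 1, shape = "disc"))
  signal <- inv - bg
  if (params$cell_median_radius_um > 0) {
    signal <- EBImage::medianFilter(
      signal, max(1L, round(params$cell_median_radius_um / wps)))
  }
  smooth <- EBImage::gblur(signal, sigma = params$cell_gaussian_sigma_um / wps)
  smooth_m <- EBImage::imageData(smooth)

  ok_tiles <- tile_background_ok(EBImage::imageData(bg), params)
  mask <- smooth_m > params$cell_intensity_threshold & tissue & ok_tiles & !near_bg
  if (!any(mask)) return(empty_region_set(c(nw, nh), wps))

  seg <- EBImage::watershed(EBImage::distmap(EBImage::Image(mask * 1)),
                            tolerance = params$cell_watershed_tolerance)
  seg <- EBImage::imageData(seg)

  # half-maximum boundary refinement: amplitude-invariant, removes the
  # blur halo a global low threshold would include
  lv <- seg[seg > 0]
  peaks <- tapply(smooth_m[seg > 0], lv, max)
  peak_of <- numeric(max(lv)); peak_of[as.integer(names(peaks))] <- peaks
  refined <- seg
  refined[seg > 0 & smooth_m < 0.5 * peak_of[ifelse(seg > 0, seg, 1)]] <- 0L

  rs <- region_set_from_labels(refined, wps, with_perimeter = FALSE)
  if (nrow(rs$regions) == 0) return(rs)
  keep <- rs$regions$area_um2 >= params$cell_min_area_um2 &
    rs$regions$area_um2 <= params$cell_max_area_um2
  drop <- rs$regions$label[!keep]
  if (length(drop)) rs$labels[rs$labels %in% drop] <- 0L
  rs <- region_set_from_labels(rs$labels, wps)

  if (nrow(rs$regions) > 0 && params$cell_expansion_um > 0) {
    exp_px <- round(params$cell_expansion_um / wps)
    dm <- EBImage::distmap(EBImage::Image((rs$labels == 0) * 1))
    grow_mask <- EBImage::imageData(dm) <= exp_px & tissue
    cells <- EBImage::propagate(EBImage::Image(smooth_m), rs$labels,
                                mask = grow_mask)
    attr(rs, "cell_labels") <- EBImage::imageData(cells)
  }
  rs
}

# Tile-level background rejection; with the default threshold of 2.0 on
# unit-scaled intensities this never triggers (units of the original
# parameter are not well defined; it is kept as a pass-through gate).
tile_background_ok <- function(bg, params) {
  nx <- nrow(bg); ny <- ncol(bg); tp <- params$tile_px
  ok <- matrix(TRUE, nx, ny)
  for (ix in seq(1, nx, by = tp)) {
    for (iy in seq(1, ny, by = tp)) {
      xs <- ix:min(ix + tp - 1, nx); ys <- iy:min(iy + tp - 1, ny)
      if (mean(bg[xs, ys]) > params$cell_max_background_intensity)
        ok[xs, ys] <- FALSE
    }
  }
  ok
}

#' Cellularity from detected regions
#'
#' The ratio of nucleated-cell area to the total of nucleated plus
#' adipocyte area. Returns 1 when no adipocyte area was detected but
#' nuclei exist; errors when both areas are zero (cellularity undefined).
#'
#' @param nuclei,adipocytes `region_set`s from the detectors.
#' @return a fraction in `[0, 1]`.
#' @export
compute_cellularity <- function(nuclei, adipocytes) {
  an <- sum(nuclei$regions$area_um2)
  aa <- sum(adipocytes$regions$area_um2)
  if (an + aa <= 0)
    stop("compute_cellularity(): no nucleated or adipocyte area; cellularity undefined")
  an / (an + aa)
}
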