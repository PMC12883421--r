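# Seeded synthetic bone-marrow ROI generator.
#
# Renders single-channel images with dark nuclei on a light background:
# a stroma/cytoplasm field at mid intensity, adipocytes at near-background
# intensity (fat dissolves during preparation, leaving background-coloured
# holes), small round erythroid/myeloid nuclei, and sparse large lobulated
# megakaryocyte nuclei built as unions of collinear-ish offset discs so that
# their eccentricity and maximum caliper exceed the megakaryocyte filter
# thresholds. Ground-truth label masks and the exact mask-level cellularity
# are carried alongside the image, so every downstream stage can be tested
# without real slides.

# Rendering constants (8-bit grey levels). Nuclear contrast is chosen so the
# default detection threshold sits well below the smoothed nuclear signal,
# and background/adipocyte intensities coincide up to small noise.
SYNTH_BG_LEVEL <- 242
SYNTH_TISSUE_LEVEL <- 185
SYNTH_NUCLEUS_LEVEL <- 95
SYNTH_BG_NOISE <- 1.5
SYNTH_TISSUE_NOISE <- 5
SYNTH_MK_AREA_RANGE <- c(140, 380) # um^2; keeps MK inside the 400 um^2 gate
SYNTH_SMALL_AREA_RANGE <- c(12, 80) # um^2; keeps small-nucleus caliper << 20 um

#' Generate synthetic ROIs for one patient
#'
#' Draws a target cellularity per ROI from the profile's clipped Gaussian,
#' converts it into area budgets for nucleated cells and adipocytes at a
#' fixed packing fraction of the tissue area, plants non-overlapping
#' megakaryocytes, small nuclei and adipocytes by rejection sampling, and
#' renders the intensity image. Every planted megakaryocyte is verified at
#' build time to pass the eccentricity/caliper filter on its own mask, and
#' every small nucleus to fail it.
#'
#' @param profile a [class_profile()].
#' @param n_rois number of ROIs (the study design uses 3 per patient).
#' @param seed integer seed; identical `(profile, seed)` gives bit-identical
#'   output.
#' @param image_size_px side length of the square image in pixels.
#' @param pixel_size_um physical pixel size (default 0.25 um, a 40x scan;
#'   detection resamples to its own working resolution).
#' @param packing_fraction fraction of the tissue area occupied by planted
#'   objects (default 0.30; higher values make non-overlapping placement
#'   fail).
#' @param margin_px width of the pure-background frame around the tissue.
#' @param gap_px minimum clearance (px) enforced between planted objects on
#'   each side; keeps the Gaussian-blurred detection masks of neighbouring
#'   nuclei from merging.
#' @param max_attempts placement attempts per object before the profile is
#'   rejected as unpackable.
#' @return list of `synthetic_roi` objects; each has fields `pixels`,
#'   `pixel_size_um`, `tissue_polygon`, `background_polygon`,
#'   `nucleus_mask`, `adipocyte_mask`, `nucleus_flags` (tibble with
#'   `label`, `is_megakaryocyte`) and `true_cellularity` (computed exactly
#'   from the masks).
#' @export
generate_patient_rois <- function(profile, n_rois = 3, seed = 1,
                                  image_size_px = 448, pixel_size_um = 0.25,
                                  packing_fraction = 0.30, margin_px = 28,
                                  gap_px = 5, max_attempts = 2000) {
  stopifnot(inherits(profile, "class_profile"), n_rois >= 1)
  set.seed(as.integer(seed))
  lapply(seq_len(n_rois), function(i) {
    # rejection-sampled placement can jam on dense draws; retry the whole
    # ROI with fresh draws a bounded number of times before giving up
    for (restart in 1:6) {
      out <- tryCatch(
        generate_roi(profile, image_size_px, pixel_size_um,
                     packing_fraction, margin_px, gap_px, max_attempts),
        mpnmorph_pack_error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
    stop("generate_patient_rois(): could not pack the requested object density; ",
         "lower packing_fraction or the object counts")
  })
}

#' Generate synthetic ROIs for an intermediate (MPN-NOS-like) patient
#'
#' Parameters are the convex combination of two class profiles; `mix = 0`
#' reproduces `generate_patient_rois(profile_a, ...)` exactly and
#' `mix = 1` reproduces `profile_b`. Intermediate mixes emulate the
#' overlapping morphology of cases that defy clean subtyping.
#'
#' @param profile_a,profile_b the two endpoint [class_profile()]s.
#' @param mix mixing fraction in `[0, 1]` (weight of `profile_b`).
#' @param seed integer seed.
#' @param ... passed to [generate_patient_rois()].
#' @return list of `synthetic_roi` objects.
#' @export
generate_nos_patient <- function(profile_a, profile_b, mix, seed = 1, ...) {
  generate_patient_rois(mix_profiles(profile_a, profile_b, mix), seed = seed, ...)
}

# One ROI; consumes the ambient RNG stream.
generate_roi <- function(profile, image_size_px, pixel_size_um,
                         packing_fraction, margin_px, gap_px, max_attempts) {
  n <- as.integer(image_size_px)
  ps <- pixel_size_um
  dims <- c(n, n)
  m <- as.integer(margin_px)
  tissue_poly <- rect_polygon(m + 1, n - m, m + 1, n - m)
  bg_poly <- rect_polygon(4, n - 3, 4, m - 8)

  tissue_px <- (n - 2 * m)^2
  tissue_um2 <- tissue_px * ps^2

  # --- area budgets ----------------------------------------------------
  cl <- profile$cellularity_clip
  target_c <- min(max(stats::rnorm(1, profile$cellularity_mean,
                                   profile$cellularity_sd), cl[1]), cl[2])
  a_total <- packing_fraction * tissue_um2
  a_nuc <- target_c * a_total
  a_adip <- a_total - a_nuc

  if (profile$mk_fraction_mean == 0) {
    mk_frac <- 0
    n_mk <- 0L
  } else {
    mk_frac <- min(max(stats::rnorm(1, profile$mk_fraction_mean,
                                    profile$mk_fraction_sd), 0), 0.6)
    n_mk <- max(1L, as.integer(round(mk_frac * a_nuc / profile$mk_area_mean_um2)))
  }
  mk_areas <- if (n_mk > 0) {
    pmin(pmax(stats::rnorm(n_mk, profile$mk_area_mean_um2, profile$mk_area_sd_um2),
              SYNTH_MK_AREA_RANGE[1]), SYNTH_MK_AREA_RANGE[2])
  } else numeric()

  a_small <- max(0, a_nuc - sum(mk_areas))
  n_small <- max(0L, as.integer(round(a_small / profile$small_cell_area_mean_um2)))
  small_areas <- if (n_small > 0) {
    pmin(pmax(stats::rnorm(n_small, profile$small_cell_area_mean_um2,
                           0.22 * profile$small_cell_area_mean_um2),
              SYNTH_SMALL_AREA_RANGE[1]), SYNTH_SMALL_AREA_RANGE[2])
  } else numeric()

  rng <- profile$adipocyte_radius_um_range
  adip_radii <- numeric()
  acc <- 0
  while (acc < a_adip && length(adip_radii) < 40) {
    r <- stats::runif(1, rng[1], rng[2])
    if (acc + pi * r^2 > a_adip) {
      r <- sqrt(max(a_adip - acc, pi * (0.6 * rng[1])^2) / pi)
      r <- min(r, rng[2])
    }
    adip_radii <- c(adip_radii, r)
    acc <- acc + pi * r^2
  }

  # --- build footprints (pixel offset sets, verified shapes) -----------
  mk_foot <- lapply(mk_areas, function(a)
    build_mk_footprint(a, profile$mk_lobulation, ps, gap_px))
  small_foot <- lapply(small_areas, function(a) {
    r <- sqrt(a / pi) / ps
    list(pts = disc_offsets(r), bound = r, coll = disc_offsets(r + gap_px),
         is_mk = FALSE)
  })
  adip_foot <- lapply(adip_radii, function(r_um) {
    r <- r_um / ps
    list(pts = disc_offsets(r), bound = r, coll = disc_offsets(r + gap_px))
  })

  # --- placement: largest first, mask-based rejection sampling ---------
  occ <- matrix(FALSE, n, n)
  nucleus_mask <- matrix(0L, n, n)
  adipocyte_mask <- matrix(0L, n, n)
  is_mk_flag <- logical()
  lab <- 0L

  place <- function(foot, write_to) {
    lo <- m + 1 + ceiling(foot$bound)
    hi <- n - m - ceiling(foot$bound)
    if (hi <= lo) stop("generate_patient_rois(): object too large for the tissue area")
    for (att in seq_len(max_attempts)) {
      cx <- stats::runif(1, lo, hi)
      cy <- stats::runif(1, lo, hi)
      coll_idx <- offsets_at(foot$coll, cx, cy, dims)
      if (!any(occ[coll_idx])) {
        occ[coll_idx] <<- TRUE
        idx <- offsets_at(foot$pts, cx, cy, dims)
        if (write_to == "nucleus") {
          lab <<- lab + 1L
          nucleus_mask[idx] <<- lab
        } else {
          adipocyte_mask[idx] <<- max(adipocyte_mask) + 1L
        }
        return(invisible(TRUE))
      }
    }
    stop(structure(class = c("mpnmorph_pack_error", "error", "condition"),
                   list(message = "placement jammed", call = NULL)))
  }

  for (f in mk_foot[order(-vapply(mk_foot, function(x) nrow(x$pts), 1))]) {
    place(f, "nucleus"); is_mk_flag <- c(is_mk_flag, TRUE)
  }
  for (f in adip_foot[order(-vapply(adip_foot, function(x) nrow(x$pts), 1))]) {
    place(f, "adipocyte")
  }
  for (f in small_foot[order(-vapply(small_foot, function(x) nrow(x$pts), 1))]) {
    place(f, "nucleus"); is_mk_flag <- c(is_mk_flag, FALSE)
  }

  # --- build-time verification of the planted shapes -------------------
  flags <- tibble::tibble(label = seq_len(lab), is_megakaryocyte = is_mk_flag)
  if (lab > 0) {
    sh <- region_shapes(nucleus_mask, ps)
    passed <- sh$eccentricity > 0.8 & sh$max_caliper_um > 20
    if (!identical(unname(passed), unname(flags$is_megakaryocyte)))
      stop("generate_patient_rois(): internal shape verification failed")
  }

  # --- render ----------------------------------------------------------
  px <- matrix(stats::rnorm(n * n, SYNTH_BG_LEVEL, SYNTH_BG_NOISE), n, n)
  tis <- rasterize_polygon(tissue_poly, dims)
  n_tis <- sum(tis)
  px[tis] <- stats::rnorm(n_tis, SYNTH_TISSUE_LEVEL, SYNTH_TISSUE_NOISE)
  adi <- adipocyte_mask > 0
  px[adi] <- stats::rnorm(sum(adi), SYNTH_BG_LEVEL, SYNTH_BG_NOISE)
  nuc <- nucleus_mask > 0
  px[nuc] <- stats::rnorm(sum(nuc), SYNTH_NUCLEUS_LEVEL, SYNTH_TISSUE_NOISE)
  px <- round(pmin(pmax(px, 0), 255))

  structure(list(
    pixels = px, pixel_size_um = ps,
    tissue_polygon = tissue_poly, background_polygon = bg_poly,
    nucleus_mask = nucleus_mask, adipocyte_mask = adipocyte_mask,
    nucleus_flags = flags,
    true_cellularity = sum(nuc) / (sum(nuc) + sum(adi))
  ), class = c("synthetic_roi", "roi_image"))
}

# Megakaryocyte footprint: union of `lobes` offset discs with collinear-ish
# centres at a fixed spacing of 1.2 lobe radii (shallow necks, so a
# tolerance-controlled watershed keeps the nucleus whole while still
# splitting distinct touching nuclei). The lobe radius
# is solved from the target area (accounting for pairwise disc overlap);
# the lobe count is raised above the profile value when needed so the
# nominal caliper clears the 20 um filter threshold with margin. The
# rasterized shape is then measured with shape_descriptors(); if pixelation
# or jitter pushes it below the filter thresholds the jitter is redrawn.
build_mk_footprint <- function(area_um2, lobes, pixel_size_um, gap_px = 5) {
  sf <- 1.2
  ov <- 2 * (acos(sf / 2) - (sf / 2) * sqrt(1 - sf^2 / 4)) # overlap / r^2
  L <- max(2L, as.integer(lobes))
  repeat {
    r_um <- sqrt(area_um2 / (pi * L - ov * (L - 1)))
    caliper <- ((L - 1) * sf + 2) * r_um
    if (caliper > 22 || L > lobes + 3) break
    L <- L + 1L
  }
  r <- r_um / pixel_size_um
  d <- sf * r
  for (try in 1:25) {
    theta <- stats::runif(1, 0, 2 * pi)
    along <- (seq_len(L) - (L + 1) / 2) * d
    perp <- stats::rnorm(L, 0, 0.10 * r)
    cx <- round(along * cos(theta) - perp * sin(theta))
    cy <- round(along * sin(theta) + perp * cos(theta))
    base <- disc_offsets(r)
    pts <- unique(do.call(rbind, lapply(seq_len(L), function(i)
      cbind(base[, 1] + cx[i], base[, 2] + cy[i]))))
    sh <- shape_descriptors(mask_from_points(pts), pixel_size_um)
    if (sh$eccentricity > 0.82 && sh$max_caliper_um > 20.5) {
      coll <- unique(do.call(rbind, lapply(seq_len(L), function(i) {
        b <- disc_offsets(r + gap_px)
        cbind(b[, 1] + cx[i], b[, 2] + cy[i])
      })))
      bound <- max(sqrt(pts[, 1]^2 + pts[, 2]^2)) + 1
      return(list(pts = pts, coll = coll, bound = bound, is_mk = TRUE))
    }
  }
  stop("build_mk_footprint(): could not realise a filter-passing megakaryocyte shape")
}

# Minimal binary matrix containing a set of integer (x, y) offsets.
mask_from_points <- function(pts) {
  x <- pts[, 1] - min(pts[, 1]) + 1L
  y <- pts[, 2] - min(pts[, 2]) + 1L
  mm <- matrix(FALSE, max(x), max(y))
  mm[cbind(x, y)] <- TRUE
  mm
}
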