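# Class-conditional generator profiles for the three MPN subtypes.

MPN_CLASSES <- c("pre-PMF", "PV", "ET")

#' Construct a class profile for the synthetic generator
#'
#' A `class_profile` bundles the distributional parameters the generator
#' draws from for one diagnosis class: the cellularity distribution, the
#' megakaryocyte (MK) load and nuclear-size distribution, the small
#' (erythroid/myeloid) nucleus size, the nuclear lobe count and the
#' adipocyte radius range.
#'
#' @param label diagnosis class label.
#' @param cellularity_mean,cellularity_sd cellularity distribution
#'   (unitless fraction); draws are clipped to mean +/- 3 sd and to (0, 1).
#' @param mk_fraction_mean,mk_fraction_sd expected fraction of total nuclear
#'   area contributed by megakaryocytes.
#' @param mk_area_mean_um2,mk_area_sd_um2 megakaryocyte nuclear area (um^2).
#' @param small_cell_area_mean_um2 small-nucleus area (um^2).
#' @param mk_lobulation integer >= 2, number of nuclear lobes rendered.
#' @param adipocyte_radius_um_range length-2 positive range of adipocyte
#'   radii (um).
#' @return an object of class `class_profile` (a named list).
#' @export
class_profile <- function(label,
                          cellularity_mean, cellularity_sd,
                          mk_fraction_mean = 0.25, mk_fraction_sd = 0.06,
                          mk_area_mean_um2 = 220, mk_area_sd_um2 = 45,
                          small_cell_area_mean_um2 = 30,
                          mk_lobulation = 3L,
                          adipocyte_radius_um_range = c(6, 14)) {
  stopifnot(
    cellularity_sd >= 0, mk_fraction_sd >= 0, mk_area_sd_um2 >= 0,
    mk_area_mean_um2 > small_cell_area_mean_um2,
    mk_lobulation >= 2, length(adipocyte_radius_um_range) == 2,
    all(adipocyte_radius_um_range > 0)
  )
  lo <- max(cellularity_mean - 3 * cellularity_sd, 0.01)
  hi <- min(cellularity_mean + 3 * cellularity_sd, 0.99)
  stopifnot(lo < hi, cellularity_mean > 0, cellularity_mean < 1)
  structure(list(
    label = label,
    cellularity_mean = cellularity_mean, cellularity_sd = cellularity_sd,
    cellularity_clip = c(lo, hi),
    mk_fraction_mean = mk_fraction_mean, mk_fraction_sd = mk_fraction_sd,
    mk_area_mean_um2 = mk_area_mean_um2, mk_area_sd_um2 = mk_area_sd_um2,
    small_cell_area_mean_um2 = small_cell_area_mean_um2,
    mk_lobulation = as.integer(mk_lobulation),
    adipocyte_radius_um_range = as.numeric(adipocyte_radius_um_range)
  ), class = "class_profile")
}

#' Default generator profiles for pre-PMF, PV and ET
#'
#' Cellularity parameters are the published cohort means and standard
#' deviations (0.55 +/- 0.12 pre-PMF, 0.67 +/- 0.13 PV, 0.65 +/- 0.14 ET).
#' Megakaryocyte parameters are documented defaults reflecting subtype
#' morphology: ET megakaryocytes are rendered largest and most lobulated
#' (giant hyperlobulated forms), pre-PMF intermediate-to-large with high
#' lobulation (atypical, bulbous nuclei), PV smaller and more pleomorphic.
#'
#' @return named list of three [class_profile()] objects
#'   (`pre-PMF`, `PV`, `ET`).
#' @export
make_default_profiles <- function() {
  list(
    "pre-PMF" = class_profile(
      "pre-PMF", cellularity_mean = 0.55, cellularity_sd = 0.12,
      mk_fraction_mean = 0.30, mk_fraction_sd = 0.06,
      mk_area_mean_um2 = 230, mk_area_sd_um2 = 45,
      small_cell_area_mean_um2 = 28, mk_lobulation = 4L
    ),
    "PV" = class_profile(
      "PV", cellularity_mean = 0.67, cellularity_sd = 0.13,
      mk_fraction_mean = 0.24, mk_fraction_sd = 0.06,
      mk_area_mean_um2 = 200, mk_area_sd_um2 = 45,
      small_cell_area_mean_um2 = 30, mk_lobulation = 3L
    ),
    "ET" = class_profile(
      "ET", cellularity_mean = 0.65, cellularity_sd = 0.14,
      mk_fraction_mean = 0.27, mk_fraction_sd = 0.06,
      mk_area_mean_um2 = 260, mk_area_sd_um2 = 45,
      small_cell_area_mean_um2 = 29, mk_lobulation = 5L
    )
  )
}

# Convex combination of two profiles (numeric fields); mix = 0 returns a
# profile identical to `a`, mix = 1 identical to `b`.
mix_profiles <- function(a, b, mix) {
  stopifnot(inherits(a, "class_profile"), inherits(b, "class_profile"),
            mix >= 0, mix <= 1)
  cvx <- function(f) (1 - mix) * a[[f]] + mix * b[[f]]
  label <- if (mix == 0) a$label else if (mix == 1) b$label else
    sprintf("mix(%s,%s,%.3f)", a$label, b$label, mix)
  class_profile(
    label,
    cellularity_mean = cvx("cellularity_mean"),
    cellularity_sd = cvx("cellularity_sd"),
    mk_fraction_mean = cvx("mk_fraction_mean"),
    mk_fraction_sd = cvx("mk_fraction_sd"),
    mk_area_mean_um2 = cvx("mk_area_mean_um2"),
    mk_area_sd_um2 = cvx("mk_area_sd_um2"),
    small_cell_area_mean_um2 = cvx("small_cell_area_mean_um2"),
    mk_lobulation = as.integer(round(cvx("mk_lobulation"))),
    adipocyte_radius_um_range = cvx("adipocyte_radius_um_range")
  )
}
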