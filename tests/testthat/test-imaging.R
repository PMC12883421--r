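# Background calibration, adipocyte and nucleated-cell detection, and the
# cellularity ratio.

make_flat_roi <- function(level = 240, n = 64) {
  roi_image(matrix(level, n, n), pixel_size_um = 0.5,
            tissue_polygon = rect_polygon(10, n - 9, 10, n - 9),
            background_polygon = rect_polygon(2, n - 1, 2, 7))
}

test_that("background calibration returns the annotation statistics", {
  bg <- calibrate_background(make_flat_roi(240))
  expect_equal(bg$mean, 240)
  expect_equal(bg$sd, 0)
})

test_that("polygons outside the grid and missing annotations error", {
  expect_error(roi_image(matrix(0, 10, 10), 0.5,
                         background_polygon = rect_polygon(2, 20, 2, 5)),
               "outside")
  r <- roi_image(matrix(0, 10, 10), 0.5)
  expect_error(calibrate_background(r), "background")
})

test_that("synthetic background calibrates to the rendering constant", {
  r <- cached_rois()[[2]]
  bg <- calibrate_background(r)
  expect_lt(abs(bg$mean - 242), 1)
})

test_that("tissue without near-background pixels yields no adipocytes", {
  r <- make_flat_roi(240)
  tis <- mpnmorph:::rasterize_polygon(r$tissue_polygon, dim(r$pixels))
  r$pixels[tis] <- 150 # tissue well away from background intensity
  ad <- detect_adipocytes(r)
  expect_equal(nrow(ad$regions), 0)
})

test_that("planted adipocytes are recovered one-to-one", {
  for (r in cached_rois()[1:2]) {
    ad <- detect_adipocytes(r, bg_stats = calibrate_background(r))
    expect_equal(nrow(ad$regions), max(r$adipocyte_mask))
    expect_equal(sum(ad$regions$area_um2),
                 sum(r$adipocyte_mask > 0) * r$pixel_size_um^2,
                 tolerance = 0.02)
  }
})

test_that("a thin near-background rectangle is removed by the circularity filter", {
  n <- 100
  px <- matrix(150, n, n)
  px[20:80, 48:50] <- 240 # 61 x 3 strip: 4*pi*A/P^2 ~ 0.14 < 0.3
  px[30:40, 65:75] <- 240 # a square blob that passes
  r <- roi_image(px, 0.5, tissue_polygon = rect_polygon(10, 90, 10, 90),
                 background_polygon = rect_polygon(2, 98, 2, 6))
  r$pixels[2:98, 2:6] <- 240
  ad <- detect_adipocytes(r)
  expect_equal(nrow(ad$regions), 1)
  expect_equal(ad$regions$area_um2, 11 * 11 * 0.25)
})

test_that("a blank image yields no nucleated cells", {
  nu <- detect_nucleated_cells(make_flat_roi(240))
  expect_equal(nrow(nu$regions), 0)
})

test_that("missing pixel size errors", {
  r <- make_flat_roi()
  r$pixel_size_um <- NA_real_
  expect_error(detect_nucleated_cells(r), "pixel_size")
})

test_that("planted nucleus count is recovered within 5% on a sparse ROI", {
  p <- make_default_profiles()$PV
  r <- generate_patient_rois(p, n_rois = 1, seed = 42, packing_fraction = 0.2)[[1]]
  nu <- detect_nucleated_cells(r)
  n_true <- nrow(r$nucleus_flags)
  expect_lte(abs(nrow(nu$regions) - n_true), ceiling(0.05 * n_true))
})

test_that("a 600 um^2 round nucleus is excluded by the 400 um^2 gate", {
  n <- 200
  px <- matrix(185, n, n)
  xy <- expand.grid(x = 1:n, y = 1:n)
  inside <- matrix((xy$x - 100)^2 + (xy$y - 100)^2 <= (sqrt(600 / pi) / 0.25)^2, n, n)
  px[inside] <- 95
  r <- roi_image(px, 0.25, tissue_polygon = rect_polygon(15, 185, 15, 185),
                 background_polygon = rect_polygon(2, 198, 2, 8))
  r$pixels[2:198, 2:8] <- 242
  nu <- detect_nucleated_cells(r)
  expect_equal(nrow(nu$regions), 0)
})

test_that("cellularity follows the area ratio with its edge cases", {
  mk_rs <- function(area) {
    rs <- mpnmorph:::empty_region_set(c(4, 4), 1)
    if (length(area)) rs$regions <- tibble::tibble(
      label = seq_along(area), area_um2 = area, perimeter_um = NA_real_,
      centroid_x = 0, centroid_y = 0)
    rs
  }
  expect_equal(compute_cellularity(mk_rs(60), mk_rs(40)), 0.6)
  expect_equal(compute_cellularity(mk_rs(c(10, 50)), mk_rs(numeric())), 1)
  expect_error(compute_cellularity(mk_rs(numeric()), mk_rs(numeric())), "undefined")
  # monotonicity
  base <- compute_cellularity(mk_rs(60), mk_rs(40))
  expect_lt(compute_cellularity(mk_rs(60), mk_rs(c(40, 10))), base)
  expect_gt(compute_cellularity(mk_rs(c(60, 10)), mk_rs(40)), base)
})

test_that("detection recovers mask-level cellularity on full synthetic ROIs", {
  for (r in cached_rois()) {
    est <- compute_cellularity(detect_nucleated_cells(r),
                               detect_adipocytes(r, bg_stats = calibrate_background(r)))
    expect_lte(abs(est - r$true_cellularity), 0.05)
  }
})

test_that("detection is deterministic for fixed image and params", {
  r <- cached_rois()[[1]]
  expect_identical(detect_nucleated_cells(r), detect_nucleated_cells(r))
  bg <- calibrate_background(r)
  expect_identical(detect_adipocytes(r, bg_stats = bg),
                   detect_adipocytes(r, bg_stats = bg))
})

test_that("areas in um^2 are stable under 2x resampling", {
  r <- cached_rois()[[2]]
  half <- EBImage::imageData(EBImage::resize(EBImage::Image(r$pixels / 255),
                                             w = nrow(r$pixels) / 2)) * 255
  r2 <- roi_image(half, r$pixel_size_um * 2,
                  tissue_polygon = r$tissue_polygon / 2,
                  background_polygon = r$background_polygon / 2)
  a1 <- sum(detect_nucleated_cells(r)$regions$area_um2)
  a2 <- sum(detect_nucleated_cells(r2)$regions$area_um2)
  expect_lt(abs(a1 - a2) / a1, 0.05)
})
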