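# Synthetic cohort generator: default profiles, determinism, mask
# bookkeeping and the build-time shape guarantees.

test_that("default profiles carry the cohort cellularity parameters", {
  prs <- make_default_profiles()
  expect_named(prs, c("pre-PMF", "PV", "ET"))
  expect_equal(prs[["pre-PMF"]]$cellularity_mean, 0.55)
  expect_equal(prs[["pre-PMF"]]$cellularity_sd, 0.12)
  expect_equal(prs[["PV"]]$cellularity_mean, 0.67)
  expect_equal(prs[["PV"]]$cellularity_sd, 0.13)
  expect_equal(prs[["ET"]]$cellularity_mean, 0.65)
  expect_equal(prs[["ET"]]$cellularity_sd, 0.14)
  for (p in prs) expect_gt(p$mk_area_mean_um2, p$small_cell_area_mean_um2)
})

test_that("profile invariants are enforced", {
  expect_error(class_profile("x", cellularity_mean = 0.5, cellularity_sd = 0.12,
                             mk_area_mean_um2 = 20, small_cell_area_mean_um2 = 30))
  expect_error(class_profile("x", cellularity_mean = 0.5, cellularity_sd = -0.1))
})

test_that("identical seeds give bit-identical ROIs", {
  p <- make_default_profiles()$PV
  a <- generate_patient_rois(p, n_rois = 1, seed = 7)
  b <- generate_patient_rois(p, n_rois = 1, seed = 7)
  expect_identical(a, b)
})

test_that("masks are disjoint and cellularity matches the masks exactly", {
  for (r in cached_rois()) {
    expect_true(all(!(r$nucleus_mask > 0 & r$adipocyte_mask > 0)))
    nuc <- sum(r$nucleus_mask > 0); adi <- sum(r$adipocyte_mask > 0)
    expect_identical(r$true_cellularity, nuc / (nuc + adi))
    expect_gte(r$true_cellularity, 0); expect_lte(r$true_cellularity, 1)
  }
})

test_that("achieved cellularity tracks the profile draw within tolerance", {
  # the documented discretization tolerance is 0.03 on the per-ROI target;
  # targets are clipped Gaussians around the class mean
  p <- make_default_profiles()$PV
  cs <- vapply(1:8, function(s)
    generate_patient_rois(p, n_rois = 1, seed = 200 + s)[[1]]$true_cellularity,
    numeric(1))
  expect_true(all(cs > p$cellularity_clip[1] - 0.03 &
                  cs < p$cellularity_clip[2] + 0.03))
  set.seed(1)
  targets <- pmin(pmax(rnorm(5000, p$cellularity_mean, p$cellularity_sd),
                       p$cellularity_clip[1]), p$cellularity_clip[2])
  expect_lt(abs(mean(targets) - p$cellularity_mean), 0.01)
})

test_that("planted megakaryocytes pass the filter and small nuclei fail it", {
  for (r in cached_rois()) {
    sh <- region_shapes(r$nucleus_mask, r$pixel_size_um)
    pass <- sh$eccentricity > 0.8 & sh$max_caliper_um > 20
    expect_identical(unname(pass), r$nucleus_flags$is_megakaryocyte)
  }
})

test_that("a zero megakaryocyte fraction plants no megakaryocytes", {
  p <- class_profile("none", cellularity_mean = 0.6, cellularity_sd = 0.05,
                     mk_fraction_mean = 0, mk_fraction_sd = 0)
  r <- generate_patient_rois(p, n_rois = 1, seed = 2)[[1]]
  expect_equal(sum(r$nucleus_flags$is_megakaryocyte), 0)
})

test_that("an unpackable density is rejected with an error", {
  p <- make_default_profiles()$PV
  expect_error(
    generate_patient_rois(p, n_rois = 1, seed = 1, packing_fraction = 0.9,
                          max_attempts = 10),
    "pack")
})

test_that("NOS mixtures reproduce the endpoints and interpolate parameters", {
  prs <- make_default_profiles()
  a0 <- generate_nos_patient(prs$ET, prs$PV, mix = 0, seed = 3, n_rois = 1)
  ref <- generate_patient_rois(prs$ET, n_rois = 1, seed = 3)
  expect_identical(a0, ref)
  a1 <- generate_nos_patient(prs$ET, prs$PV, mix = 1, seed = 3, n_rois = 1)
  ref1 <- generate_patient_rois(prs$PV, n_rois = 1, seed = 3)
  expect_identical(a1, ref1)
  mid <- mpnmorph:::mix_profiles(prs$ET, prs$PV, 0.5)
  expect_equal(mid$cellularity_mean, (0.65 + 0.67) / 2)
  expect_equal(mid$mk_area_mean_um2, (260 + 200) / 2)
})

test_that("feature cohorts recover class means exactly at zero noise", {
  prs <- make_default_profiles()
  X <- generate_feature_cohort(prs, n_per_class = 5, noise_scale = 0, seed = 9)
  expect_equal(nrow(X), 15)
  fc <- feature_columns()
  for (nm in names(prs)) {
    mu <- feature_class_means(prs[[nm]])[fc]
    sub <- as.matrix(X[X$label == nm, fc])
    expect_true(all(apply(sub, 2, stats::sd) == 0))
    expect_equal(unname(colMeans(sub)), unname(mu))
  }
})

test_that("informative columns separate classes by at least one noise SD", {
  prs <- make_default_profiles()
  tmpl <- mpnmorph:::feature_noise_template()
  mus <- sapply(prs, feature_class_means)
  informative <- c("area_mean", "perimeter_mean", "circularity_mean", "density_mean")
  for (f in informative) {
    d <- sort(mus[f, ])
    expect_gte(min(diff(d)) / tmpl[[f]], 1 - 1e-9)
  }
  # cellularity mirrors the published pattern: pre-PMF separated from PV
  expect_gte((mus["cellularity", "PV"] - mus["cellularity", "pre-PMF"]) / 0.13, 0.9)
})

test_that("Kruskal-Wallis flags every column separated by >= 1 SD (n = 30)", {
  prs <- make_default_profiles()
  X <- generate_feature_cohort(prs, n_per_class = 30, seed = 1)
  sel <- kruskal_wallis_select(X[feature_columns()], X$label)
  tmpl <- mpnmorph:::feature_noise_template()
  mus <- sapply(prs, feature_class_means)
  for (f in feature_columns("full21")) {
    sdv <- if (f == "cellularity") 0.13 else tmpl[[f]]
    if (max(mus[f, ]) - min(mus[f, ]) >= sdv)
      expect_true(f %in% sel$selected, label = paste("selected:", f))
  }
})
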