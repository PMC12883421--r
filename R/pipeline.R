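# End-to-end pipeline: segment -> morphometry -> features -> train/eval ->
# NOS prediction, with per-stage logging and a provenance record.

#' Pipeline configuration
#'
#' One document holding every stage's parameters with the published
#' defaults, so the configuration in force is auditable in a single place.
#'
#' @param ... overrides, named after the entries below (nested lists are
#'   replaced wholesale).
#' @return a named list of class `mpn_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    detection = detection_params(),
    morphometry = list(ecc_min = 0.8, caliper_min_um = 20),
    features = list(feature_set = "full21", n_rois = 3, mk_only = TRUE),
    model = list(alpha = 0.05, cost = 1, k = 5, repeats = 5,
                 nested_selection = FALSE, gmean_sqrt = FALSE)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("pipeline_config(): unknown section(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(ov)) cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
  structure(cfg, class = "mpn_config")
}

# Segment one ROI and return its nuclear shapes plus cellularity.
process_roi <- function(roi, cfg, verbose = FALSE) {
  bg <- calibrate_background(roi)
  adip <- detect_adipocytes(roi, cfg$detection, bg)
  nuc <- detect_nucleated_cells(roi, cfg$detection)
  shapes <- region_shapes(nuc)
  cellularity <- compute_cellularity(nuc, adip)
  if (verbose) {
    mk <- filter_megakaryocytes(shapes, cfg$morphometry$ecc_min,
                                cfg$morphometry$caliper_min_um)
    message(sprintf("  ROI: %d nuclei, %d adipocytes, %d megakaryocytes, cellularity %.3f",
                    nrow(shapes), nrow(adip$regions), nrow(mk), cellularity))
  }
  list(shapes = shapes, cellularity = cellularity,
       n_adipocytes = nrow(adip$regions))
}

#' Featurize one patient from ROI images
#'
#' Runs detection and morphometry on each ROI and assembles the patient
#' feature vector.
#'
#' @param rois list of `roi_image`s (one patient).
#' @param cfg a [pipeline_config()].
#' @param patient_id,label passed through to [patient_vector()].
#' @param verbose log per-ROI counts.
#' @return one-row feature tibble.
#' @export
featurize_patient <- function(rois, cfg = pipeline_config(),
                              patient_id = "patient", label = NA_character_,
                              verbose = FALSE) {
  proc <- lapply(rois, process_roi, cfg = cfg, verbose = verbose)
  patient_vector(
    lapply(proc, `[[`, "shapes"),
    vapply(proc, `[[`, numeric(1), "cellularity"),
    patient_id = patient_id, label = label,
    n_rois_expected = cfg$features$n_rois,
    feature_set = cfg$features$feature_set, mk_only = cfg$features$mk_only,
    ecc_min = cfg$morphometry$ecc_min,
    caliper_min_um = cfg$morphometry$caliper_min_um
  )
}

#' Run the full pipeline on a cohort manifest
#'
#' Executes segmentation, morphometry and feature building for every
#' patient, screens features with the Kruskal-Wallis test on the labelled
#' (non-NOS) patients, evaluates a linear SVM with repeated stratified
#' cross-validation, refits on the full labelled cohort, and assigns any
#' NOS patients by maximum calibrated score. All stages are deterministic
#' given the manifest, configuration and seed.
#'
#' @param manifest an `mpn_manifest` ([load_manifest()]) with `roi_paths`
#'   and `annotation_paths`, or a list of pre-loaded per-patient ROI lists
#'   named by patient id together with a `labels` vector.
#' @param config a [pipeline_config()].
#' @param seed master seed for fold assignment.
#' @param out_dir optional directory: writes `features.csv`,
#'   `cv_predictions.csv`, `nos_scores.csv`, `report.json` and a
#'   `provenance.json` (config, seed, package version).
#' @param verbose log stage progress.
#' @return list with `features`, `selection`, `cv_report`, `model`,
#'   `nos_scores` (NULL when no NOS patients), `config`, `seed`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), seed = 1,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(manifest, "mpn_manifest"))
  if (!all(c("roi_paths", "annotation_paths") %in% names(manifest)))
    stop("run_pipeline(): manifest lacks roi_paths/annotation_paths")

  feats <- lapply(seq_len(nrow(manifest)), function(i) {
    if (verbose) message("featurizing ", manifest$patient_id[i])
    rois <- mapply(read_roi_tiff, manifest$roi_paths[[i]],
                   manifest$annotation_paths[[i]], SIMPLIFY = FALSE)
    featurize_patient(rois, config, patient_id = manifest$patient_id[i],
                      label = manifest$label[i], verbose = verbose)
  })
  features <- do.call(rbind, feats)

  labelled <- features[features$label != "NOS", ]
  if (nrow(labelled) == 0 || length(unique(labelled$label)) < 2)
    stop("run_pipeline(): stage train-eval requires a labelled multi-class cohort",
         if (any(features$label == "NOS")) " (NOS-only manifests cannot train a model)" else "")
  fcols <- feature_columns(config$features$feature_set)
  Xl <- labelled[fcols]
  yl <- factor(labelled$label, levels = intersect(MPN_CLASS_ORDER, labelled$label))

  selection <- kruskal_wallis_select(Xl, yl, alpha = config$model$alpha)
  sel <- selection$selected
  if (length(sel) == 0) sel <- fcols # degenerate screen: keep everything

  cv_report <- repeated_cv(
    Xl[sel], yl, k = config$model$k, repeats = config$model$repeats,
    seed = seed, cost = config$model$cost,
    nested_selection = config$model$nested_selection,
    alpha = config$model$alpha, gmean_sqrt = config$model$gmean_sqrt)

  std <- fit_standardizer(Xl[sel])
  model <- train_svm(apply_standardizer(std, Xl[sel]), yl,
                     cost = config$model$cost, seed = seed)

  nos_scores <- NULL
  nos <- features[features$label == "NOS", ]
  if (nrow(nos) > 0) {
    nos_scores <- predict_nos(model, apply_standardizer(std, nos[sel]),
                              patient_ids = nos$patient_id)
  }

  res <- list(features = features, selection = selection,
              cv_report = cv_report, model = model, standardizer = std,
              nos_scores = nos_scores, config = config, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(cv_report$predictions,
                     file.path(out_dir, "cv_predictions.csv"), row.names = FALSE)
    if (!is.null(nos_scores))
      utils::write.csv(nos_scores, file.path(out_dir, "nos_scores.csv"),
                       row.names = FALSE)
    jsonlite::write_json(cv_report$summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = seed, package = "mpnmorph",
           version = as.character(utils::packageVersion("mpnmorph")),
           config = unclass_config(config)),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$detection <- unclass(cfg$detection)
  cfg
}
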