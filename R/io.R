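# Cohort manifests, image and annotation IO.

MANIFEST_LABELS <- c("pre-PMF", "PV", "ET", "NOS")

#' Load and validate a cohort manifest
#'
#' CSV with columns `patient_id`, `label` (pre-PMF / PV / ET / NOS),
#' optional `roi_paths` and `annotation_paths` (`;`-separated), optional
#' `pathologist_cellularity` (a number, or a range `"0.4-0.6"` which is
#' resolved to its upper bound, the convention used when comparing against
#' pathologist estimates) and optional `true_cellularity`.
#'
#' @param path CSV path.
#' @param check_paths verify that every referenced file exists.
#' @return a validated tibble of class `mpn_manifest`; `roi_paths` and
#'   `annotation_paths` become list-columns, and
#'   `pathologist_cellularity_is_range` records which entries were ranges.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("load_manifest(): no such file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("load_manifest(): unreadable manifest: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("load_manifest(): manifest is empty")
  req <- c("patient_id", "label")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("load_manifest(): missing column(s): ",
                         paste(miss, collapse = ", "))
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup)) stop("load_manifest(): duplicate patient_id: ",
                        paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$label), MANIFEST_LABELS)
  if (length(bad)) stop("load_manifest(): unknown label(s): ",
                        paste(bad, collapse = ", "))
  out <- tibble::as_tibble(df)
  for (col in c("roi_paths", "annotation_paths")) {
    if (col %in% names(out)) {
      lst <- strsplit(as.character(out[[col]]), ";", fixed = TRUE)
      lst <- lapply(lst, trimws)
      if (check_paths) {
        base <- dirname(normalizePath(path))
        lst <- lapply(lst, function(p)
          ifelse(file.exists(p), p, file.path(base, p)))
        missing <- unlist(lst)[!file.exists(unlist(lst))]
        if (length(missing)) stop("load_manifest(): missing file(s): ",
                                  paste(missing, collapse = ", "))
      }
      out[[col]] <- lst
    }
  }
  if ("pathologist_cellularity" %in% names(out)) {
    raw <- as.character(out$pathologist_cellularity)
    is_range <- grepl("^\\s*[0-9.]+\\s*-\\s*[0-9.]+\\s*$", raw)
    val <- suppressWarnings(as.numeric(raw))
    val[is_range] <- vapply(raw[is_range], function(r)
      max(as.numeric(strsplit(r, "-", fixed = TRUE)[[1]])), numeric(1))
    bad <- !is.na(raw) & raw != "" & is.na(val)
    if (any(bad)) stop("load_manifest(): unparseable cellularity: ",
                       paste(raw[bad], collapse = ", "))
    out$pathologist_cellularity <- val
    out$pathologist_cellularity_is_range <- is_range
  }
  class(out) <- c("mpn_manifest", class(out))
  out
}

#' Write / read an ROI image as TIFF
#'
#' Grayscale 8-bit TIFF; RGB inputs are collapsed to luminance on read.
#'
#' @param roi a `roi_image` (or `synthetic_roi`).
#' @param path output path.
#' @export
write_roi_tiff <- function(roi, path) {
  tiff::writeTIFF(t(roi$pixels) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_roi_tiff
#' @param annotation_path GeoJSON annotation file written by
#'   [write_annotations_geojson()].
#' @param pixel_size_um pixel size; overrides the annotation sidecar.
#' @export
read_roi_tiff <- function(path, annotation_path = NULL, pixel_size_um = NULL) {
  a <- tiff::readTIFF(path)
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  px <- t(a) * 255
  tissue <- NULL; background <- NULL
  if (!is.null(annotation_path)) {
    ann <- read_annotations_geojson(annotation_path)
    tissue <- ann$tissue; background <- ann$background
    if (is.null(pixel_size_um)) pixel_size_um <- ann$pixel_size_um
  }
  stopifnot(!is.null(pixel_size_um))
  roi_image(px, pixel_size_um, tissue_polygon = tissue,
            background_polygon = background)
}

#' Write / read tissue and background annotations as GeoJSON
#'
#' A `FeatureCollection` with one polygon per annotation class
#' (`Tissue Boundaries`, `Background`), coordinates in pixel units, with
#' the pixel size stored as a foreign member.
#'
#' @param roi a `roi_image`.
#' @param path GeoJSON path.
#' @export
write_annotations_geojson <- function(roi, path) {
  poly_feature <- function(poly, cls) {
    coords <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(classification = cls),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(coords)),
                                                   function(i) as.numeric(coords[i, ])))))
  }
  fc <- list(type = "FeatureCollection",
             pixel_size_um = roi$pixel_size_um,
             features = list(
               poly_feature(roi$tissue_polygon, "Tissue Boundaries"),
               poly_feature(roi$background_polygon, "Background")))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations_geojson
#' @export
read_annotations_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  out <- list(tissue = NULL, background = NULL,
              pixel_size_um = fc$pixel_size_um)
  for (ft in fc$features) {
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    m <- m[-nrow(m), , drop = FALSE] # drop closing vertex
    colnames(m) <- c("x", "y")
    cls <- ft$properties$classification
    if (identical(cls, "Tissue Boundaries")) out$tissue <- m
    if (identical(cls, "Background")) out$background <- m
  }
  out
}

#' Simulate a cohort to disk
#'
#' Generates `n_per_class` patients per profile (plus optional NOS-like
#' mixtures), writes each ROI as TIFF + GeoJSON annotations, and a
#' manifest CSV (`patient_id`, `label`, `roi_paths`, `annotation_paths`,
#' `true_cellularity` = mask-level mean over the ROIs).
#'
#' @param out_dir output directory (created).
#' @param profiles list of [class_profile()]s; default
#'   [make_default_profiles()].
#' @param n_per_class patients per profile (recycled).
#' @param n_nos number of NOS patients simulated as 0.5 mixtures of two
#'   randomly chosen profiles.
#' @param n_rois ROIs per patient.
#' @param seed master seed.
#' @param ... passed to [generate_patient_rois()].
#' @return the manifest tibble (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
simulate_cohort <- function(out_dir, profiles = make_default_profiles(),
                            n_per_class = 5, n_nos = 0, n_rois = 3, seed = 1,
                            ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_per_class <- rep_len(n_per_class, length(profiles))
  rows <- list()
  pid <- 0L
  emit <- function(label, rois) {
    pid <<- pid + 1L
    id <- sprintf("SYN%03d", pid)
    ipaths <- character(length(rois)); apaths <- character(length(rois))
    for (j in seq_along(rois)) {
      ipaths[j] <- file.path(out_dir, sprintf("%s_roi%d.tif", id, j))
      apaths[j] <- file.path(out_dir, sprintf("%s_roi%d.geojson", id, j))
      write_roi_tiff(rois[[j]], ipaths[j])
      write_annotations_geojson(rois[[j]], apaths[j])
    }
    rows[[length(rows) + 1]] <<- data.frame(
      patient_id = id, label = label,
      roi_paths = paste(ipaths, collapse = ";"),
      annotation_paths = paste(apaths, collapse = ";"),
      true_cellularity = mean(vapply(rois, `[[`, numeric(1), "true_cellularity")))
  }
  for (ci in seq_along(profiles)) {
    for (i in seq_len(n_per_class[ci])) {
      rois <- generate_patient_rois(profiles[[ci]], n_rois = n_rois,
                                    seed = seed + 1000L * ci + i, ...)
      emit(profiles[[ci]]$label, rois)
    }
  }
  if (n_nos > 0) {
    set.seed(seed + 777L)
    pairs <- replicate(n_nos, sample(length(profiles), 2), simplify = FALSE)
    for (i in seq_len(n_nos)) {
      rois <- generate_nos_patient(profiles[[pairs[[i]][1]]],
                                   profiles[[pairs[[i]][2]]], mix = 0.5,
                                   seed = seed + 9000L + i, n_rois = n_rois, ...)
      emit("NOS", rois)
    }
  }
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  load_manifest(file.path(out_dir, "manifest.csv"))
}
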