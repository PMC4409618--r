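#' Centroid of a mask in mm coordinates
#'
#' Used to derive A50% seed points from lesion masks when no manual seed is
#' given.
#'
#' @param mask logical 3D mask, nonempty
#' @param spacing voxel spacing, mm
#' @return numeric length-3 point, mm
#' @export
mask_centroid_mm <- function(mask, spacing) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  ijk <- arrayInd(which(mask != 0), dim(mask))
  colMeans(sweep(ijk - 0.5, 2, spacing, "*"))
}

segment_scan <- function(image, kcs_by_source, lesion_masks, kf_preset,
                         a50 = a50_params(), seeds_mm = NULL, leak_rim = 2L,
                         scan = "test") {
  late <- mean_last_frames_image(image)
  kf <- run_kf_preset(image, kcs_by_source, lesion_masks, kf_preset)
  stats <- purrr::imap_dfr(lesion_masks, function(mask, id) {
    seed <- if (!is.null(seeds_mm) && id %in% names(seeds_mm)) {
      seeds_mm[[id]]
    } else {
      mask_centroid_mm(mask, image$spacing)
    }
    bound <- dilate_mask(as_mask(mask, dim(image$data)[1:3]), leak_rim)
    a50_res <- a50_segment(late, seed, image$spacing, a50, bound_mask = bound)
    dplyr::bind_rows(
      lesion_stats(kf$results[[id]], late, image$spacing, image$dose_MBq,
                   image$weight_kg, id, scan),
      lesion_stats(a50_res, late, image$spacing, image$dose_MBq,
                   image$weight_kg, id, scan)
    )
  })
  list(stats = stats, kf = kf)
}

#' Run the full test-retest segmentation pipeline
#'
#' Applies a kinetic-filtering variant and the A50% method to a test and a
#' retest dynamic scan (per lesion mask; A50% seeds default to the mask
#' centroids), gathers per-lesion volume and SUV statistics on the late-frame
#' mean image, and computes the test-retest comparison. Optionally writes
#' per-lesion CSVs, the TRT summary, KF label images and a machine-readable
#' run log to `out_dir`.
#'
#' @param test,retest `dynamic_image`s with dose and weight, on one grid
#' @param lesion_masks named list of logical 3D lesion masks
#' @param kcs_by_source named list of `kinetic_class_set`s (or a single set)
#' @param kf_preset preset name or `kf_config` (default `"KF1"`)
#' @param a50 an `a50_params`
#' @param seeds_mm optional named list of A50% seed points (mm) per lesion
#' @param leak_rim voxels of dilation of the lesion mask used as the A50% leak
#'   bounding region
#' @param out_dir optional output directory
#' @return list: `stats` (per-lesion, per-scan, per-method tibble),
#'   `comparison` (a `trt_comparison`), `kf_test`/`kf_retest` (KF run
#'   outputs), `log` (run configuration list)
#' @export
run_trt_pipeline <- function(test, retest, lesion_masks, kcs_by_source,
                             kf_preset = "KF1", a50 = a50_params(),
                             seeds_mm = NULL, leak_rim = 2L, out_dir = NULL) {
  for (img in list(test, retest)) {
    if (is.na(img$dose_MBq) || is.na(img$weight_kg)) {
      stop("test and retest images must carry dose_MBq and weight_kg",
           call. = FALSE)
    }
  }
  if (!all(dim(test$data)[1:3] == dim(retest$data)[1:3])) {
    stop("test and retest grids differ", call. = FALSE)
  }
  st <- segment_scan(test, kcs_by_source, lesion_masks, kf_preset, a50,
                     seeds_mm, leak_rim, scan = "test")
  sr <- segment_scan(retest, kcs_by_source, lesion_masks, kf_preset, a50,
                     seeds_mm, leak_rim, scan = "retest")
  stats <- dplyr::bind_rows(st$stats, sr$stats)
  comparison <- compare_methods(stats)
  cfg <- st$kf$config
  log <- list(
    kf_preset = cfg$name, kc_source = cfg$kc_source,
    sigma_scale = cfg$sigma_scale, time_window = cfg$time_window,
    temporal_smoothing = cfg$temporal_smoothing,
    resample_direction = cfg$resample_direction,
    min_detect_voxels = cfg$min_detect_voxels,
    a50 = unclass(a50), leak_rim = leak_rim,
    n_lesions = length(lesion_masks),
    package_version = as.character(utils::packageVersion("dynpetseg"))
  )
  out <- list(stats = stats, comparison = comparison, kf_test = st$kf,
              kf_retest = sr$kf, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(stats, file.path(out_dir, "lesion_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$trt, file.path(out_dir, "trt_lesions.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$summary, file.path(out_dir, "trt_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$detection, file.path(out_dir, "detection.csv"),
                     row.names = FALSE)
    write_label_image(st$kf$labels, file.path(out_dir, "kf_labels_test.nii.gz"))
    write_label_image(sr$kf$labels, file.path(out_dir, "kf_labels_retest.nii.gz"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Run the pipeline from a JSON study manifest
#'
#' The manifest names, for the test and the retest scan, the 4D image (with
#' timing sidecar), the lesion-mask label image, and dose/weight overrides;
#' plus the kinetic-class JSON file(s) and the KF preset. All file paths are
#' resolved relative to the manifest location.
#'
#' Manifest keys: `test`/`retest` (objects with `image`, optional `dose_MBq`,
#' `weight_kg`), `lesion_masks` (label-image path), `kinetic_classes` (named
#' object source -> path, or a single path), `kf_preset`.
#'
#' @param manifest path to a manifest JSON file, or an equivalent list
#' @param out_dir output directory
#' @param ... further arguments to [run_trt_pipeline()]
#' @return see [run_trt_pipeline()]
#' @export
run_pipeline <- function(manifest, out_dir, ...) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  for (role in c("test", "retest")) {
    if (is.null(manifest[[role]]) || is.null(manifest[[role]]$image)) {
      stop(sprintf("manifest lacks a '%s' scan image", role), call. = FALSE)
    }
  }
  load_scan <- function(entry) {
    img <- read_dynamic_image(resolve(entry$image))
    if (!is.null(entry$dose_MBq)) img$dose_MBq <- entry$dose_MBq
    if (!is.null(entry$weight_kg)) img$weight_kg <- entry$weight_kg
    if (is.na(img$dose_MBq) || img$dose_MBq <= 0) {
      stop("scan has no positive dose_MBq", call. = FALSE)
    }
    if (is.na(img$weight_kg) || img$weight_kg <= 0) {
      stop("scan has no positive weight_kg", call. = FALSE)
    }
    img
  }
  test <- load_scan(manifest$test)
  retest <- load_scan(manifest$retest)
  masks <- read_label_image(resolve(manifest$lesion_masks),
                            grid = dim(test$data)[1:3])
  kc_entry <- manifest$kinetic_classes
  kcs_by_source <- if (is.character(kc_entry) && length(kc_entry) == 1 &&
                       is.null(names(kc_entry))) {
    read_kinetic_classes(resolve(kc_entry))
  } else {
    lapply(as.list(kc_entry), function(p) read_kinetic_classes(resolve(p)))
  }
  run_trt_pipeline(test, retest, masks, kcs_by_source,
                   kf_preset = manifest$kf_preset %||% "KF1",
                   out_dir = out_dir, ...)
}
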