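#' Mahalanobis distance between a voxel TAC and a kinetic class
#'
#' The per-voxel classification statistic of kinetic filtering: the distance
#' between the voxel TAC and the class mean TAC, weighted per frame by the
#' class standard deviation,
#' `D = sqrt( sum_t ((p_t - mu_t) / (s * sigma_t))^2 )`,
#' where `s` is an optional uniform scaling of the weighting factors.
#'
#' @param p voxel TAC (same normalization and schedule as the class)
#' @param kc a `kinetic_class`
#' @param sigma_scale positive scaling factor applied to all sigma_t
#' @param frames optional integer subset of frames to use (time-window
#'   restriction); default all
#' @return non-negative scalar distance (dimensionless)
#' @export
mahalanobis_distance <- function(p, kc, sigma_scale = 1, frames = NULL) {
  stopifnot(inherits(kc, "kinetic_class"))
  if (sigma_scale <= 0) stop("sigma_scale must be positive", call. = FALSE)
  if (is.null(frames)) frames <- seq_along(kc$mu)
  if (length(p) != length(kc$mu)) {
    stop("voxel TAC and class length differ", call. = FALSE)
  }
  sig <- sigma_scale * kc$sigma[frames]
  if (any(sig == 0)) {
    stop(sprintf("class '%s' has zero SD in a frame in scope (degenerate class)",
                 kc$tissue), call. = FALSE)
  }
  sqrt(sum(((p[frames] - kc$mu[frames]) / sig)^2))
}

#' Kinetic-filtering configuration
#'
#' Bundles the knobs that define a KF variant: which kinetic-class set to use,
#' optional temporal smoothing, which way to resample schedules, a uniform
#' scaling of the SD weighting factors, an optional classification time
#' window, class-subset restrictions, and the reclassification maps.
#'
#' @param name variant name
#' @param kc_source which kinetic-class set to use (key into the set list
#'   handed to [run_kf_preset()])
#' @param temporal_smoothing smooth every frame with its neighbours before
#'   classification
#' @param resample_direction `"classes_to_scan"` (resample the classes to the
#'   scan's frame times, the original behaviour) or `"scan_to_classes"`
#'   (interpolate the scan's voxel TACs to the class frame times)
#' @param sigma_scale uniform positive scaling of all class SDs
#' @param time_window `c(t0, t1)` in minutes, or `NULL` for the full scan;
#'   frames outside the window are disregarded during classification
#' @param class_subset tissues retained for classification (`NULL` = all in
#'   the set); must include tumour
#' @param class_omit tissues removed from the retained set (convenience for
#'   "liver omitted" style variants)
#' @param reclass_global named character map applied to the whole label image
#'   after classification (original algorithm: `c(vertebrae = "tumour")`,
#'   because vertebrae and tumour kinetics are not reliably separable)
#' @param reclass_in_mask named character map applied only inside lesion masks
#'   (e.g. `c(liver = "tumour")`)
#' @param min_detect_voxels a lesion counts as detected when at least this
#'   many tumour voxels fall inside its mask (default 1)
#' @return a `kf_config`
#' @export
kf_config <- function(name = "custom",
                      kc_source = "hammersmith",
                      temporal_smoothing = FALSE,
                      resample_direction = c("classes_to_scan", "scan_to_classes"),
                      sigma_scale = 1,
                      time_window = NULL,
                      class_subset = NULL,
                      class_omit = NULL,
                      reclass_global = c(vertebrae = "tumour"),
                      reclass_in_mask = NULL,
                      min_detect_voxels = 1L) {
  resample_direction <- match.arg(resample_direction)
  if (sigma_scale <= 0) stop("sigma_scale must be positive", call. = FALSE)
  if (!is.null(time_window) &&
      (length(time_window) != 2 || time_window[1] >= time_window[2])) {
    stop("time_window must be c(t0, t1) minutes with t0 < t1", call. = FALSE)
  }
  structure(
    list(name = name, kc_source = kc_source,
         temporal_smoothing = isTRUE(temporal_smoothing),
         resample_direction = resample_direction, sigma_scale = sigma_scale,
         time_window = time_window, class_subset = class_subset,
         class_omit = class_omit, reclass_global = reclass_global,
         reclass_in_mask = reclass_in_mask,
         min_detect_voxels = as.integer(min_detect_voxels)),
    class = "kf_config"
  )
}

#' The nine published KF variants
#'
#' Named configurations KF1-KF9. KF1 is the original algorithm with the
#' Hammersmith classes (vertebrae reclassified globally as tumour); KF2 adds
#' temporal smoothing; KF3 interpolates the scan to the class frame times
#' instead of vice versa; KF4/KF5 reclassify liver as tumour inside the lesion
#' masks and restrict classification to 9-60 / 20-60 min post injection;
#' KF6/KF7 omit the liver / the liver and vertebrae classes; KF8 is the
#' original algorithm with the VUmc classes; KF9 uses the VUmc classes with
#' liver and vertebrae reclassified inside the masks, temporal smoothing, and
#' a 15-60 min window.
#'
#' @return named list of `kf_config` objects
#' @export
kf_presets <- function() {
  list(
    KF1 = kf_config("KF1"),
    KF2 = kf_config("KF2", temporal_smoothing = TRUE),
    KF3 = kf_config("KF3", resample_direction = "scan_to_classes"),
    KF4 = kf_config("KF4", reclass_in_mask = c(liver = "tumour"),
                    time_window = c(9, 60)),
    KF5 = kf_config("KF5", reclass_in_mask = c(liver = "tumour"),
                    time_window = c(20, 60)),
    KF6 = kf_config("KF6", class_omit = "liver"),
    KF7 = kf_config("KF7", class_omit = c("liver", "vertebrae")),
    KF8 = kf_config("KF8", kc_source = "vumc"),
    KF9 = kf_config("KF9", kc_source = "vumc",
                    reclass_in_mask = c(liver = "tumour", vertebrae = "tumour"),
                    temporal_smoothing = TRUE, time_window = c(15, 60))
  )
}

# Linear interpolation of the rows of a voxel-by-frame matrix onto a target
# schedule's mid-times (clamped outside the source range).
resample_tac_matrix <- function(V, from, to) {
  f <- from$mid_s
  x <- pmin(pmax(to$mid_s, f[1]), f[length(f)])
  i <- findInterval(x, f, all.inside = TRUE)
  w <- (x - f[i]) / (f[i + 1] - f[i])
  out <- matrix(0, nrow = nrow(V), ncol = length(x))
  for (t in seq_along(x)) {
    out[, t] <- (1 - w[t]) * V[, i[t]] + w[t] * V[, i[t] + 1]
  }
  out
}

retained_tissues <- function(kcs, config) {
  tissues <- names(kcs$classes)
  keep <- config$class_subset %||% tissues
  keep <- setdiff(keep, config$class_omit)
  missing <- setdiff(keep, tissues)
  if (length(missing)) {
    stop(sprintf("class subset names not in the class set: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"tumour" %in% keep) stop("class subset must include tumour", call. = FALSE)
  keep
}

#' Classify every voxel to its nearest kinetic class
#'
#' Voxel TACs are dose-normalized (the classes are stored per injected MBq),
#' schedules are aligned according to the configured resampling direction, the
#' optional time window and class subset are applied, and each voxel is
#' assigned the class with the smallest Mahalanobis distance; ties go to the
#' earlier class in the set order. Finally the configured global
#' reclassification map is applied (the original algorithm relabels vertebrae
#' as tumour).
#'
#' @param image a `dynamic_image` with a known `dose_MBq`
#' @param kcs a `kinetic_class_set`
#' @param config a `kf_config` (smoothing is NOT applied here; see
#'   [run_kf_preset()])
#' @return a `label_image`: list with `labels` (3D integer array),
#'   `label_table` (named integer vector tissue -> code) and `spacing`
#' @export
classify_voxels <- function(image, kcs, config = kf_config()) {
  stopifnot(inherits(image, "dynamic_image"), inherits(kcs, "kinetic_class_set"))
  if (is.na(image$dose_MBq) || image$dose_MBq <= 0) {
    stop("image must carry a positive dose_MBq for dose normalization",
         call. = FALSE)
  }
  V <- as_tac_matrix(image) / image$dose_MBq

  if (config$resample_direction == "classes_to_scan") {
    kcs_use <- resample_class_set(kcs, image$schedule)
    sched <- image$schedule
  } else {
    V <- resample_tac_matrix(V, image$schedule, kcs$schedule)
    kcs_use <- kcs
    sched <- kcs$schedule
  }

  frames <- if (is.null(config$time_window)) seq_len(n_frames(sched)) else
    restrict_time_window(sched, config$time_window)

  keep <- retained_tissues(kcs_use, config)
  D2 <- matrix(NA_real_, nrow = nrow(V), ncol = length(keep))
  for (j in seq_along(keep)) {
    k <- kcs_use$classes[[keep[j]]]
    sig <- config$sigma_scale * k$sigma[frames]
    if (any(sig == 0)) {
      stop(sprintf("class '%s' has zero SD in a frame in scope (degenerate class)",
                   k$tissue), call. = FALSE)
    }
    acc <- 0
    for (t in seq_along(frames)) {
      acc <- acc + ((V[, frames[t]] - k$mu[frames[t]]) / sig[t])^2
    }
    D2[, j] <- acc
  }
  lab <- max.col(-D2, ties.method = "first")

  label_table <- stats::setNames(seq_along(keep), keep)
  labels <- array(lab, grid_dim(image))
  li <- new_label_image(labels, label_table, image$spacing)
  apply_reclass(li, config$reclass_global)
}

new_label_image <- function(labels, label_table, spacing) {
  structure(list(labels = labels, label_table = label_table,
                 spacing = as.numeric(spacing)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_image> %dx%dx%d voxels; tissues: %s\n", d[1], d[2], d[3],
              paste(names(x$label_table), collapse = ", ")))
  invisible(x)
}

# Apply a named from->to tissue map to a label image, optionally only where
# `where` (logical array) is TRUE.
apply_reclass <- function(li, map, where = NULL) {
  if (is.null(map) || length(map) == 0) return(li)
  lt <- li$label_table
  for (from in names(map)) {
    to <- map[[from]]
    if (!from %in% names(lt)) next  # class absent (e.g. omitted): no-op
    if (!to %in% names(lt)) {
      stop(sprintf("reclass target '%s' not among labels", to), call. = FALSE)
    }
    sel <- li$labels == lt[[from]]
    if (!is.null(where)) sel <- sel & where
    li$labels[sel] <- lt[[to]]
  }
  li
}

#' Reclassify labels inside a lesion mask
#'
#' Applies a class-to-class map only where the lesion mask is true; voxels
#' outside the mask are untouched. Used to fold liver/vertebrae
#' misclassifications inside a drawn lesion mask back into tumour (no liver or
#' vertebrae can be inside a lung-lesion mask).
#'
#' @param labels a `label_image`
#' @param lesion_mask logical 3D mask on the same grid
#' @param map named character vector, `c(from = "to", ...)` tissue names
#' @return a `label_image`
#' @export
reclassify_within_mask <- function(labels, lesion_mask, map) {
  stopifnot(inherits(labels, "label_image"))
  mask <- as_mask(lesion_mask, dim(labels$labels))
  apply_reclass(labels, map, where = mask)
}

#' Extract the tumour segmentation of one lesion
#'
#' Applies the in-mask reclassification of the configuration, then takes the
#' tumour-labelled voxels inside the lesion mask as the lesion VOI. The lesion
#' is "detected" when the VOI holds at least `min_detect_voxels` voxels.
#'
#' @param labels a `label_image` (output of [classify_voxels()])
#' @param lesion_mask logical 3D mask
#' @param config a `kf_config`
#' @return a `segmentation_result` list: `voi` (logical array), `detected`,
#'   `n_voxels`, `volume_cm3`, `composition` (voxel counts per label inside
#'   the mask, after reclassification), `method`
#' @export
segment_lesion_kf <- function(labels, lesion_mask, config = kf_config()) {
  stopifnot(inherits(labels, "label_image"))
  mask <- as_mask(lesion_mask, dim(labels$labels))
  if (!any(mask)) stop("lesion mask is empty", call. = FALSE)
  li <- apply_reclass(labels, config$reclass_in_mask, where = mask)
  tumour_code <- li$label_table[["tumour"]]
  voi <- (li$labels == tumour_code) & mask
  inside <- li$labels[mask]
  comp <- table(factor(names(li$label_table)[inside],
                       levels = names(li$label_table)))
  structure(
    list(voi = voi, detected = sum(voi) >= config$min_detect_voxels,
         n_voxels = sum(voi),
         volume_cm3 = volume_cm3(voi, li$spacing),
         composition = comp, method = config$name),
    class = "segmentation_result"
  )
}

#' Run a full KF variant on a dynamic image
#'
#' Executes the variant pipeline: optional temporal smoothing, schedule
#' alignment per the configured direction, time-window restriction, class
#' subsetting, per-voxel nearest-class assignment, global and in-mask
#' reclassification, and per-lesion segmentation.
#'
#' @param image a `dynamic_image` with dose
#' @param kcs_by_source named list of `kinetic_class_set`s (keys matched
#'   against the preset's `kc_source`), or a single set used for any source
#' @param lesion_masks named list of logical 3D lesion masks
#' @param preset a preset name (`"KF1"`..`"KF9"`) or a `kf_config`
#' @return list with `labels` (the post-global-reclass `label_image`),
#'   `results` (named list of per-lesion `segmentation_result`s) and
#'   `lesions` (tibble: lesion_id, method, detected, n_voxels, volume_cm3)
#' @export
run_kf_preset <- function(image, kcs_by_source, lesion_masks, preset = "KF1") {
  config <- if (inherits(preset, "kf_config")) preset else {
    presets <- kf_presets()
    if (!preset %in% names(presets)) {
      stop(sprintf("unknown KF preset '%s'", preset), call. = FALSE)
    }
    presets[[preset]]
  }
  kcs <- if (inherits(kcs_by_source, "kinetic_class_set")) kcs_by_source else {
    if (!config$kc_source %in% names(kcs_by_source)) {
      stop(sprintf("kinetic-class source '%s' not available", config$kc_source),
           call. = FALSE)
    }
    kcs_by_source[[config$kc_source]]
  }
  if (config$temporal_smoothing) image <- temporal_smooth(image)
  labels <- classify_voxels(image, kcs, config)
  results <- lapply(lesion_masks, segment_lesion_kf, labels = labels,
                    config = config)
  lesions <- purrr::imap_dfr(results, function(r, id) {
    tibble::tibble(lesion_id = id, method = config$name, detected = r$detected,
                   n_voxels = r$n_voxels, volume_cm3 = r$volume_cm3)
  })
  list(labels = labels, results = results, lesions = lesions, config = config)
}
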