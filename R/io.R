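#' Write a dynamic image as 4D NIfTI with a JSON timing sidecar
#'
#' The frame schedule (and dose/weight, when known) goes to a JSON sidecar
#' next to the image (keys `starts_s`, `durations_s`, `dose_MBq`,
#' `weight_kg`), since NIfTI timing metadata is unreliable across tools.
#'
#' @param image a `dynamic_image`
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_dynamic_image <- function(image, path) {
  stopifnot(inherits(image, "dynamic_image"))
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- c(image$spacing, 1)
  RNifti::writeNifti(nii, path)
  side <- sidecar_path(path)
  jsonlite::write_json(
    list(starts_s = image$schedule$start_s,
         durations_s = image$schedule$duration_s,
         dose_MBq = image$dose_MBq, weight_kg = image$weight_kg),
    side, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a dynamic image written with [write_dynamic_image()]
#'
#' @param path 4D NIfTI path; the JSON timing sidecar must sit next to it
#'   unless `schedule` is given
#' @param schedule optional `frame_schedule` overriding the sidecar
#' @return a `dynamic_image`
#' @export
read_dynamic_image <- function(path, schedule = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 3) {
    stop("file is a 3D image, not a dynamic (4D) scan", call. = FALSE)
  }
  if (length(dim(arr)) != 4) stop("expected a 4D NIfTI", call. = FALSE)
  spacing <- RNifti::pixdim(nii)[1:3]
  dose <- NA_real_; weight <- NA_real_
  if (is.null(schedule)) {
    side <- sidecar_path(path)
    if (!file.exists(side)) {
      stop(sprintf("timing sidecar '%s' not found", side), call. = FALSE)
    }
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    schedule <- new_frame_schedule(meta$starts_s, meta$durations_s)
    dose <- meta$dose_MBq %||% NA_real_
    weight <- meta$weight_kg %||% NA_real_
    dose <- if (is.null(dose) || is.na(dose)) NA_real_ else as.numeric(dose)
    weight <- if (is.null(weight) || is.na(weight)) NA_real_ else as.numeric(weight)
  }
  if (dim(arr)[4] != n_frames(schedule)) {
    stop(sprintf("image has %d frames but the schedule has %d",
                 dim(arr)[4], n_frames(schedule)), call. = FALSE)
  }
  dynamic_image(arr, spacing, schedule, dose_MBq = dose, weight_kg = weight)
}

#' Write a 3D integer label image with a JSON label table
#'
#' @param labels 3D integer array (or a `label_image`)
#' @param path output NIfTI path
#' @param spacing voxel spacing, mm (taken from a `label_image` if given)
#' @param label_table named integer vector tissue -> code
#' @return `path`, invisibly
#' @export
write_label_image <- function(labels, path, spacing = NULL, label_table = NULL) {
  if (inherits(labels, "label_image")) {
    spacing <- spacing %||% labels$spacing
    label_table <- label_table %||% labels$label_table
    labels <- labels$labels
  }
  nii <- RNifti::asNifti(array(as.integer(labels), dim(labels)))
  if (!is.null(spacing)) RNifti::pixdim(nii) <- c(spacing, 1)
  RNifti::writeNifti(nii, path, datatype = "int16")
  if (!is.null(label_table)) {
    jsonlite::write_json(as.list(label_table), sidecar_path(path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a 3D integer label image into per-tissue masks
#'
#' @param path NIfTI path with integer voxel values
#' @param label_table named integer vector tissue -> code; defaults to the
#'   JSON sidecar written by [write_label_image()]
#' @param grid optional expected grid dimensions; a mismatch is an error
#' @return named list of logical masks, one per label-table entry (absent
#'   labels give an empty mask with a warning)
#' @export
read_label_image <- function(path, label_table = NULL, grid = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3) stop("expected a 3D label image", call. = FALSE)
  if (any(arr != round(arr))) {
    stop("label image has non-integer voxel values", call. = FALSE)
  }
  if (!is.null(grid) && !all(dim(arr) == grid)) {
    stop(sprintf("label grid %s does not match expected grid %s",
                 paste(dim(arr), collapse = "x"),
                 paste(grid, collapse = "x")), call. = FALSE)
  }
  if (is.null(label_table)) {
    side <- sidecar_path(path)
    if (!file.exists(side)) {
      stop("no label table given and no JSON sidecar found", call. = FALSE)
    }
    label_table <- unlist(jsonlite::read_json(side, simplifyVector = TRUE))
  }
  masks <- lapply(label_table, function(code) arr == code)
  absent <- vapply(masks, function(m) !any(m), logical(1))
  if (any(absent)) {
    warning(sprintf("labels absent from image (empty masks): %s",
                    paste(names(label_table)[absent], collapse = ", ")))
  }
  masks
}

#' Write a kinetic-class set as JSON
#'
#' @param kcs a `kinetic_class_set`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_kinetic_classes <- function(kcs, path) {
  stopifnot(inherits(kcs, "kinetic_class_set"))
  jsonlite::write_json(
    list(source = kcs$source,
         schedule = list(starts_s = kcs$schedule$start_s,
                         durations_s = kcs$schedule$duration_s),
         classes = lapply(unname(kcs$classes), function(k) {
           list(tissue = k$tissue, mu = k$mu, sigma = k$sigma,
                n_scans = k$n_scans)
         })),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a kinetic-class set written with [write_kinetic_classes()]
#'
#' @param path JSON path
#' @return a `kinetic_class_set`
#' @export
read_kinetic_classes <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sched <- new_frame_schedule(j$schedule$starts_s, j$schedule$durations_s)
  classes <- lapply(seq_len(nrow(j$classes)), function(i) {
    kinetic_class(j$classes$tissue[i], j$classes$mu[[i]], j$classes$sigma[[i]],
                  sched, n_scans = j$classes$n_scans[i])
  })
  kinetic_class_set(classes, source = j$source)
}

#' Write a phantom realization to a directory
#'
#' Emits the dynamic image (`image.nii.gz` + timing sidecar), the truth labels
#' and lesion masks as integer label images, the per-tissue true TACs as CSV,
#' and the phantom parameters as JSON.
#'
#' @param phantom a `phantom_output`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dynamic_image(phantom$image, file.path(dir, "image.nii.gz"))
  write_label_image(phantom$labels, file.path(dir, "labels.nii.gz"),
                    spacing = phantom$image$spacing,
                    label_table = phantom$label_table)
  lesion_ids <- names(phantom$lesion_masks)
  mask_labels <- array(0L, dim(phantom$labels))
  for (i in seq_along(lesion_ids)) mask_labels[phantom$lesion_masks[[i]]] <- i
  write_label_image(mask_labels, file.path(dir, "lesion_masks.nii.gz"),
                    spacing = phantom$image$spacing,
                    label_table = stats::setNames(seq_along(lesion_ids), lesion_ids))
  utils::write.csv(phantom$true_tacs, file.path(dir, "true_tacs.csv"),
                   row.names = FALSE)
  spec <- phantom$spec
  jsonlite::write_json(
    list(grid = spec$grid, spacing_mm = spec$spacing_mm,
         noise_level = spec$noise_level, dose_MBq = spec$dose_MBq,
         weight_kg = spec$weight_kg, seed = spec$seed,
         rim_voxels = spec$rim_voxels),
    file.path(dir, "phantom_spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
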