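#' Construct a dynamic (4D) PET image
#'
#' Container for a dynamic PET scan: a 4D array of activity concentration
#' (kBq/mL) indexed `[x, y, z, frame]`, the voxel spacing in mm, the frame
#' schedule, and optionally the injected dose (MBq) and body weight (kg) of
#' the scan.
#'
#' @param data 4D numeric array `[x, y, z, frame]`
#' @param spacing voxel spacing in mm, length 3, all positive
#' @param schedule a `frame_schedule` with `dim(data)[4]` frames
#' @param dose_MBq injected dose in MBq (optional, needed for dose
#'   normalization and SUV)
#' @param weight_kg body weight in kg (optional, needed for SUV)
#' @return a `dynamic_image` object
#' @export
dynamic_image <- function(data, spacing, schedule, dose_MBq = NA_real_,
                          weight_kg = NA_real_) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  }
  assert_schedule(schedule)
  if (dim(data)[4] != n_frames(schedule)) {
    stop(sprintf("image has %d frames but schedule has %d",
                 dim(data)[4], n_frames(schedule)), call. = FALSE)
  }
  structure(
    list(data = data, spacing = as.numeric(spacing), schedule = schedule,
         dose_MBq = dose_MBq, weight_kg = weight_kg),
    class = "dynamic_image"
  )
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_image> %dx%dx%d voxels x %d frames, spacing %s mm, %.1f min scan\n",
    d[1], d[2], d[3], d[4], paste(x$spacing, collapse = "x"),
    total_duration_s(x$schedule) / 60
  ))
  if (!is.na(x$dose_MBq)) cat(sprintf("  dose %.0f MBq", x$dose_MBq))
  if (!is.na(x$weight_kg)) cat(sprintf(", weight %.0f kg", x$weight_kg))
  if (!is.na(x$dose_MBq) || !is.na(x$weight_kg)) cat("\n")
  invisible(x)
}

#' @export
dim.dynamic_image <- function(x) dim(x$data)

grid_dim <- function(image) dim(image$data)[1:3]

#' Flatten a dynamic image to a voxel-by-frame matrix
#'
#' @param image a `dynamic_image`
#' @return numeric matrix, one row per voxel (column-major voxel order), one
#'   column per frame
#' @export
as_tac_matrix <- function(image) {
  d <- dim(image$data)
  matrix(image$data, nrow = prod(d[1:3]), ncol = d[4])
}

#' Duration-weighted mean of the last n frames
#'
#' Collapses a dynamic image into a single late-uptake 3D image, e.g. the
#' 45-60 min post-injection mean used as input for A50% segmentation, SUV
#' statistics, and manual VOI definition. Frames are weighted by their
#' duration, which reduces to the plain mean when the late frames are equal
#' length.
#'
#' @param image a `dynamic_image`
#' @param n number of trailing frames to average (default 3)
#' @return 3D numeric array on the image grid
#' @export
mean_last_frames_image <- function(image, n = 3) {
  stopifnot(inherits(image, "dynamic_image"))
  N <- n_frames(image$schedule)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (n > N) stop(sprintf("n = %d exceeds frame count %d", n, N), call. = FALSE)
  idx <- (N - n + 1):N
  w <- image$schedule$duration_s[idx]
  w <- w / sum(w)
  d <- dim(image$data)
  out <- array(0, d[1:3])
  for (k in seq_along(idx)) {
    out <- out + w[k] * array(image$data[, , , idx[k]], d[1:3])
  }
  out
}

#' Mean time-activity curve over a volume of interest
#'
#' @param image a `dynamic_image`
#' @param voi logical (or 0/1) 3D mask on the image grid
#' @return numeric vector of per-frame spatial means, length `n_frames`
#' @export
extract_tac <- function(image, voi) {
  stopifnot(inherits(image, "dynamic_image"))
  voi <- as_mask(voi, grid_dim(image))
  if (!any(voi)) stop("VOI is empty", call. = FALSE)
  m <- as_tac_matrix(image)
  colMeans(m[as.vector(voi), , drop = FALSE])
}

#' Temporal smoothing of a dynamic image
#'
#' Averages every frame with its previous and next frames (unweighted 3-point
#' moving mean along time). The first and last frames average the two existing
#' frames. Used by kinetic-filtering variants to suppress frame noise before
#' classification; the frame count is unchanged.
#'
#' @param image a `dynamic_image`
#' @return a smoothed `dynamic_image` on the same grid and schedule
#' @export
temporal_smooth <- function(image) {
  stopifnot(inherits(image, "dynamic_image"))
  N <- n_frames(image$schedule)
  if (N == 1) return(image)
  d <- dim(image$data)
  sm <- array(0, d)
  for (t in seq_len(N)) {
    nb <- intersect(c(t - 1, t, t + 1), seq_len(N))
    acc <- array(0, d[1:3])
    for (j in nb) acc <- acc + array(image$data[, , , j], d[1:3])
    sm[, , , t] <- acc / length(nb)
  }
  out <- image
  out$data <- sm
  out
}

# Coerce a mask-like object (logical/numeric array) to logical, checking grid.
as_mask <- function(mask, dims) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3) {
    stop("mask must be a 3D array", call. = FALSE)
  }
  if (!all(dim(mask) == dims)) {
    stop(sprintf("mask grid %s does not match image grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(dims, collapse = "x")), call. = FALSE)
  }
  array(as.logical(mask != 0), dim(mask))
}
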