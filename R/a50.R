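#' Parameters of the background-adapted 50% isocontour method
#'
#' @param initial_fraction fraction of the maximum defining the initial
#'   isocontour used to locate the lesion boundary (default 0.70)
#' @param threshold_fraction final threshold as a fraction of
#'   (maximum + local background) (default 0.50)
#' @param shell_distance_mm distance from the initial-isocontour boundary to
#'   the background shell (default 15 mm)
#' @param search_radius_mm radius of the sphere around the user seed searched
#'   for the maximum voxel (default 20 mm)
#' @param connectivity voxel connectivity for region growing, 6 or 26
#'   (default 26)
#' @return an `a50_params` list
#' @export
a50_params <- function(initial_fraction = 0.70, threshold_fraction = 0.50,
                       shell_distance_mm = 15, search_radius_mm = 20,
                       connectivity = 26) {
  if (initial_fraction <= 0 || initial_fraction >= 1 ||
      threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("isocontour fractions must be in (0, 1)", call. = FALSE)
  }
  if (shell_distance_mm <= 0) stop("shell distance must be positive", call. = FALSE)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26", call. = FALSE)
  structure(list(initial_fraction = initial_fraction,
                 threshold_fraction = threshold_fraction,
                 shell_distance_mm = shell_distance_mm,
                 search_radius_mm = search_radius_mm,
                 connectivity = connectivity),
            class = "a50_params")
}

voxel_centres_mm <- function(dims, spacing) {
  list(x = (seq_len(dims[1]) - 0.5) * spacing[1],
       y = (seq_len(dims[2]) - 0.5) * spacing[2],
       z = (seq_len(dims[3]) - 0.5) * spacing[3])
}

#' Locate the hottest voxel near a seed point
#'
#' Searches the sphere of `search_radius_mm` around a user-indicated seed (mm
#' coordinates; the centre of voxel `(i,j,k)` is at `(i-0.5)*spacing` etc.)
#' for the voxel with the highest value. Ties go to the lowest linear index.
#'
#' @param image3d 3D numeric array
#' @param seed_mm seed point in mm, length 3, inside the grid
#' @param search_radius_mm search sphere radius, mm
#' @param spacing voxel spacing, mm
#' @return integer voxel index, length 3 (1-based)
#' @export
find_max_voxel <- function(image3d, seed_mm, search_radius_mm, spacing) {
  d <- dim(image3d)
  stopifnot(length(d) == 3, length(seed_mm) == 3)
  extent <- d * spacing
  if (any(seed_mm < 0) || any(seed_mm > extent)) {
    stop("seed point is outside the image grid", call. = FALSE)
  }
  cc <- voxel_centres_mm(d, spacing)
  dist2 <- outer(outer((cc$x - seed_mm[1])^2, (cc$y - seed_mm[2])^2, "+"),
                 (cc$z - seed_mm[3])^2, "+")
  cand <- which(dist2 <= search_radius_mm^2)
  if (length(cand) == 0) {
    stop("search radius covers no voxels", call. = FALSE)
  }
  best <- cand[which.max(image3d[cand])]  # which.max: first max = lowest index
  as.integer(arrayInd(best, d))
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

#' Grow an isocontour region from a starting voxel
#'
#' Returns the connected component (6- or 26-connectivity) of the voxels with
#' value at or above the threshold that contains the starting voxel — the
#' region-growing step of the A50% method.
#'
#' @param image3d 3D numeric array
#' @param start_voxel integer voxel index, length 3
#' @param threshold inclusive lower bound on voxel value
#' @param connectivity 6 or 26 (default 26)
#' @return logical 3D mask
#' @export
grow_isocontour <- function(image3d, start_voxel, threshold, connectivity = 26) {
  d <- dim(image3d)
  stopifnot(length(d) == 3, length(start_voxel) == 3)
  if (image3d[start_voxel[1], start_voxel[2], start_voxel[3]] < threshold) {
    stop("starting voxel is below the threshold", call. = FALSE)
  }
  above <- image3d >= threshold
  visited <- array(FALSE, d)
  off <- neighbour_offsets(connectivity)
  start_lin <- start_voxel[1] + d[1] * (start_voxel[2] - 1 + d[2] * (start_voxel[3] - 1))
  visited[start_lin] <- TRUE
  frontier <- start_lin
  while (length(frontier) > 0) {
    ijk <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (r in seq_len(nrow(off))) {
      nb <- sweep(ijk, 2, off[r, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (!any(ok)) next
      lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1 + d[2] * (nb[ok, 3] - 1))
      lin <- lin[above[lin] & !visited[lin]]
      if (length(lin)) {
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    frontier <- unique(nxt)
  }
  visited
}

#' Local background from a shell around the initial isocontour
#'
#' Estimates the background uptake as the unweighted mean of a one-voxel-thick
#' shell of voxels at `shell_distance_mm` from the boundary of the initial
#' (70%-of-max) isocontour. Distances are Euclidean in mm from each outside
#' voxel centre to the nearest boundary voxel centre of the contour; the shell
#' comprises the voxels with distance in
#' `[shell_distance_mm, shell_distance_mm + mean voxel pitch)`.
#'
#' @param image3d 3D numeric array
#' @param contour70 logical mask of the initial isocontour (nonempty)
#' @param params an `a50_params`
#' @param spacing voxel spacing, mm
#' @return scalar mean background value
#' @export
local_background <- function(image3d, contour70, params, spacing) {
  d <- dim(image3d)
  contour70 <- as_mask(contour70, d)
  if (!any(contour70)) stop("initial isocontour is empty", call. = FALSE)
  pitch <- mean(spacing)
  dmin <- params$shell_distance_mm
  dmax <- dmin + pitch

  # boundary voxels of the contour: contour voxels with a face neighbour
  # outside the contour (or on the grid border)
  surf <- contour_surface(contour70)
  surf_ijk <- arrayInd(which(surf), d)
  surf_mm <- sweep(surf_ijk - 0.5, 2, spacing, "*")

  # candidates: outside-contour voxels within the expanded bounding box
  lo <- pmax(floor((apply(surf_mm, 2, min) - dmax) / spacing), 0) + 1
  hi <- pmin(ceiling((apply(surf_mm, 2, max) + dmax) / spacing), d)
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  cand_lin <- cand[, 1] + d[1] * (cand[, 2] - 1 + d[2] * (cand[, 3] - 1))
  outside <- !contour70[cand_lin]
  cand <- cand[outside, , drop = FALSE]
  cand_lin <- cand_lin[outside]
  cand_mm <- sweep(cand - 0.5, 2, spacing, "*")
  if (nrow(cand_mm) == 0) {
    stop(sprintf("background shell at %.1f mm is empty (no voxels outside the contour)",
                 dmin), call. = FALSE)
  }

  dmin2 <- numeric(nrow(cand_mm))
  s2 <- rowSums(surf_mm^2)
  chunk <- 4096L
  for (a in seq(1, nrow(cand_mm), by = chunk)) {
    b <- min(a + chunk - 1, nrow(cand_mm))
    cm <- cand_mm[a:b, , drop = FALSE]
    cross <- cm %*% t(surf_mm)                       # (b-a+1) x nsurf
    dd <- outer(rowSums(cm^2), s2, "+") - 2 * cross
    dmin2[a:b] <- apply(dd, 1, min)
  }
  shell <- cand_lin[dmin2 >= dmin^2 & dmin2 < dmax^2]
  if (length(shell) == 0) {
    stop(sprintf(paste0("background shell at %.1f mm is empty ",
                        "(lesion too close to the image border?)"), dmin),
         call. = FALSE)
  }
  mean(image3d[shell])
}

# Face-boundary voxels of a mask: mask voxels with a 6-neighbour outside the
# mask or on the grid border.
contour_surface <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (axis in 1:3) {
    n <- d[axis]
    shift <- function(by) {
      idx <- pmin(pmax(seq_len(n) + by, 1), n)
      if (axis == 1) m <- mask[idx, , , drop = FALSE]
      else if (axis == 2) m <- mask[, idx, , drop = FALSE]
      else m <- mask[, , idx, drop = FALSE]
      # border voxels count as surface: mark shifted-out positions FALSE
      if (by == 1) {
        if (axis == 1) m[n, , ] <- FALSE
        else if (axis == 2) m[, n, ] <- FALSE
        else m[, , n] <- FALSE
      } else {
        if (axis == 1) m[1, , ] <- FALSE
        else if (axis == 2) m[, 1, ] <- FALSE
        else m[, , 1] <- FALSE
      }
      m
    }
    interior <- interior & shift(1) & shift(-1)
  }
  mask & !interior
}

#' Background-adapted 50% isocontour segmentation (A50%)
#'
#' Segments a lesion on a (late-uptake) 3D image: locates the maximum voxel
#' near the seed, grows an initial isocontour at `initial_fraction * max`,
#' measures the local background on a shell 1.5 cm outside that contour, sets
#' the final threshold to `threshold_fraction * (max + background)`, and grows
#' the final VOI from the maximum voxel at that threshold. The lesion counts
#' as not detected when the threshold does not exceed the background (no
#' contrast) or when the VOI escapes the optional bounding region (leak).
#'
#' @param image3d 3D numeric array (e.g. [mean_last_frames_image()] output)
#' @param seed_mm seed point in mm
#' @param spacing voxel spacing, mm
#' @param params an `a50_params`
#' @param bound_mask optional logical mask; a VOI voxel outside it flags a
#'   leak and the lesion counts as not detected
#' @return a `segmentation_result` list: `voi`, `detected`, `max_value`,
#'   `background`, `threshold`, `n_voxels`, `volume_cm3`, `leak`,
#'   `max_voxel`, `method = "A50"`
#' @export
a50_segment <- function(image3d, seed_mm, spacing, params = a50_params(),
                        bound_mask = NULL) {
  stopifnot(inherits(params, "a50_params"))
  mv <- find_max_voxel(image3d, seed_mm, params$search_radius_mm, spacing)
  max_value <- image3d[mv[1], mv[2], mv[3]]
  contour70 <- grow_isocontour(image3d, mv, params$initial_fraction * max_value,
                               params$connectivity)
  background <- if (all(contour70)) {
    # the initial isocontour floods the whole grid (no contrast anywhere):
    # no background shell exists outside it; treat background as the maximum
    # so the lesion is flagged undetected below
    max_value
  } else {
    local_background(image3d, contour70, params, spacing)
  }
  threshold <- params$threshold_fraction * (max_value + background)
  detected <- threshold > background
  voi <- if (threshold > max_value) {
    array(FALSE, dim(image3d))  # threshold above every voxel: empty VOI
  } else {
    grow_isocontour(image3d, mv, threshold, params$connectivity)
  }
  if (!any(voi)) detected <- FALSE
  leak <- FALSE
  if (!is.null(bound_mask)) {
    leak <- any(voi & !as_mask(bound_mask, dim(image3d)))
    if (leak) detected <- FALSE
  }
  structure(
    list(voi = voi, detected = detected, max_value = max_value,
         background = background, threshold = threshold,
         n_voxels = sum(voi), volume_cm3 = volume_cm3(voi, spacing),
         leak = leak, max_voxel = mv, method = "A50"),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %s, %d voxels (%.2f cm3)\n",
              x$method, if (x$detected) "detected" else "not detected",
              x$n_voxels, x$volume_cm3))
  invisible(x)
}
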