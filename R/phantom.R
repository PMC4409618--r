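#' Parametric tissue time-activity model
#'
#' Analytic TAC families reproducing the qualitative kinetics of the main
#' thoracic tissues seen in dynamic FLT-PET:
#' \describe{
#'   \item{`flat`}{constant low uptake (lung background, soft tissue).}
#'   \item{`vascular`}{early bolus peak relaxing to a plateau (heart /
#'     blood pool): `plateau + (amplitude - plateau) * (t/tp) * exp(1 - t/tp)`,
#'     peaking at `peak_time_min`.}
#'   \item{`accumulating`}{monotone irreversible trapping (tumour, vertebral
#'     bone marrow): Hill-type `amplitude * t^h / (t50^h + t^h)`.}
#'   \item{`liver`}{reversible peak-then-decline (hepatic metabolism):
#'     scaled biexponential `exp(-washout*t) - exp(-uptake*t)`, normalised so
#'     the peak equals `amplitude`.}
#' }
#' Amplitudes are activity concentrations in kBq/mL; times in minutes.
#'
#' @param name tissue label (e.g. "lung", "tumour", "liver")
#' @param shape one of `"flat"`, `"vascular"`, `"accumulating"`, `"liver"`
#' @param amplitude activity-concentration scale, kBq/mL, >= 0
#' @param uptake_rate uptake rate constant, 1/min (liver rise; Hill half-time
#'   is `1/uptake_rate` min for accumulating tissues)
#' @param peak_time_min time of peak, minutes (vascular and liver shapes)
#' @param washout_rate washout rate constant, 1/min (vascular plateau decay,
#'   liver decline)
#' @param plateau late plateau level, kBq/mL (vascular shape)
#' @param hill Hill exponent for accumulating tissues (default 1.2)
#' @return a `tissue_model` object
#' @export
tissue_model <- function(name, shape, amplitude,
                         uptake_rate = 0.2, peak_time_min = 1,
                         washout_rate = 0.05, plateau = amplitude / 4,
                         hill = 1.2) {
  shape <- match.arg(shape, c("flat", "vascular", "accumulating", "liver"))
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(
    list(name = name, shape = shape, amplitude = amplitude,
         uptake_rate = uptake_rate, peak_time_min = peak_time_min,
         washout_rate = washout_rate, plateau = plateau, hill = hill),
    class = "tissue_model"
  )
}

#' Evaluate a tissue model on a frame schedule
#'
#' The TAC value of each frame is the model curve evaluated at the frame
#' mid-time (point evaluation, not the integral over the frame).
#'
#' @param model a `tissue_model`
#' @param schedule a `frame_schedule`
#' @return numeric vector of activity concentrations (kBq/mL), length
#'   `n_frames(schedule)`
#' @export
evaluate_tissue_tac <- function(model, schedule) {
  stopifnot(inherits(model, "tissue_model"))
  assert_schedule(schedule)
  t_min <- schedule$mid_s / 60
  switch(model$shape,
    flat = rep(model$amplitude, length(t_min)),
    vascular = {
      tp <- model$peak_time_min
      model$plateau + (model$amplitude - model$plateau) * (t_min / tp) * exp(1 - t_min / tp)
    },
    accumulating = {
      t50 <- 1 / model$uptake_rate
      h <- model$hill
      model$amplitude * t_min^h / (t50^h + t_min^h)
    },
    liver = {
      kw <- model$washout_rate
      ku <- model$uptake_rate
      stopifnot(ku > kw)
      tpk <- log(ku / kw) / (ku - kw)
      peak <- exp(-kw * tpk) - exp(-ku * tpk)
      model$amplitude * (exp(-kw * t_min) - exp(-ku * t_min)) / peak
    }
  )
}

#' Default thoracic tissue models
#'
#' One model per tissue compartment of the digital phantom, with amplitudes
#' chosen to give realistic late-time FLT SUVs (roughly 0.1 lung, 0.2 soft
#' tissue, 0.5 heart plateau, 2 vertebrae, 2.9 tumour, liver peaking near 3)
#' at a 364 MBq dose in a 75 kg subject.
#'
#' @return named list of `tissue_model` objects, in the fixed tissue order
#'   lung, soft_tissue, heart, liver, vertebrae, tumour
#' @export
default_tissue_models <- function() {
  list(
    lung = tissue_model("lung", "flat", amplitude = 0.5),
    soft_tissue = tissue_model("soft_tissue", "flat", amplitude = 1.0),
    heart = tissue_model("heart", "vascular", amplitude = 12,
                         peak_time_min = 0.75, plateau = 2.5),
    liver = tissue_model("liver", "liver", amplitude = 15,
                         uptake_rate = 0.5, washout_rate = 0.015),
    vertebrae = tissue_model("vertebrae", "accumulating", amplitude = 13,
                             uptake_rate = 1 / 10, hill = 1.2),
    tumour = tissue_model("tumour", "accumulating", amplitude = 18,
                          uptake_rate = 1 / 8, hill = 1.2)
  )
}

#' Geometric primitive for phantom tissue placement
#'
#' @param tissue tissue name (must match a tissue model)
#' @param type `"sphere"`, `"box"` or `"ellipsoid"`
#' @param centre_mm centre in mm (3 values, physical coordinates; the centre
#'   of voxel `(i, j, k)` is `(i - 0.5) * spacing` etc.)
#' @param size_mm radius (sphere), half-widths (box) or semi-axes (ellipsoid),
#'   mm
#' @param id optional lesion id (tumour geometries only)
#' @return a `phantom_shape` list
#' @export
phantom_shape <- function(tissue, type, centre_mm, size_mm, id = NULL) {
  type <- match.arg(type, c("sphere", "box", "ellipsoid"))
  if (type == "sphere") size_mm <- rep(size_mm[1], 3)
  stopifnot(length(centre_mm) == 3, length(size_mm) == 3, all(size_mm > 0))
  structure(list(tissue = tissue, type = type, centre_mm = as.numeric(centre_mm),
                 size_mm = as.numeric(size_mm), id = id),
            class = "phantom_shape")
}

shape_mask <- function(shape, grid, spacing) {
  ax <- lapply(1:3, function(a) (seq_len(grid[a]) - 0.5) * spacing[a])
  # normalized per-axis offsets, broadcast over the grid
  u1 <- (ax[[1]] - shape$centre_mm[1]) / shape$size_mm[1]
  u2 <- (ax[[2]] - shape$centre_mm[2]) / shape$size_mm[2]
  u3 <- (ax[[3]] - shape$centre_mm[3]) / shape$size_mm[3]
  if (shape$type == "box") {
    m <- outer(outer(abs(u1) <= 1, abs(u2) <= 1, "&"), abs(u3) <= 1, "&")
  } else {
    q <- outer(outer(u1^2, u2^2, "+"), u3^2, "+")
    m <- q <= 1
  }
  m
}

#' Phantom specification
#'
#' Describes a synthetic dynamic PET scan: grid, voxel spacing, tissue
#' geometry, lesions, acquisition schedule, noise level, dose and weight.
#' Every voxel not covered by an explicit geometry is lung background.
#'
#' @param grid voxel counts per axis (length 3)
#' @param spacing_mm voxel spacing per axis, mm
#' @param schedule a `frame_schedule`
#' @param tissues named list of `tissue_model`s (must include `lung` and
#'   `tumour`)
#' @param organs list of `phantom_shape`s for non-tumour tissues
#' @param lesions list of `phantom_shape`s with `tissue = "tumour"` and ids
#' @param noise_level coefficient of the frame-noise model: per-voxel noise is
#'   zero-mean Gaussian with SD
#'   `noise_level * sqrt(tissue amplitude) / sqrt(frame duration in min)`
#' @param dose_MBq injected dose, MBq
#' @param weight_kg body weight, kg
#' @param seed RNG seed for the noise realization
#' @param rim_voxels lesion-mask rim: each lesion mask is the true lesion
#'   dilated by this many voxels (26-neighbourhood), emulating a manually
#'   drawn mask of "tumour plus a rim of surrounding soft tissue"
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(grid, spacing_mm, schedule,
                         tissues = default_tissue_models(),
                         organs = list(), lesions = list(),
                         noise_level = 1.0, dose_MBq = 364, weight_kg = 75,
                         seed = 1L, rim_voxels = 2L) {
  stopifnot(length(grid) == 3, all(grid >= 1),
            length(spacing_mm) == 3, all(spacing_mm > 0))
  if (dose_MBq <= 0) stop("dose must be positive", call. = FALSE)
  if (noise_level < 0) stop("noise level must be >= 0", call. = FALSE)
  assert_schedule(schedule)
  stopifnot(all(c("lung", "tumour") %in% names(tissues)))
  structure(
    list(grid = as.integer(grid), spacing_mm = as.numeric(spacing_mm),
         schedule = schedule, tissues = tissues, organs = organs,
         lesions = lesions, noise_level = noise_level, dose_MBq = dose_MBq,
         weight_kg = weight_kg, seed = as.integer(seed),
         rim_voxels = as.integer(rim_voxels)),
    class = "phantom_spec"
  )
}

#' Default phantom specification
#'
#' A 40x40x20 grid at 4 mm isotropic spacing (16x16x8 cm field of view)
#' holding a soft-tissue chest-wall slab, a heart sphere, a liver box, a
#' vertebral column, and two spherical lung lesions of 12 and 8 mm radius.
#' Acquisition follows the 39-frame 60-min test-retest schedule by default.
#'
#' @param schedule a `frame_schedule` (default `builtin_schedules()$vumc_trt_39`)
#' @param noise_level frame-noise coefficient (default 1.0)
#' @param seed RNG seed
#' @param lesion_radii_mm radii of the spherical lung lesions, mm
#' @return a `phantom_spec`
#' @export
default_phantom_spec <- function(schedule = builtin_schedules()$vumc_trt_39,
                                 noise_level = 1.0, seed = 1L,
                                 lesion_radii_mm = c(12, 8)) {
  centres <- list(c(44, 48, 40), c(116, 44, 44))
  lesions <- lapply(seq_along(lesion_radii_mm), function(i) {
    phantom_shape("tumour", "sphere", centres[[i]],
                  lesion_radii_mm[i], id = paste0("lesion", i))
  })
  organs <- list(
    phantom_shape("soft_tissue", "box", c(80, 150, 40), c(78, 10, 38)),
    phantom_shape("heart", "sphere", c(80, 96, 40), 18),
    phantom_shape("liver", "box", c(40, 120, 14), c(24, 16, 12)),
    phantom_shape("vertebrae", "box", c(120, 110, 40), c(8, 8, 38))
  )
  phantom_spec(grid = c(40, 40, 20), spacing_mm = c(4, 4, 4),
               schedule = schedule, organs = organs, lesions = lesions,
               noise_level = noise_level, seed = seed)
}

#' Generate a synthetic dynamic PET scan with ground truth
#'
#' Paints the tissue geometries onto the grid (every remaining voxel is lung
#' background), assigns each voxel its tissue's noiseless TAC, and adds
#' zero-mean Gaussian frame noise with standard deviation
#' `noise_level * sqrt(amplitude) / sqrt(duration_min)`, mimicking the
#' duration dependence of reconstructed PET count noise. Overlapping
#' geometries are an error. Reproducible for a fixed seed.
#'
#' @param spec a `phantom_spec`
#' @return a `phantom_output` list with elements `image` (`dynamic_image`),
#'   `labels` (3D integer array), `label_table` (named integer vector
#'   tissue -> label), `lesion_masks` (named list of logical arrays, each the
#'   true lesion dilated by `rim_voxels`), `lesion_truth` (undilated true
#'   lesion masks), `true_tacs` (tibble: tissue, frame, mid_s, value)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  tissue_names <- names(spec$tissues)
  label_table <- stats::setNames(seq_along(tissue_names), tissue_names)

  labels <- array(label_table[["lung"]], grid)
  claimed <- array(FALSE, grid)
  paint <- function(sh) {
    m <- shape_mask(sh, grid, spec$spacing_mm)
    if (!any(m)) stop(sprintf("geometry '%s' covers no voxels", sh$tissue),
                      call. = FALSE)
    if (any(claimed & m)) {
      stop(sprintf("geometry '%s' overlaps a previously placed tissue",
                   sh$tissue), call. = FALSE)
    }
    claimed[m] <<- TRUE
    labels[m] <<- label_table[[sh$tissue]]
    m
  }
  for (sh in spec$organs) paint(sh)
  lesion_truth <- list()
  for (sh in spec$lesions) {
    if (sh$tissue != "tumour") stop("lesions must have tissue 'tumour'", call. = FALSE)
    lesion_truth[[sh$id %||% paste0("lesion", length(lesion_truth) + 1)]] <- paint(sh)
  }

  sched <- spec$schedule
  N <- n_frames(sched)
  tac_by_tissue <- lapply(spec$tissues, evaluate_tissue_tac, schedule = sched)
  amp_by_tissue <- vapply(spec$tissues, function(m) m$amplitude, numeric(1))

  nvox <- prod(grid)
  lab_vec <- as.vector(labels)
  data <- matrix(0, nrow = nvox, ncol = N)
  for (tn in tissue_names) {
    sel <- lab_vec == label_table[[tn]]
    if (any(sel)) data[sel, ] <- matrix(tac_by_tissue[[tn]], nrow = sum(sel),
                                        ncol = N, byrow = TRUE)
  }
  if (spec$noise_level > 0) {
    set.seed(spec$seed)
    dur_min <- sched$duration_s / 60
    sd_vox <- spec$noise_level * sqrt(amp_by_tissue[lab_vec]) # per voxel
    for (t in seq_len(N)) {
      data[, t] <- data[, t] + stats::rnorm(nvox, 0, sd_vox / sqrt(dur_min[t]))
    }
  }
  img <- dynamic_image(array(data, c(grid, N)), spec$spacing_mm, sched,
                       dose_MBq = spec$dose_MBq, weight_kg = spec$weight_kg)

  lesion_masks <- lapply(lesion_truth, dilate_mask, voxels = spec$rim_voxels)

  true_tacs <- purrr::map_dfr(tissue_names, function(tn) {
    tibble::tibble(tissue = tn, frame = sched$frame, start_s = sched$start_s,
                   duration_s = sched$duration_s, mid_s = sched$mid_s,
                   value = tac_by_tissue[[tn]])
  })

  structure(
    list(image = img, labels = labels, label_table = label_table,
         lesion_masks = lesion_masks, lesion_truth = lesion_truth,
         true_tacs = true_tacs, spec = spec),
    class = "phantom_output"
  )
}

#' Generate a paired test-retest phantom
#'
#' Two realizations of the same phantom specification (identical geometry and
#' true TACs) with independent noise, emulating a patient scanned twice within
#' days.
#'
#' @param spec a `phantom_spec`
#' @param seeds two distinct RNG seeds, one per scan
#' @return list with elements `test` and `retest`, each a `phantom_output`
#' @export
generate_trt_pair <- function(spec, seeds = c(1L, 2L)) {
  stopifnot(length(seeds) == 2)
  if (seeds[1] == seeds[2]) stop("seeds must differ", call. = FALSE)
  s1 <- spec; s1$seed <- as.integer(seeds[1])
  s2 <- spec; s2$seed <- as.integer(seeds[2])
  list(test = generate_phantom(s1), retest = generate_phantom(s2))
}

#' Binary dilation of a 3D mask
#'
#' Grows a mask by `voxels` layers of 26-connected neighbours; `voxels = 0`
#' returns the mask unchanged.
#'
#' @param mask logical 3D array
#' @param voxels number of dilation layers (non-negative integer)
#' @return logical 3D array, superset of `mask`
#' @export
dilate_mask <- function(mask, voxels = 1L) {
  stopifnot(length(dim(mask)) == 3, voxels >= 0)
  m <- array(as.logical(mask), dim(mask))
  if (voxels == 0 || !any(m)) return(m)
  d <- dim(m)
  for (r in seq_len(voxels)) {
    out <- m
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
      out <- out | m[xs, ys, zs]
    }
    m <- out
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
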