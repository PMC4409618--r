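# Shared fixtures: small phantoms and kinetic-class sets built in code.

# Compact phantom for fast tests: same tissue layout as the default spec but
# on a 20x20x10 grid at 8 mm spacing (same 16x16x8 cm field of view).
small_phantom_spec <- function(schedule = builtin_schedules()$vumc_trt_39,
                               noise_level = 0, seed = 1L) {
  organs <- list(
    phantom_shape("soft_tissue", "box", c(80, 150, 40), c(78, 10, 38)),
    phantom_shape("heart", "sphere", c(80, 96, 40), 18),
    phantom_shape("liver", "box", c(40, 120, 14), c(24, 16, 12)),
    phantom_shape("vertebrae", "box", c(120, 110, 40), c(8, 8, 38))
  )
  lesions <- list(
    phantom_shape("tumour", "sphere", c(44, 48, 40), 14, id = "lesion1"),
    phantom_shape("tumour", "sphere", c(116, 44, 44), 10, id = "lesion2")
  )
  phantom_spec(grid = c(20, 20, 10), spacing_mm = c(8, 8, 8),
               schedule = schedule, organs = organs, lesions = lesions,
               noise_level = noise_level, seed = seed, rim_voxels = 1L)
}

# Kinetic classes whose means equal the phantom's true (dose-normalized)
# tissue TACs. SDs are proportional to the mean with a floor tied to the
# class peak: real reference-class SDs do not vanish in the early frames
# (bolus-timing spread across subjects), and a vanishing sigma would let the
# noisy early frames dominate the distance.
truth_kcs <- function(phantom, source = "hammersmith", sigma_frac = 0.1) {
  spec <- phantom$spec
  classes <- lapply(names(phantom$label_table), function(tn) {
    mu <- dose_normalize(
      phantom$true_tacs$value[phantom$true_tacs$tissue == tn], spec$dose_MBq)
    sigma <- sigma_frac * mu + 0.2 * sigma_frac * max(mu)
    kinetic_class(tn, mu, sigma, phantom$image$schedule)
  })
  kinetic_class_set(classes, source = source)
}

# Kinetic classes derived from a cohort of noisy phantom realizations with
# truth-label VOIs, mirroring how reference classes are built from scans.
cohort_kcs <- function(spec_fn = default_phantom_spec, n = 4, noise = 1.0,
                       source = "hammersmith", seed0 = 100L) {
  scans <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(spec_fn(noise_level = noise, seed = seed0 + i))
    vois <- lapply(ph$label_table, function(code) ph$labels == code)
    list(image = ph$image, vois = vois)
  })
  derive_kinetic_classes(scans, source = source)
}

# Uniform sphere on a uniform background, for A50% geometry tests.
sphere_image <- function(grid, spacing, centre_mm, radius_mm, value,
                         background = 0) {
  ax <- lapply(1:3, function(a) (seq_len(grid[a]) - 0.5) * spacing[a])
  d2 <- outer(outer((ax[[1]] - centre_mm[1])^2, (ax[[2]] - centre_mm[2])^2, "+"),
              (ax[[3]] - centre_mm[3])^2, "+")
  img <- array(background, grid)
  img[d2 <= radius_mm^2] <- value
  img
}

# Per-voxel reference implementation of nearest-class assignment, built
# directly on mahalanobis_distance(); the oracle for classify_voxels().
brute_force_classify <- function(image, kcs, sigma_scale = 1, frames = NULL,
                                 tissues = names(kcs$classes)) {
  kcs_rs <- resample_class_set(kcs, image$schedule)
  V <- as_tac_matrix(image) / image$dose_MBq
  labs <- integer(nrow(V))
  for (v in seq_len(nrow(V))) {
    dists <- vapply(tissues, function(tn) {
      mahalanobis_distance(V[v, ], kcs_rs$classes[[tn]], sigma_scale, frames)
    }, numeric(1))
    labs[v] <- which.min(dists)  # first minimum = earlier class wins ties
  }
  array(labs, dim(image$data)[1:3])
}
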