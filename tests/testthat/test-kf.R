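mini_schedule <- function(n) new_frame_schedule(60 * (seq_len(n) - 1), rep(60, n))

test_that("mahalanobis_distance matches the direct summation oracle", {
  s1 <- mini_schedule(1)
  kc1 <- kinetic_class("t", mu = 1, sigma = 1, schedule = s1)
  expect_equal(mahalanobis_distance(1, kc1), 0)      # p = mu
  expect_equal(mahalanobis_distance(3, kc1), 2)      # sqrt(((3-1)/1)^2)

  s2 <- mini_schedule(2)
  kc2 <- kinetic_class("t", mu = c(1, 3), sigma = c(1, 2), schedule = s2)
  expect_equal(mahalanobis_distance(c(2, 5), kc2), sqrt(2))

  # oracle on random cases: direct sum, including sigma scaling and windows
  set.seed(1)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    kc <- kinetic_class("t", mu = runif(n), sigma = runif(n, 0.1, 2),
                        schedule = mini_schedule(n))
    p <- runif(n)
    sc <- sample(c(0.5, 1, 2), 1)
    fr <- sort(sample(n, sample(2:n, 1)))
    expect_equal(mahalanobis_distance(p, kc, sc, fr),
                 sqrt(sum(((p[fr] - kc$mu[fr]) / (sc * kc$sigma[fr]))^2)))
  }

  kc0 <- kinetic_class("t", mu = c(1, 2), sigma = c(1, 0), schedule = s2)
  expect_error(mahalanobis_distance(c(1, 2), kc0), "degenerate")
  expect_equal(mahalanobis_distance(c(1, 2), kc0, frames = 1), 0)
})

test_that("temporal smoothing is the 3-point mean with edge rule", {
  sch <- mini_schedule(3)
  data <- array(0, c(1, 1, 1, 3)); data[1, 1, 1, ] <- c(0, 3, 0)
  img <- dynamic_image(data, c(4, 4, 4), sch)
  sm <- temporal_smooth(img)
  expect_equal(as.numeric(sm$data[1, 1, 1, ]), c(1.5, 1, 1.5))

  const <- dynamic_image(array(7, c(2, 2, 1, 4)), c(4, 4, 4), mini_schedule(4))
  expect_equal(temporal_smooth(const)$data, const$data)

  single <- dynamic_image(array(5, c(2, 2, 1, 1)), c(4, 4, 4), mini_schedule(1))
  expect_identical(temporal_smooth(single)$data, single$data)
})

test_that("noiseless matched-class phantom is classified exactly", {
  ph <- generate_phantom(small_phantom_spec(noise_level = 0))
  kcs <- truth_kcs(ph)
  # without any reclassification, labels equal truth everywhere
  cfg <- kf_config("raw", reclass_global = NULL)
  li <- classify_voxels(ph$image, kcs, cfg)
  expect_identical(as.vector(li$labels), as.vector(ph$labels))

  # the original rule folds vertebrae into tumour globally
  li2 <- classify_voxels(ph$image, kcs, kf_config())
  truth2 <- ph$labels
  truth2[truth2 == ph$label_table[["vertebrae"]]] <- ph$label_table[["tumour"]]
  expect_identical(as.vector(li2$labels), as.vector(truth2))
})

test_that("vectorized classification equals the per-voxel brute-force loop", {
  spec <- small_phantom_spec(noise_level = 2, seed = 21L)
  ph <- generate_phantom(spec)
  kcs <- truth_kcs(ph)
  li <- classify_voxels(ph$image, kcs, kf_config("raw", reclass_global = NULL))
  oracle <- brute_force_classify(ph$image, kcs)
  expect_identical(as.vector(li$labels), as.vector(oracle))

  # with a time window and sigma scaling
  win <- c(15, 60)
  cfg <- kf_config("w", reclass_global = NULL, time_window = win,
                   sigma_scale = 2)
  li_w <- classify_voxels(ph$image, kcs, cfg)
  fr <- restrict_time_window(ph$image$schedule, win)
  oracle_w <- brute_force_classify(ph$image, kcs, sigma_scale = 2, frames = fr)
  expect_identical(as.vector(li_w$labels), as.vector(oracle_w))
})

test_that("equidistant voxels break ties by class order", {
  sch <- mini_schedule(2)
  kcs <- kinetic_class_set(list(
    kinetic_class("tumour", c(1, 1), c(1, 1), sch),
    kinetic_class("lung", c(3, 3), c(1, 1), sch)
  ))
  data <- array(2, c(2, 2, 1, 2))   # every voxel exactly between the classes
  img <- dynamic_image(data, c(4, 4, 4), sch, dose_MBq = 1)
  li <- classify_voxels(img, kcs, kf_config("tie", reclass_global = NULL))
  expect_true(all(li$labels == li$label_table[["tumour"]]))
})

test_that("uniform sigma scaling leaves the classification unchanged", {
  ph <- generate_phantom(small_phantom_spec(noise_level = 2, seed = 3L))
  kcs <- truth_kcs(ph)
  labs <- lapply(c(0.5, 1.0, 2.0), function(s) {
    classify_voxels(ph$image, kcs, kf_config(sigma_scale = s))$labels
  })
  expect_identical(labs[[1]], labs[[2]])
  expect_identical(labs[[2]], labs[[3]])
})

test_that("omitting classes only reassigns voxels of the omitted classes", {
  ph <- generate_phantom(small_phantom_spec(noise_level = 2, seed = 4L))
  kcs <- truth_kcs(ph)
  full <- classify_voxels(ph$image, kcs, kf_config("f", reclass_global = NULL))
  red <- classify_voxels(ph$image, kcs,
                         kf_config("r", reclass_global = NULL,
                                   class_omit = "liver"))
  full_t <- names(full$label_table)[full$labels]
  red_t <- names(red$label_table)[red$labels]
  expect_false(any(red_t == "liver"))
  moved <- full_t != red_t
  expect_true(all(full_t[moved] == "liver"))
})

test_that("in-mask reclassification maps only inside the mask and conserves voxels", {
  ph <- generate_phantom(small_phantom_spec(noise_level = 0))
  kcs <- truth_kcs(ph)
  li <- classify_voxels(ph$image, kcs, kf_config("raw", reclass_global = NULL))
  liver_code <- li$label_table[["liver"]]
  # mask covering part of the liver
  mask <- array(FALSE, dim(li$labels))
  liver_vox <- which(li$labels == liver_code)
  mask[liver_vox[1:5]] <- TRUE

  out <- reclassify_within_mask(li, mask, c(liver = "tumour"))
  expect_true(all(out$labels[mask] == out$label_table[["tumour"]]))
  expect_identical(out$labels[!mask], li$labels[!mask])
  expect_identical(length(out$labels), length(li$labels))

  # idempotence and the empty map
  again <- reclassify_within_mask(out, mask, c(liver = "tumour"))
  expect_identical(again$labels, out$labels)
  expect_identical(reclassify_within_mask(li, mask, NULL)$labels, li$labels)
})

test_that("per-lesion segmentation extracts tumour voxels within the mask", {
  ph <- generate_phantom(small_phantom_spec(noise_level = 0))
  kcs <- truth_kcs(ph)
  li <- classify_voxels(ph$image, kcs, kf_config())
  for (id in names(ph$lesion_masks)) {
    res <- segment_lesion_kf(li, ph$lesion_masks[[id]], kf_config())
    expect_true(res$detected)
    expect_equal(dice(res$voi, ph$lesion_truth[[id]]), 1.0)
    expect_equal(res$volume_cm3,
                 volume_cm3(ph$lesion_truth[[id]], ph$image$spacing))
  }
  # a mask with no tumour-labelled voxels -> not detected, empty VOI
  far <- array(FALSE, dim(li$labels)); far[1, 1, 1] <- TRUE
  res0 <- segment_lesion_kf(li, far, kf_config())
  expect_false(res0$detected)
  expect_equal(res0$n_voxels, 0)
  expect_error(segment_lesion_kf(li, array(FALSE, dim(li$labels)), kf_config()),
               "empty")
})

test_that("KF presets run end to end with their configured rules", {
  ph <- generate_phantom(small_phantom_spec(noise_level = 0, seed = 9L))
  kcs_by_source <- list(hammersmith = truth_kcs(ph, "hammersmith"),
                        vumc = truth_kcs(ph, "vumc"))
  presets <- kf_presets()
  expect_named(presets, paste0("KF", 1:9))

  # KF1 on a matched phantom detects all lesions
  r1 <- run_kf_preset(ph$image, kcs_by_source, ph$lesion_masks, "KF1")
  expect_true(all(r1$lesions$detected))

  # KF7: liver and vertebrae classes absent -> no voxel carries those labels
  r7 <- run_kf_preset(ph$image, kcs_by_source, ph$lesion_masks, "KF7")
  expect_false(any(c("liver", "vertebrae") %in% names(r7$labels$label_table)))

  # KF9 uses the VUmc source, smoothing, window and in-mask reclassification
  r9 <- run_kf_preset(ph$image, kcs_by_source, ph$lesion_masks, "KF9")
  expect_true(all(r9$lesions$detected))

  expect_error(run_kf_preset(ph$image, kcs_by_source, ph$lesion_masks, "KF99"),
               "unknown")
  expect_error(run_kf_preset(ph$image, list(other = kcs_by_source$vumc),
                             ph$lesion_masks, "KF1"), "not available")
})

test_that("KF1 lesion Dice does not improve with increasing noise", {
  kcs <- cohort_kcs(small_phantom_spec, n = 3, noise = 1, seed0 = 300L)
  mean_dice <- sapply(c(1, 5, 10), function(nl) {
    mean(sapply(1:5, function(s) {
      ph <- generate_phantom(small_phantom_spec(noise_level = nl,
                                                seed = 400L + 10 * nl + s))
      run <- run_kf_preset(ph$image, kcs, ph$lesion_masks, "KF1")
      mean(sapply(names(ph$lesion_masks), function(id) {
        dice(run$results[[id]]$voi, ph$lesion_truth[[id]])
      }))
    }))
  })
  expect_true(all(diff(mean_dice) <= 0.02))  # non-increasing up to sampling noise
})
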