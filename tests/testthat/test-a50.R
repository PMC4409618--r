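test_that("find_max_voxel locates the hottest voxel near the seed", {
  img <- sphere_image(c(20, 20, 10), c(4, 4, 4), c(40, 40, 20), 10, 8, 1)
  img[10, 10, 5] <- 50   # unique global max at (10,10,5) -> mm (38,38,18)
  expect_identical(find_max_voxel(img, c(38, 38, 18), 20, c(4, 4, 4)),
                   c(10L, 10L, 5L))
  # uniform image: tie goes to the lowest linear index in the sphere
  flat <- array(1, c(8, 8, 8))
  got <- find_max_voxel(flat, c(16, 16, 16), 6, c(4, 4, 4))
  cand <- which(outer(outer(((1:8) * 4 - 2 - 16)^2, ((1:8) * 4 - 2 - 16)^2, "+"),
                      ((1:8) * 4 - 2 - 16)^2, "+") <= 36)
  expect_identical(got, as.integer(arrayInd(min(cand), c(8, 8, 8))))
  # brute-force max within the search sphere oracle
  got2 <- find_max_voxel(img, c(40, 40, 20), 15, c(4, 4, 4))
  ctr <- lapply(1:3, function(a) ((seq_len(dim(img)[a])) - 0.5) * 4)
  d2 <- outer(outer((ctr[[1]] - 40)^2, (ctr[[2]] - 40)^2, "+"),
              (ctr[[3]] - 20)^2, "+")
  expect_equal(img[got2[1], got2[2], got2[3]], max(img[d2 <= 15^2]))
  expect_error(find_max_voxel(img, c(500, 0, 0), 20, c(4, 4, 4)), "outside")
})

test_that("grow_isocontour returns the seeded connected component", {
  sp <- c(4, 4, 4)
  img <- sphere_image(c(20, 20, 10), sp, c(30, 30, 20), 9, 8, 0)
  img2 <- img + sphere_image(c(20, 20, 10), sp, c(56, 56, 20), 9, 8, 0)
  start <- find_max_voxel(img2, c(30, 30, 20), 10, sp)

  # only the first sphere's voxels
  m <- grow_isocontour(img2, start, 4)
  expect_true(all(img2[m] >= 4))
  expect_identical(as.vector(m), as.vector(img >= 4))

  # threshold at the max keeps the start voxel (plus equal-valued neighbours)
  top <- grow_isocontour(img2, start, 8)
  expect_true(all(img2[top] == 8))
  expect_true(top[start[1], start[2], start[3]])

  # threshold at the global minimum floods the whole grid
  all_m <- grow_isocontour(img2, start, 0)
  expect_true(all(all_m))

  expect_error(grow_isocontour(img2, c(1, 1, 1), 4), "below the threshold")
})

test_that("region growing equals a brute-force component labelling oracle", {
  set.seed(8)
  img <- array(runif(6 * 6 * 4), c(6, 6, 4))
  thr <- 0.5
  starts <- which(img >= thr)
  start <- arrayInd(starts[1], dim(img))
  for (conn in c(6, 26)) {
    m <- grow_isocontour(img, as.integer(start), thr, conn)
    # oracle: iterate dilation-and-mask until fixpoint
    ref <- array(FALSE, dim(img)); ref[start[1], start[2], start[3]] <- TRUE
    above <- img >= thr
    repeat {
      if (conn == 26) {
        grown <- dilate_mask(ref, 1L) & above
      } else {
        d <- dim(ref); grown <- ref
        for (ax in 1:3) for (by in c(-1, 1)) {
          idx <- pmin(pmax(seq_len(d[ax]) + by, 1), d[ax])
          sh <- switch(ax, ref[idx, , , drop = FALSE],
                       ref[, idx, , drop = FALSE], ref[, , idx, drop = FALSE])
          grown <- grown | (array(sh, d) & above)
        }
      }
      if (identical(grown, ref)) break
      ref <- grown
    }
    expect_identical(m, ref)
  }
})

test_that("local background averages the 1.5-cm shell and matches brute force", {
  sp <- c(4, 4, 4)
  grid <- c(24, 24, 24)
  img <- sphere_image(grid, sp, c(48, 48, 48), 10, 8, 2)
  contour <- sphere_image(grid, sp, c(48, 48, 48), 10, 1, 0) > 0
  p <- a50_params()
  expect_equal(local_background(img, contour, p, sp), 2)  # uniform background
  expect_equal(local_background(array(0, grid), contour, p, sp), 0)

  # brute-force shell oracle: per-voxel min distance to contour surface
  set.seed(2)
  img_r <- img + array(rnorm(prod(grid)), grid)
  ijk_all <- arrayInd(which(contour), dim(contour))
  # surface = contour voxels with an outside 6-neighbour
  is_surf <- apply(ijk_all, 1, function(v) {
    for (ax in 1:3) for (by in c(-1, 1)) {
      w <- v; w[ax] <- w[ax] + by
      if (any(w < 1) || any(w > grid)) return(TRUE)
      if (!contour[w[1], w[2], w[3]]) return(TRUE)
    }
    FALSE
  })
  surf_mm <- sweep(ijk_all[is_surf, , drop = FALSE] - 0.5, 2, sp, "*")
  pitch <- mean(sp)
  vals <- c(); n_shell <- 0
  for (lin in which(!contour)) {
    v <- arrayInd(lin, grid)
    mm <- (v - 0.5) * sp
    dmin <- sqrt(min(colSums((t(surf_mm) - as.numeric(mm))^2)))
    if (dmin >= 15 && dmin < 15 + pitch) {
      vals <- c(vals, img_r[lin]); n_shell <- n_shell + 1
    }
  }
  expect_gt(n_shell, 0)
  expect_equal(local_background(img_r, contour, p, sp), mean(vals))

  # lesion too close to the border: shell empty
  tiny <- sphere_image(c(6, 6, 6), sp, c(12, 12, 12), 8, 5, 1)
  tiny_contour <- tiny > 4
  expect_error(local_background(tiny, tiny_contour, p, sp), "shell")
})

test_that("a50_segment applies threshold = 0.5 x (max + background)", {
  sp <- c(4, 4, 4)
  img <- sphere_image(c(24, 24, 24), sp, c(48, 48, 48), 10, 10, 2)
  res <- a50_segment(img, c(48, 48, 48), sp)
  expect_equal(res$max_value, 10)
  expect_equal(res$background, 2)
  expect_equal(res$threshold, 6)      # 0.5 x (10 + 2)
  expect_true(res$detected)
  expect_true(all(img[res$voi] >= res$threshold))
  expect_identical(as.vector(res$voi), as.vector(img >= 6))
})

test_that("A50 is invariant to positive rescaling of the image", {
  sp <- c(4, 4, 4)
  img <- sphere_image(c(24, 24, 24), sp, c(48, 48, 48), 12, 4, 1)
  set.seed(5)
  img <- img + array(abs(rnorm(length(img), 0, 0.1)), dim(img))
  base <- a50_segment(img, c(48, 48, 48), sp)
  for (k in c(0.1, 3, 250)) {
    scaled <- a50_segment(k * img, c(48, 48, 48), sp)
    expect_identical(scaled$voi, base$voi)
    expect_equal(scaled$threshold, k * base$threshold)
  }
})

test_that("raising the threshold fraction never enlarges the VOI", {
  sp <- c(4, 4, 4)
  img <- sphere_image(c(24, 24, 24), sp, c(48, 48, 48), 12, 8, 1)
  set.seed(6)
  img <- img + array(abs(rnorm(length(img), 0, 0.2)), dim(img))
  fracs <- c(0.3, 0.5, 0.7, 0.9)
  sizes <- sapply(fracs, function(f) {
    a50_segment(img, c(48, 48, 48), sp,
                a50_params(threshold_fraction = f))$n_voxels
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("flat images yield no contrast and no detection", {
  img <- array(3, c(12, 12, 12))
  res <- a50_segment(img, c(24, 24, 24), c(4, 4, 4))
  expect_false(res$detected)
  expect_equal(res$threshold, res$background)
})

test_that("noiseless spheres are recovered within the discretization bound", {
  sp <- c(2, 2, 2)
  grid <- c(40, 40, 40)
  centre <- c(40, 40, 40)
  pitch <- mean(sp)
  for (radius in c(6, 10, 14, 20)) {
    for (contrast in c(0, 0.25, 0.5)) {
      img <- sphere_image(grid, sp, centre, radius, 8, 8 * contrast)
      res <- a50_segment(img, centre, sp)
      expect_true(res$detected)
      v_true <- 4 / 3 * pi * radius^3 / 1000
      bound <- 4 * pi * radius^2 * 1.5 * pitch / 1000  # 1.5 surface shells
      expect_lt(abs(res$volume_cm3 - v_true), bound)
    }
  }
})

test_that("a leak beyond the bounding region suppresses detection", {
  sp <- c(4, 4, 4)
  img <- sphere_image(c(24, 24, 24), sp, c(48, 48, 48), 10, 10, 2)
  bound_tight <- sphere_image(c(24, 24, 24), sp, c(48, 48, 48), 6, 1, 0) > 0
  res <- a50_segment(img, c(48, 48, 48), sp, bound_mask = bound_tight)
  expect_true(res$leak)
  expect_false(res$detected)
})
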