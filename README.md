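# dynpetseg

Segmentation of metabolically active tumour volume in **dynamic PET**
(e.g. 18F-FLT) and evaluation of its **test–retest repeatability**, for
imaging scientists working with dynamic thoracic PET protocols.

The package implements:

* **Kinetic filtering (KF)** — supervised per-voxel classification of
  time-activity curves (TACs). Each voxel TAC `p_t` over `N` frames is
  assigned to the reference *kinetic class* (tissue mean TAC `mu_t` with
  per-frame SD `sigma_t`) minimising the Mahalanobis distance

  `D_M = sqrt( sum_t ((p_t - mu_t) / sigma_t)^2 )`,

  with nine published variant configurations (`KF1`–`KF9`: temporal
  smoothing, schedule resampling direction, SD scaling, time windows, class
  subsets, global and in-lesion-mask reclassification).
* **A50%** — a background-adapted isocontour on the late-frame mean image:
  region growing from the hottest voxel at a threshold of
  `0.5 * (max + local background)`, the background being the mean of a
  1-voxel shell 1.5 cm outside the 70%-of-max isocontour.
* **Kinetic-class derivation** from cohorts of dynamic scans with tissue
  VOIs, plus temporal resampling of classes between frame schedules.
* **Metrics** — volume, body-weight SUV, the TRT statistic
  `|test - retest| / mean * 100`, and method comparison tables.
* A **4D digital phantom** (lung/soft-tissue/heart/liver/vertebrae/tumour
  compartments with class-distinct kinetics and frame-duration-dependent
  noise, paired test/retest realizations) so that every stage is testable
  without clinical data.

Tabular results are tibbles; `tidy()`, `glance()` and `autoplot()` methods
are provided for class sets and TRT comparisons. See the vignette
(`vignettes/dynamic-pet-segmentation.Rmd`) for the methods and all design
decisions.

## Worked example

Simulate a paired test/retest phantom, derive kinetic classes from a
simulated development cohort, and compare the repeatability of a KF variant
against A50%:

```r
library(dynpetseg)

# a 60-min, 39-frame dynamic protocol; two lung lesions; strong noise
spec <- default_phantom_spec(noise_level = 5, seed = 1L)
pair <- generate_trt_pair(spec, seeds = c(11L, 12L))

# kinetic classes from 4 simulated scans with tissue VOIs
scans <- lapply(1:4, function(i) {
  ph <- generate_phantom(default_phantom_spec(noise_level = 1, seed = 100L + i))
  list(image = ph$image,
       vois = lapply(ph$label_table, function(code) ph$labels == code))
})
kcs <- derive_kinetic_classes(scans, source = "hammersmith")

res <- run_trt_pipeline(pair$test$image, pair$retest$image,
                        pair$test$lesion_masks, kcs, kf_preset = "KF5")
glance(res$comparison)
res$comparison$detection
```

```
  method     metric n median_pct_var median_abs_diff
1    A50    suv_max 2           25.9           1.599
2    A50   suv_mean 2           17.9           0.745
3    A50 volume_cm3 2           72.8           2.624
4    KF5    suv_max 2           25.9           1.599
5    KF5   suv_mean 2            5.3           0.172
6    KF5 volume_cm3 2            0.0           0.000

  method n_detected_both n_lesions
1    A50               2         2
2    KF5               2         2
```

Both methods detect both lesions on both scans. The columns are per-lesion
test–retest variability (percent of the test/retest mean) and absolute
differences, summarised per method and metric. At this deliberately high
noise level the threshold method's volume repeatability degrades (its
threshold depends on the noise-inflated maximum voxel), while the kinetic
classifier, which pools evidence over all 39 frames, still reproduces the
lesion volume exactly; at the default `noise_level = 1` both methods achieve
0% volume variability on the homogeneous phantom. Phantom TRT values are
optimistic relative to clinical data — tissues are homogeneous and the pairs
are perfectly aligned (see the vignette's phantom section).

A command-line interface wrapping the same functions is installed as
`exec/dynpetseg` (`simulate`, `derive-kc`, `segment-kf`, `segment-a50`,
`trt`, `run`), reading/writing NIfTI images with JSON timing sidecars.

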