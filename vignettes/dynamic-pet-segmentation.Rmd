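---
title: "Kinetic filtering and A50% segmentation of dynamic PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic filtering and A50% segmentation of dynamic PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpetseg)
```

## The problem

Dynamic PET with proliferation tracers such as 18F-FLT records, for every
voxel, a time-activity curve (TAC): the tissue activity concentration over a
sequence of acquisition frames of varying duration. Delineating the
metabolically active tumour volume in such data is needed for response
monitoring, and manual delineation is slow and observer-dependent. This
package implements two automated approaches and the machinery to evaluate
their test-retest (TRT) repeatability:

* **Kinetic filtering (KF)** — a supervised per-voxel classifier that assigns
  each voxel to the reference tissue whose kinetics it most resembles;
* **A50%** — a background-adapted relative threshold applied to the late
  uptake image, grown as an isocontour region from the hottest voxel.

Because the clinical scans this family of methods was developed on are not
publicly available, the package ships a 4D digital phantom whose ground truth
(tissue labels, lesion masks, noiseless TACs) makes every stage verifiable.

## Kinetic filtering

### The classifier

Each voxel TAC $p_t$ ($t = 1 \dots N$ frames) is compared against a set of
*kinetic classes* (KCs). A kinetic class for tissue $M$ consists of a mean
dose-normalized TAC $\mu_t$ and a per-frame standard deviation $\sigma_t$.
The voxel is assigned to the class minimising the SD-weighted (Mahalanobis)
distance

$$ D_M \;=\; \sqrt{\sum_{t=1}^{N} \left( \frac{p_t - \mu_t}{\sigma_t} \right)^{\!2} }, $$

with $\sigma_t$ acting as a per-frame weighting factor: frames on which the
reference population varied widely contribute less. Voxel TACs are
dose-normalized (divided by the injected MBq) before the comparison, since
classes are stored per injected MBq. Classes are defined on their own frame
schedule; before classification either the classes are linearly resampled to
the scan's frame mid-times (the default) or the scan's voxel TACs are
interpolated to the class frame times.

Ties at exactly equal distance are broken by the class order of the set — a
deterministic rule the method itself does not specify. Classification is pure
per-voxel nearest-class assignment; no spatial regularisation is applied.

A frame in which $\sigma_t = 0$ makes the distance undefined; the package
raises an error rather than silently dropping the frame, because silent frame
dropping would change the statistic invisibly. Degenerate classes arise, for
example, when classes are derived from identical scans; a small SD floor in
the class definition is the user's explicit decision, not the package's.

### Kinetic classes

`derive_kinetic_classes()` builds a class set from two or more dynamic scans
with per-tissue VOIs: per scan, the tissue TAC is the spatial mean over the
VOI, dose-normalized; per tissue, $\mu_t$ is the across-scan mean and
$\sigma_t$ the across-scan sample SD (denominator $n-1$). The across-scan
(rather than across-voxel) SD matches the description of the reference
classes this implementation follows. Dose normalization divides by injected
MBq only; body weight enters SUV computation but not the classes.

### Temporal resampling

`resample_tac()` interpolates (mid-time, value) pairs linearly and clamps
outside the source range (nearest value). Mid-time linear interpolation is
the standard TAC convention; clamping makes the 95-min-class versus
60-min-scan mismatch deterministic: class frames beyond the scan simply hold
the last scan value, and vice versa. The resampling is exact for identical
schedules and for affine-in-time inputs at interior mid-times.

### The variants KF1–KF9

`kf_presets()` encodes nine published variants as configurations over one
pipeline (smoothing → schedule alignment → time window → class subset →
classification → reclassification → per-lesion segmentation):

| preset | classes | changes relative to the original |
|---|---|---|
| KF1 | site A ("hammersmith") | none (vertebrae folded into tumour globally) |
| KF2 | site A | 3-point temporal smoothing of voxel TACs |
| KF3 | site A | scan interpolated to the class frame times |
| KF4 | site A | liver→tumour inside lesion masks; 9–60 min window |
| KF5 | site A | liver→tumour inside lesion masks; 20–60 min window |
| KF6 | site A | liver class omitted |
| KF7 | site A | liver and vertebrae classes omitted |
| KF8 | site B ("vumc") | none |
| KF9 | site B | liver+vertebrae→tumour in masks; smoothing; 15–60 min window |

Notes on interpretation where the published description is ambiguous:

* The KF9 mechanism ("the required order of the distances … to allow for
  reclassification of vertebrae") is implemented as the in-mask
  reclassification map `{liver→tumour, vertebrae→tumour}` combined with
  smoothing and the 15–60-min window.
* The frame-count arithmetic quoted for the schedule-adaptation variant
  ("from 40 to 31 frames by reducing the first 10 minutes from 26 to 16
  frames") does not match the printed schedules (the TRT schedule has 39
  frames and 26 frames in the first 10 min would leave 13+13 ≠ 31). KF3
  therefore resamples to the full 31-frame reference schedule, which is what
  the printed schedules support.
* Whether the SD scaling (0.5/1.0/2.0) was uniform or per-class is not
  stated; it is implemented as a uniform factor, under which the arg-min —
  and hence the label image — is provably unchanged. The package asserts this
  invariance rather than tuning the factor.

### Lesion masks and detection

Lesion-level output is constrained to user-supplied lesion masks (in the
phantom: the true lesion dilated by a 2-voxel rim, emulating a manually drawn
"tumour plus a rim" VOI). The lesion VOI is the set of tumour-labelled voxels
inside the mask after the in-mask reclassification. A lesion counts as
*detected* when the VOI holds at least `min_detect_voxels` voxels (default
1). The published work never defines "reliably segmented"; the threshold is
therefore configurable and recorded in the run log. The VOI is deliberately
not restricted to one connected component; component statistics can be
derived from the label image by users who want stricter rules.

## A50% segmentation

The input is the duration-weighted mean of the last three frames (45–60 min
post injection on the 60-min protocol). A "sum image" and a mean image give
identical segmentations because all A50% thresholds are relative; the mean is
used because it is also the correct input for SUV.

1. `find_max_voxel()` — the hottest voxel within 20 mm (configurable) of a
   user seed; ties go to the lowest linear index.
2. `grow_isocontour()` at 70% of the maximum — the initial contour
   (26-connectivity by default; 6 available).
3. `local_background()` — the mean of a one-voxel-thick shell of voxels at
   1.5 cm from the boundary of the initial contour. Distance is Euclidean in
   mm from each outside voxel centre to the nearest boundary voxel centre;
   "one voxel thick" is one mean voxel pitch, which generalises to
   anisotropic grids. No exclusion of other hot structures is applied beyond
   the contour interior itself.
4. Final threshold $0.5 \times (\text{max} + \text{background})$;
   `grow_isocontour()` from the maximum voxel gives the VOI. Comparison is
   inclusive (`>=`): voxels exactly at the threshold are included.
5. Not detected when the threshold does not exceed the background (no
   contrast, e.g. a flat image) or when the VOI escapes an optional bounding
   region (leak guard; in the pipeline the lesion mask dilated by 2 voxels).

Degenerate cases are explicit: an initial contour flooding the whole grid
leaves no background shell, and the background is then taken equal to the
maximum, which forces "not detected"; a final threshold above the maximum
yields an empty VOI. A lesion so close to the image border that the shell is
empty raises an error with a diagnostic rather than returning a biased
background.

## Volume, SUV and test-retest statistics

* Volume: voxel count × voxel volume (cm³).
* SUV: body-weight convention, $\mathrm{SUV} = C \cdot w / D$ with $C$ in
  kBq/mL, $w$ in kg, $D$ in MBq (unit factors cancel exactly). Decay
  correction is assumed applied in the image. Both SUVmean and SUVmax are
  emitted, since published per-lesion SUV reporting is ambiguous between
  them.
* TRT variability: $|x_\mathrm{test} - x_\mathrm{retest}| / \bar{x} \times
  100$ — symmetric, scale-invariant, bounded by 200, undefined (NA) when both
  values are zero.
* `compare_methods()` restricts variability rows to lesions detected by every
  method on both scans, and reports both the median and the mean summaries
  (published work mixes the two), plus per-method detection tallies.

## The digital phantom

`generate_phantom()` builds a thoracic scene with six compartments: lung
background, soft tissue, heart, liver, vertebrae and spherical tumours. TAC
shapes are simple analytic families chosen to satisfy the qualitative
kinetics of FLT:

* tumour and vertebral bone marrow: Hill-type monotone accumulation
  (irreversible trapping), half-time 8 and 10 min;
* liver: scaled biexponential — high early uptake with explicitly reversible
  kinetics (decline after the peak), reflecting hepatic metabolisation of the
  tracer;
* heart/blood pool: early bolus peak (~45 s) relaxing to a plateau;
* lung and soft tissue: low flat uptake.

Amplitudes are free parameters of the phantom — the reference-class
amplitudes they mimic are not published as numbers — chosen once so late-time
SUVs are realistic for FLT at 364 MBq in a 75-kg subject: ~0.1 lung, ~0.2
soft tissue, ~0.5 heart plateau, ~2 vertebrae, ~2.9 tumour, liver peaking
near 3.

Frame values are point evaluations of the model curve at frame mid-times,
not integrals over the frame; all downstream operations consume per-frame
values identically, so nothing depends on the distinction.

Noise is zero-mean Gaussian per voxel and frame with

$$ \mathrm{SD} = \text{noise level} \times \sqrt{A} \,/\, \sqrt{\Delta t_\text{min}}, $$

where $A$ is the tissue amplitude and $\Delta t$ the frame duration in
minutes — the duration and intensity dependence of reconstructed-PET count
noise in an OSEM-like (artefact-free) image. The default noise level is 1.0,
which gives roughly 10% relative noise on the tumour in the late 5-min
frames and much noisier early 5-s frames, as in real dynamic scans.

The default scene is a 40×40×20 grid at 4 mm isotropic spacing (16×16×8 cm
field of view) with two lung lesions of 12 and 8 mm radius; the test suite
additionally uses a 20×20×10 grid at 8 mm for fast oracle comparisons. These
sizes were chosen as the smallest grids on which lesions, organs and the
1.5-cm background shell are all well separated.

**What the phantom does and does not emulate.** It reproduces
class-distinct kinetics, frame-duration-dependent noise, paired test-retest
realizations with shared ground truth, and rim-style lesion masks. It does
*not* simulate reconstruction (no FBP streak artefacts — the classifier is
specified for OSEM-like noise only), partial-volume/point-spread effects,
respiratory motion, intra-tissue kinetic heterogeneity, or test-retest
misregistration (pairs are perfectly aligned). Passing phantom tests
therefore demonstrates algorithmic correctness and the direction of noise
effects, not clinical-level repeatability values; in particular the phantom's
TRT percentages are smaller than clinical ones because tissue is homogeneous
and scans are aligned.

### Noise levels used in the stochastic tests

The degradation tests use noise levels 1, 5 and 10 with five seed pairs per
level. Level 1 is the realistic default at which classification of the
homogeneous phantom is essentially error-free; 5 and 10 span the regime where
boundary voxels start flipping class and volume repeatability visibly
degrades. At far higher noise the volume TRT statistic saturates (labels
approach randomness and the tumour fraction inside the mask stabilises), so
monotonicity is only expected — and only asserted — over this moderate range.

## Numerical and design choices, in one place

* Mid-time linear TAC interpolation with clamped extrapolation.
* Across-scan sample SD with denominator $n-1$ for class derivation.
* Duration-weighted (not plain) mean for the late-frame image; identical for
  the equal-length late frames of the built-in schedules.
* Classification ties → first class in set order; `which.min` semantics.
* $\sigma_t = 0$ in scope → error (no silent frame dropping).
* Threshold comparisons inclusive (`>=`); isocontour connectivity default 26.
* Background shell: one mean voxel pitch thick, Euclidean mm distances.
* A50% seed search radius default 20 mm ("near the seed" is unquantified).
* Lesion-mask rim default 2 voxels ("a rim of a few voxels" is unquantified).
* Detection rule: ≥ 1 tumour voxel in the mask, configurable.
* Images interchange as NIfTI with JSON timing sidecars (`starts_s`,
  `durations_s`); NIfTI timing metadata is not trusted. Voxel (i, j, k)
  centres sit at ((i−0.5)·sx, (j−0.5)·sy, (k−0.5)·sz) mm.

## Known limitations

* Per-voxel classification only; no spatial regularisation, so salt-and-pepper
  labels at high noise are expected and visible in the label images.
* The phantom's homogeneous tissues make the classifier look better than it
  is on heterogeneous tumours — the published motivation for in-mask
  reclassification — so variant rankings on the phantom should not be read as
  clinical rankings.
* SUV assumes decay-corrected input; no decay handling is performed.
* No DICOM ingestion, no registration, no partial-volume correction.
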