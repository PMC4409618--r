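#' Volume of a voxel mask in cm3
#'
#' @param voi logical (or 0/1) 3D mask
#' @param spacing voxel spacing, mm
#' @return voxel count x voxel volume, cm3
#' @export
volume_cm3 <- function(voi, spacing) {
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  sum(voi != 0) * prod(spacing) / 1000
}

#' SUV statistics over a VOI
#'
#' Body-weight standard uptake value per voxel:
#' `SUV = concentration * weight / dose` with concentration in kBq/mL, weight
#' in kg and dose in MBq (the unit factors cancel: kBq/mL x g / Bq x 10^6 = 1).
#' Decay correction is assumed already applied in the image, as is standard
#' for reconstructed PET.
#'
#' @param image3d 3D activity-concentration image, kBq/mL
#' @param voi logical 3D mask, nonempty
#' @param dose_MBq injected dose, MBq, > 0
#' @param weight_kg body weight, kg, > 0
#' @return tibble with columns `suv_mean`, `suv_max`
#' @export
suv_stats <- function(image3d, voi, dose_MBq, weight_kg) {
  if (dose_MBq <= 0 || weight_kg <= 0) {
    stop("dose and weight must be positive", call. = FALSE)
  }
  voi <- as_mask(voi, dim(image3d))
  if (!any(voi)) stop("VOI is empty", call. = FALSE)
  suv <- image3d[voi] * weight_kg / dose_MBq
  tibble::tibble(suv_mean = mean(suv), suv_max = max(suv))
}

#' Test-retest variability percentage
#'
#' The repeatability statistic: the absolute difference between test and
#' retest, divided by the mean of both, times 100. Symmetric, scale-invariant
#' and bounded by 200. Undefined (NA) when both values are zero.
#'
#' @param test,retest scalar (or vector) measurements; mean must be positive
#'   where defined
#' @return percent variability in `[0, 200]`, NA where both values are 0
#' @export
trt_variability <- function(test, retest) {
  m <- (test + retest) / 2
  out <- ifelse(test == 0 & retest == 0, NA_real_,
                abs(test - retest) / m * 100)
  bad <- !is.na(out) & m <= 0
  if (any(bad)) {
    stop("mean of test and retest must be positive", call. = FALSE)
  }
  out
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b logical 3D masks on the same grid
#' @return `2|a & b| / (|a| + |b|)`; defined as 1 when both masks are empty
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share a grid", call. = FALSE)
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum((a != 0) & (b != 0)) / (na + nb)
}

#' Per-lesion statistics of a segmentation on a late-uptake image
#'
#' @param result a `segmentation_result`
#' @param image3d late-uptake 3D image (kBq/mL) to read SUVs from
#' @param spacing voxel spacing, mm
#' @param dose_MBq injected dose, MBq
#' @param weight_kg body weight, kg
#' @param lesion_id lesion identifier
#' @param scan scan role label (e.g. `"test"`, `"retest"`)
#' @return one-row tibble: lesion_id, method, scan, detected, n_voxels,
#'   volume_cm3, suv_mean, suv_max (SUVs are NA when the VOI is empty)
#' @export
lesion_stats <- function(result, image3d, spacing, dose_MBq, weight_kg,
                         lesion_id, scan = "test") {
  stopifnot(inherits(result, "segmentation_result"))
  suv <- if (any(result$voi)) {
    suv_stats(image3d, result$voi, dose_MBq, weight_kg)
  } else {
    tibble::tibble(suv_mean = NA_real_, suv_max = NA_real_)
  }
  tibble::tibble(lesion_id = lesion_id, method = result$method, scan = scan,
                 detected = result$detected, n_voxels = result$n_voxels,
                 volume_cm3 = result$volume_cm3,
                 suv_mean = suv$suv_mean, suv_max = suv$suv_max)
}

#' Compare test-retest repeatability of segmentation methods
#'
#' Takes per-lesion statistics of one or more methods on a test and a retest
#' scan and computes, for the lesions detected by every method on both scans,
#' the per-lesion absolute differences and percent test-retest variabilities
#' of volume and SUV, together with per-method median and mean summaries and
#' detection tallies.
#'
#' @param stats tibble as produced by [lesion_stats()] rows, with columns
#'   lesion_id, method, scan ("test"/"retest"), detected, volume_cm3,
#'   suv_mean, suv_max
#' @param metrics which columns to evaluate (default volume and both SUVs)
#' @return a `trt_comparison` list: `trt` (per-lesion rows: lesion_id, method,
#'   metric, test, retest, abs_diff, pct_var), `summary` (per method x metric:
#'   median/mean of both), `detection` (per method: lesions detected on both
#'   scans, total lesions)
#' @export
compare_methods <- function(stats,
                            metrics = c("volume_cm3", "suv_mean", "suv_max")) {
  stopifnot(all(c("lesion_id", "method", "scan", "detected") %in% names(stats)))
  metrics <- intersect(metrics, names(stats))

  detection <- stats |>
    dplyr::group_by(.data$method, .data$lesion_id) |>
    dplyr::summarise(both = all(c("test", "retest") %in% .data$scan) &&
                       all(.data$detected), .groups = "drop_last") |>
    dplyr::summarise(n_detected_both = sum(.data$both),
                     n_lesions = dplyr::n(), .groups = "drop")

  common <- stats |>
    dplyr::group_by(.data$lesion_id) |>
    dplyr::filter(all(.data$detected)) |>
    dplyr::ungroup()
  if (nrow(common) == 0) {
    warning("no lesions detected by all methods on both scans")
    trt <- tibble::tibble(lesion_id = character(), method = character(),
                          metric = character(), test = numeric(),
                          retest = numeric(), abs_diff = numeric(),
                          pct_var = numeric())
  } else {
    trt <- common |>
      tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
      tidyr::pivot_wider(id_cols = c("lesion_id", "method", "metric"),
                         names_from = "scan", values_from = "value") |>
      dplyr::mutate(abs_diff = abs(.data$test - .data$retest),
                    pct_var = trt_variability(.data$test, .data$retest))
  }
  summary <- trt |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_pct_var = stats::median(.data$pct_var, na.rm = TRUE),
      mean_pct_var = mean(.data$pct_var, na.rm = TRUE),
      median_abs_diff = stats::median(.data$abs_diff, na.rm = TRUE),
      mean_abs_diff = mean(.data$abs_diff, na.rm = TRUE),
      .groups = "drop"
    )
  structure(list(trt = trt, summary = summary, detection = detection),
            class = "trt_comparison")
}

#' @export
print.trt_comparison <- function(x, ...) {
  cat("<trt_comparison>\n")
  print(x$summary)
  print(x$detection)
  invisible(x)
}

#' Tidy per-lesion test-retest rows
#' @param x a `trt_comparison`
#' @param ... unused
#' @return the per-lesion TRT tibble
#' @export
tidy.trt_comparison <- function(x, ...) x$trt

#' One-row-per-method-and-metric TRT summary
#' @param x a `trt_comparison`
#' @param ... unused
#' @return the summary tibble
#' @export
glance.trt_comparison <- function(x, ...) x$summary

#' Boxplot of test-retest variability per method and metric
#' @param object a `trt_comparison`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.trt_comparison <- function(object, ...) {
  ggplot2::ggplot(object$trt,
                  ggplot2::aes(x = .data$method, y = .data$pct_var)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "test-retest variability (%)")
}
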