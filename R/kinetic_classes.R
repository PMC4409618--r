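#' Dose-normalize a time-activity curve
#'
#' Kinetic classes are stored per injected MBq so that classes derived from
#' scans with different doses are comparable; voxel TACs are normalized the
#' same way before distance computation.
#'
#' @param tac numeric TAC (activity concentration, kBq/mL)
#' @param dose_MBq injected dose, MBq, > 0
#' @return TAC divided elementwise by the dose (kBq/mL/MBq)
#' @export
dose_normalize <- function(tac, dose_MBq) {
  if (!is.numeric(dose_MBq) || length(dose_MBq) != 1 || is.na(dose_MBq) ||
      dose_MBq <= 0) {
    stop("dose must be a single positive number (MBq)", call. = FALSE)
  }
  tac / dose_MBq
}

#' Construct a kinetic class
#'
#' A kinetic class (KC) is the reference TAC of a tissue: the across-scan mean
#' dose-normalized TAC `mu` plus the per-frame standard deviation `sigma` used
#' as the weighting factor in the Mahalanobis distance.
#'
#' @param tissue tissue name
#' @param mu mean dose-normalized TAC, length N
#' @param sigma per-frame SD, length N, elementwise >= 0
#' @param schedule the `frame_schedule` the TAC is sampled on
#' @param n_scans number of scans averaged (informational)
#' @return a `kinetic_class`
#' @export
kinetic_class <- function(tissue, mu, sigma, schedule, n_scans = NA_integer_) {
  assert_schedule(schedule)
  if (length(mu) != n_frames(schedule) || length(sigma) != length(mu)) {
    stop("mu, sigma and schedule lengths must agree", call. = FALSE)
  }
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  structure(list(tissue = tissue, mu = as.numeric(mu), sigma = as.numeric(sigma),
                 schedule = schedule, n_scans = n_scans),
            class = "kinetic_class")
}

#' Construct a kinetic-class set
#'
#' An ordered collection of kinetic classes on one shared schedule. The order
#' is fixed and recorded: it is the tie-breaking order during classification.
#'
#' @param classes list of `kinetic_class` objects with unique tissue names
#' @param source provenance label (e.g. `"hammersmith"`, `"vumc_osem"`)
#' @return a `kinetic_class_set`
#' @export
kinetic_class_set <- function(classes, source = "unspecified") {
  stopifnot(length(classes) >= 1,
            all(vapply(classes, inherits, logical(1), "kinetic_class")))
  tissues <- vapply(classes, function(k) k$tissue, character(1))
  if (anyDuplicated(tissues)) stop("duplicate tissue names", call. = FALSE)
  sched <- classes[[1]]$schedule
  for (k in classes) {
    if (!schedules_equal(k$schedule, sched)) {
      stop("all classes must share one schedule", call. = FALSE)
    }
  }
  structure(list(classes = stats::setNames(classes, tissues),
                 schedule = sched, source = source),
            class = "kinetic_class_set")
}

#' @export
print.kinetic_class_set <- function(x, ...) {
  cat(sprintf("<kinetic_class_set> '%s': %d classes (%s) on %d frames\n",
              x$source, length(x$classes),
              paste(names(x$classes), collapse = ", "),
              n_frames(x$schedule)))
  invisible(x)
}

#' Tidy a kinetic-class set into a long tibble
#'
#' @param x a `kinetic_class_set`
#' @param ... unused
#' @return tibble with columns tissue, frame, mid_s, mu, sigma
#' @export
tidy.kinetic_class_set <- function(x, ...) {
  purrr::map_dfr(x$classes, function(k) {
    tibble::tibble(tissue = k$tissue, frame = k$schedule$frame,
                   mid_s = k$schedule$mid_s, mu = k$mu, sigma = k$sigma)
  })
}

#' Plot a kinetic-class set
#'
#' Mean dose-normalized TAC per tissue with a +/- 1 SD ribbon.
#'
#' @param object a `kinetic_class_set`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.kinetic_class_set <- function(object, ...) {
  df <- tidy.kinetic_class_set(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_s / 60, y = .data$mu,
                                   colour = .data$tissue, fill = .data$tissue)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mu - .data$sigma,
                                      ymax = .data$mu + .data$sigma),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time post injection (min)",
                  y = "dose-normalized activity (kBq/mL/MBq)",
                  title = sprintf("Kinetic classes (%s)", object$source))
}

#' Derive kinetic classes from a set of dynamic scans with tissue VOIs
#'
#' For every scan, the tissue TAC is extracted as the spatial mean over the
#' tissue VOI and dose-normalized; per tissue, the across-scan mean gives the
#' class TAC `mu` and the across-scan sample SD (denominator n-1) per frame
#' gives the weighting factors `sigma`.
#'
#' @param scans list of scans; each element a list with `image`
#'   (`dynamic_image`), `vois` (named list of 3D masks, one per tissue) and
#'   `dose_MBq` (defaults to the image's dose)
#' @param source provenance label for the resulting set
#' @return a `kinetic_class_set`
#' @export
derive_kinetic_classes <- function(scans, source = "derived") {
  if (length(scans) < 2) stop("need at least 2 scans", call. = FALSE)
  sched <- scans[[1]]$image$schedule
  tissues <- names(scans[[1]]$vois)
  for (s in scans) {
    if (!schedules_equal(s$image$schedule, sched)) {
      stop("all scans must share one frame schedule", call. = FALSE)
    }
    if (!setequal(names(s$vois), tissues)) {
      stop("every scan must provide a VOI for every tissue", call. = FALSE)
    }
  }
  classes <- lapply(tissues, function(tn) {
    tacs <- vapply(scans, function(s) {
      dose <- s$dose_MBq %||% s$image$dose_MBq
      dose_normalize(extract_tac(s$image, s$vois[[tn]]), dose)
    }, numeric(n_frames(sched)))           # N x n_scans
    kinetic_class(tn,
                  mu = rowMeans(tacs),
                  sigma = apply(tacs, 1, stats::sd),
                  schedule = sched, n_scans = length(scans))
  })
  kinetic_class_set(classes, source = source)
}

#' Resample a TAC onto another frame schedule
#'
#' Linear interpolation of (mid-time, value) pairs at the target schedule's
#' mid-times; target mid-times outside the source range take the nearest
#' source value (clamped extrapolation). This is how kinetic classes are
#' brought onto the schedule of the scan under analysis (or vice versa).
#'
#' @param values numeric TAC on the `from` schedule
#' @param from source `frame_schedule` (length must match `values`)
#' @param to target `frame_schedule`
#' @return numeric TAC of length `n_frames(to)`
#' @export
resample_tac <- function(values, from, to) {
  assert_schedule(from); assert_schedule(to)
  if (length(values) != n_frames(from)) {
    stop("values length does not match source schedule", call. = FALSE)
  }
  if (schedules_equal(from, to)) return(as.numeric(values))
  if (n_frames(from) == 1) return(rep(as.numeric(values), n_frames(to)))
  stats::approx(x = from$mid_s, y = values, xout = to$mid_s, method = "linear",
                rule = 2)$y
}

#' Resample a kinetic-class set onto another schedule
#'
#' `mu` and `sigma` of every class are resampled with [resample_tac()]; the
#' set's schedule is replaced by the target.
#'
#' @param kcs a `kinetic_class_set`
#' @param to target `frame_schedule`
#' @return a `kinetic_class_set` on the target schedule
#' @export
resample_class_set <- function(kcs, to) {
  stopifnot(inherits(kcs, "kinetic_class_set"))
  classes <- lapply(kcs$classes, function(k) {
    kinetic_class(k$tissue,
                  mu = resample_tac(k$mu, k$schedule, to),
                  sigma = resample_tac(k$sigma, k$schedule, to),
                  schedule = to, n_scans = k$n_scans)
  })
  kinetic_class_set(unname(classes), source = kcs$source)
}
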