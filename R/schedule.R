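#' Build a frame schedule from (count, duration) blocks
#'
#' A dynamic PET acquisition is binned into contiguous time frames of varying
#' duration. A frame schedule records, for each frame, its start time and
#' duration in seconds from injection; frame mid-times are the standard
#' abscissa for time-activity curves (TACs).
#'
#' @param blocks a data frame (or tibble) with columns `count` and
#'   `duration_s`, each row describing a run of `count` consecutive frames of
#'   `duration_s` seconds; or a list of `c(count, duration_s)` pairs.
#' @return a `frame_schedule`: a tibble with one row per frame and columns
#'   `frame` (1-based index), `start_s`, `duration_s`, `mid_s`.
#' @examples
#' sched <- make_frame_schedule(data.frame(
#'   count = c(10, 5, 5, 5, 6),
#'   duration_s = c(30, 60, 120, 180, 600)
#' ))
#' n_frames(sched)      # 31
#' total_duration_s(sched) / 60  # 95 min
#' @export
make_frame_schedule <- function(blocks) {
  if (is.list(blocks) && !is.data.frame(blocks)) {
    blocks <- do.call(rbind, lapply(blocks, function(b) {
      data.frame(count = b[[1]], duration_s = b[[2]])
    }))
  }
  if (!is.data.frame(blocks) || nrow(blocks) == 0) {
    stop("frame schedule spec is empty", call. = FALSE)
  }
  if (!all(c("count", "duration_s") %in% names(blocks))) {
    stop("blocks must have columns 'count' and 'duration_s'", call. = FALSE)
  }
  if (any(blocks$count < 1) || any(blocks$count != round(blocks$count))) {
    stop("frame counts must be positive integers", call. = FALSE)
  }
  if (any(blocks$duration_s <= 0)) {
    stop("frame durations must be positive", call. = FALSE)
  }
  durations <- rep(blocks$duration_s, times = blocks$count)
  starts <- cumsum(c(0, durations[-length(durations)]))
  new_frame_schedule(starts, durations)
}

new_frame_schedule <- function(starts, durations) {
  sched <- tibble::tibble(
    frame = seq_along(starts),
    start_s = as.numeric(starts),
    duration_s = as.numeric(durations),
    mid_s = as.numeric(starts) + as.numeric(durations) / 2
  )
  class(sched) <- c("frame_schedule", class(sched))
  sched
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d frames, total %.1f s (%.2f min)\n",
    nrow(x), total_duration_s(x), total_duration_s(x) / 60
  ))
  NextMethod()
}

#' Number of frames in a schedule
#' @param schedule a `frame_schedule`
#' @return integer frame count
#' @export
n_frames <- function(schedule) nrow(schedule)

#' Total acquisition duration in seconds
#' @param schedule a `frame_schedule`
#' @return end of the last frame, seconds from injection
#' @export
total_duration_s <- function(schedule) {
  with(schedule, start_s[nrow(schedule)] + duration_s[nrow(schedule)])
}

#' Frame mid-times in seconds
#' @param schedule a `frame_schedule`
#' @return numeric vector, length `n_frames(schedule)`
#' @export
frame_mid_s <- function(schedule) schedule$mid_s

assert_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("start_s", "duration_s", "mid_s") %in% names(schedule)))
  invisible(schedule)
}

schedules_equal <- function(a, b) {
  nrow(a) == nrow(b) &&
    isTRUE(all.equal(a$start_s, b$start_s)) &&
    isTRUE(all.equal(a$duration_s, b$duration_s))
}

#' Built-in published frame schedules
#'
#' Three acquisition protocols used in dynamic FLT-PET work, as frame
#' schedules:
#' \describe{
#'   \item{hammersmith_31}{95-min scan, 31 frames:
#'     10x30, 5x60, 5x120, 5x180, 6x600 s.}
#'   \item{vumc_dev_40}{60.5-min scan, 40 frames: a 30-s pre-injection frame
#'     then 6x5, 6x10, 3x20, 5x30, 5x60, 8x150, 6x300 s.}
#'   \item{vumc_trt_39}{60-min test-retest scan, 39 frames:
#'     6x5, 6x10, 3x20, 5x30, 5x60, 8x150, 6x300 s.}
#' }
#' @return named list of `frame_schedule` objects
#' @export
builtin_schedules <- function() {
  spec <- function(counts, durs) {
    make_frame_schedule(data.frame(count = counts, duration_s = durs))
  }
  list(
    hammersmith_31 = spec(c(10, 5, 5, 5, 6), c(30, 60, 120, 180, 600)),
    vumc_dev_40 = spec(c(1, 6, 6, 3, 5, 5, 8, 6), c(30, 5, 10, 20, 30, 60, 150, 300)),
    vumc_trt_39 = spec(c(6, 6, 3, 5, 5, 8, 6), c(5, 10, 20, 30, 60, 150, 300))
  )
}

#' Select frame indices whose mid-time falls in a time window
#'
#' Used to restrict Mahalanobis classification to a sub-interval of the scan;
#' frames outside the window are disregarded. The same index subset must be
#' applied to voxel TACs and class TACs.
#'
#' @param schedule a `frame_schedule`
#' @param window `c(t0, t1)` in minutes post injection, `t0 < t1`
#' @return integer vector of frame indices with mid-time in `[t0, t1]`
#' @export
restrict_time_window <- function(schedule, window) {
  assert_schedule(schedule)
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(t0, t1) in minutes with t0 < t1", call. = FALSE)
  }
  mid_min <- schedule$mid_s / 60
  idx <- which(mid_min >= window[1] & mid_min <= window[2])
  if (length(idx) == 0) {
    stop(sprintf("no frame mid-times within window [%g, %g] min",
                 window[1], window[2]), call. = FALSE)
  }
  idx
}
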