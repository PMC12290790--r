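#' Frame schedule of a dynamic PET measurement
#'
#' Constructs the frame timing of a dynamic scan: frame start times and
#' durations in minutes. Frames must be contiguous (each frame starts where
#' the previous one ends) and non-overlapping, with strictly positive
#' durations.
#'
#' @param start Numeric vector of frame start times (minutes).
#' @param dur Numeric vector of frame durations (minutes).
#' @return An object of class `frame_schedule` with elements `start`, `dur`,
#'   `mid` (frame mid-times) and `end`.
#' @export
frame_schedule <- function(start, dur) {
  stopifnot(length(start) == length(dur), length(start) >= 1)
  if (any(!is.finite(start)) || any(!is.finite(dur))) {
    stop("frame times must be finite")
  }
  if (any(dur <= 0)) stop("frame durations must be positive")
  if (length(start) > 1) {
    gaps <- start[-1] - (start[-length(start)] + dur[-length(dur)])
    if (any(abs(gaps) > 1e-8)) {
      stop("frames must be contiguous and non-overlapping")
    }
  }
  structure(
    list(start = as.numeric(start), dur = as.numeric(dur),
         mid = as.numeric(start + dur / 2), end = as.numeric(start + dur)),
    class = "frame_schedule"
  )
}

#' Default 20-frame, 110-minute schedule
#'
#' The acquisition schedule used throughout the package: 3 frames of 20 s,
#' 3 of 1 min, 3 of 2 min, 2 of 5 min and 9 of 10 min, totalling 110
#' minutes over 20 frames.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(1 / 3, 3), rep(1, 3), rep(2, 3), rep(5, 2), rep(10, 9))
  start <- cumsum(c(0, dur[-length(dur)]))
  frame_schedule(start, dur)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.4g min total\n",
              length(x$dur), sum(x$dur)))
  invisible(x)
}

n_frames <- function(schedule) length(schedule$dur)
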