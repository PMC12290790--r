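#' Arterial input container
#'
#' Bundles the continuous-time metabolite-corrected parent plasma curve, the
#' whole-plasma curve (used as the whole-blood proxy for the blood-volume
#' term) and the plasma-free fraction of one subject. Both curves are
#' functions evaluable at any non-negative time (minutes) returning kBq/mL,
#' zero before injection onset.
#'
#' @param cp_parent Function of time: metabolite-corrected plasma activity.
#' @param c_wholeplasma Function of time: whole-plasma activity.
#' @param fP Plasma-free fraction in (0, 1].
#' @return An object of class `arterial_input`.
#' @export
arterial_input <- function(cp_parent, c_wholeplasma, fP = NA_real_) {
  stopifnot(is.function(cp_parent), is.function(c_wholeplasma))
  if (!is.na(fP) && (fP <= 0 || fP > 1)) stop("fP must be in (0, 1]")
  structure(list(cp_parent = cp_parent, c_wholeplasma = c_wholeplasma,
                 fP = fP),
            class = "arterial_input")
}

#' Validated arterial blood sample table
#'
#' @param sample_times Minutes post injection, strictly increasing.
#' @param whole_plasma Whole-plasma activity (kBq/mL), non-negative.
#' @param parent_fraction Fraction of plasma activity that is unmetabolised
#'   parent compound, in \[0, 1\].
#' @return A `blood_data` object (data frame).
#' @export
blood_data <- function(sample_times, whole_plasma, parent_fraction) {
  n <- length(sample_times)
  stopifnot(length(whole_plasma) == n, length(parent_fraction) == n)
  d <- diff(sample_times)
  if (any(d <= 0)) {
    stop(sprintf("sample times must be strictly increasing (first violation at row %d)",
                 which(d <= 0)[1] + 1))
  }
  if (any(whole_plasma < 0)) stop("whole-plasma activity must be non-negative")
  if (any(parent_fraction < 0 | parent_fraction > 1)) {
    stop("parent fraction must lie in [0, 1]")
  }
  structure(data.frame(sample_times = sample_times,
                       whole_plasma = whole_plasma,
                       parent_fraction = parent_fraction),
            class = c("blood_data", "data.frame"))
}

# Interpolator for a sampled blood curve: linear up to the peak sample,
# log-linear after the peak (activity decays roughly exponentially), and
# constant beyond the last sample (with a warning the first time the
# curve is evaluated there). Zero before the first sample time ramps
# linearly from 0 at t = 0.
blood_interp <- function(times, values, label = "blood curve") {
  ipk <- which.max(values)
  tpk <- times[ipk]
  pos <- pmax(values, 1e-12)
  warned <- new.env(parent = emptyenv())
  warned$yes <- FALSE
  tmax <- times[length(times)]
  vmax <- values[length(values)]
  force(label)
  function(t) {
    out <- numeric(length(t))
    pre <- t <= 0
    beyond <- t > tmax
    if (any(beyond) && !warned$yes) {
      warned$yes <- TRUE
      warning(sprintf("%s evaluated beyond last sample (%.3g min); using constant extrapolation",
                      label, tmax), call. = FALSE)
    }
    early <- !pre & t <= tpk
    late <- !pre & t > tpk & !beyond
    if (any(early)) {
      out[early] <- approx(c(0, times[seq_len(ipk)]),
                           c(0, values[seq_len(ipk)]),
                           xout = t[early], rule = 2)$y
    }
    if (any(late)) {
      out[late] <- exp(approx(times[ipk:length(times)],
                              log(pos[ipk:length(times)]),
                              xout = t[late], rule = 2)$y)
      out[late][values[ipk] == 0] <- 0
    }
    out[beyond] <- vmax
    out
  }
}

#' Build an arterial input from a blood sample table
#'
#' Metabolite-corrected parent plasma is `whole_plasma * parent_fraction` at
#' the samples; both it and the whole-plasma curve are interpolated linearly
#' before the peak and log-linearly after it, with constant extrapolation
#' beyond the last sample.
#'
#' @param blood A [blood_data()] table.
#' @param fP Plasma-free fraction in (0, 1].
#' @return An [arterial_input()].
#' @export
arterial_input_from_blood <- function(blood, fP = NA_real_) {
  stopifnot(inherits(blood, "blood_data"))
  cp <- blood$whole_plasma * blood$parent_fraction
  arterial_input(
    cp_parent = blood_interp(blood$sample_times, cp, "parent plasma"),
    c_wholeplasma = blood_interp(blood$sample_times, blood$whole_plasma,
                                 "whole plasma"),
    fP = fP
  )
}
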