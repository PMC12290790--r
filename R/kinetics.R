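#' Time-activity curve container
#'
#' @param subject_id Subject identifier.
#' @param region Region identifier.
#' @param schedule A [frame_schedule()].
#' @param activity Decay-corrected frame activity (kBq/mL), one per frame.
#' @param weights Optional non-negative per-frame weights.
#' @return An object of class `tac`.
#' @export
tac <- function(subject_id, region, schedule, activity, weights = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(activity) != n_frames(schedule)) {
    stop("activity length must equal frame count")
  }
  if (any(!is.finite(activity))) stop("activity must be finite")
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(activity), all(weights >= 0))
  }
  structure(list(subject_id = subject_id, region = region,
                 schedule = schedule, activity = as.numeric(activity),
                 weights = weights),
            class = "tac")
}

#' Two-tissue compartment model rate constants
#'
#' @param K1 Plasma-to-tissue transfer (mL/cm^3/min), `K1 >= 0`.
#' @param k2,k3,k4 Tissue rate constants (1/min), non-negative (`k2`, `k4`
#'   positive for a well-defined model; `K1 = 0` and `k3 = 0` are permitted
#'   degenerate cases).
#' @param vB Blood-volume fraction in \[0, 1).
#' @return A `tcm2_params` list.
#' @export
tcm2_params <- function(K1, k2, k3, k4, vB = 0.05) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rate constants must be finite and non-negative")
  }
  if (vB < 0 || vB >= 1) stop("vB must be in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "tcm2_params")
}

#' Simplified reference tissue model parameters
#'
#' @param R1 Relative delivery target/reference, `R1 > 0`.
#' @param k2prime Reference-region efflux rate (1/min), `> 0`.
#' @param BPND Binding potential relative to non-displaceable uptake,
#'   `> -1`.
#' @return An `srtm_params` list with derived `k2 = R1 * k2prime` and
#'   `k2a = k2 / (1 + BPND)`.
#' @export
srtm_params <- function(R1, k2prime, BPND) {
  stopifnot(R1 > 0, k2prime > 0, BPND > -1)
  k2 <- R1 * k2prime
  structure(list(R1 = R1, k2prime = k2prime, BPND = BPND, k2 = k2,
                 k2a = k2 / (1 + BPND)),
            class = "srtm_params")
}

# Evaluate the input curves on the uniform model grid covering the scan.
input_grids <- function(input, schedule, dt) {
  tmax <- max(schedule$end)
  tg <- seq(0, tmax, by = dt)
  if (tg[length(tg)] < tmax - 1e-9) tg <- c(tg, tmax)
  list(t = tg, cp = pmax(input$cp_parent(tg), 0),
       wb = pmax(input$c_wholeplasma(tg), 0), dt = dt)
}

#' Analytic 2TCM forward model, frame-averaged
#'
#' Solves the two-tissue compartment model
#' `C(t) = (1 - vB) * C_tissue(t) + vB * C_wholeplasma(t)` analytically
#' (bi-exponential convolution of the parent plasma input) and returns the
#' time-average of the continuous solution over each frame. When
#' `scale_input_by_fp` is set, the tissue compartments are driven by
#' `fP * cp_parent` (the free-ligand input); the blood-volume term always
#' uses the unscaled whole-plasma curve.
#'
#' @param params A [tcm2_params()].
#' @param input An [arterial_input()] covering the scan window.
#' @param schedule A [frame_schedule()].
#' @param scale_input_by_fp Scale the tissue input by the plasma-free
#'   fraction (requires `fP` on `input`).
#' @param dt Model grid spacing (minutes) for the piecewise-linear input
#'   representation.
#' @param subject_id,region Labels for the returned curve.
#' @return A [tac()] with the model frame values.
#' @export
solve_2tcm <- function(params, input, schedule, scale_input_by_fp = FALSE,
                       dt = 1 / 960, subject_id = "model",
                       region = "model") {
  stopifnot(inherits(params, "tcm2_params"),
            inherits(input, "arterial_input"))
  disc <- (params$k2 + params$k3 + params$k4)^2 - 4 * params$k2 * params$k4
  if (disc < -1e-12) stop("negative 2TCM discriminant")
  g <- input_grids(input, schedule, dt)
  cp <- g$cp
  if (scale_input_by_fp) {
    if (is.na(input$fP)) stop("scale_input_by_fp requires fP on the input")
    cp <- cp * input$fP
  }
  curve <- tcm2_curve_cpp(params$K1, params$k2, params$k3, params$k4,
                          params$vB, cp, g$wb, g$dt)
  act <- frame_avg_cpp(curve, g$dt, schedule$start, schedule$dur)
  tac(subject_id, region, schedule, act)
}

#' Analytic SRTM forward model, frame-averaged
#'
#' `C(t) = R1 * Cr(t) + (k2 - R1 * k2a) * [Cr (x) exp(-k2a t)](t)` with
#' `k2 = R1 * k2prime` and `k2a = k2 / (1 + BPND)`, frame-averaged over the
#' schedule.
#'
#' @param params An [srtm_params()].
#' @param ref_tac Continuous reference-region curve: a function of time, or
#'   a [tac()] (interpolated at frame mid-times).
#' @param schedule A [frame_schedule()].
#' @param dt Model grid spacing (minutes).
#' @inheritParams solve_2tcm
#' @return A [tac()].
#' @export
solve_srtm <- function(params, ref_tac, schedule, dt = 1 / 960,
                       subject_id = "model", region = "model") {
  stopifnot(inherits(params, "srtm_params"))
  if (params$k2a <= 0) stop("nonpositive k2a")
  ref_fun <- as_ref_fun(ref_tac)
  tmax <- max(schedule$end)
  tg <- seq(0, tmax, by = dt)
  if (tg[length(tg)] < tmax - 1e-9) tg <- c(tg, tmax)
  refg <- pmax(ref_fun(tg), 0)
  act <- srtm_frames_cpp(params$R1, params$k2prime, params$BPND, refg, dt,
                         schedule$start, schedule$dur)
  tac(subject_id, region, schedule, act)
}

# Reference curve as a function of time; measured reference TACs are
# interpolated linearly through (0, 0) and the frame mid-times.
as_ref_fun <- function(ref) {
  if (is.function(ref)) return(ref)
  if (inherits(ref, "tac")) {
    tt <- c(0, ref$schedule$mid)
    vv <- c(0, ref$activity)
    return(function(t) approx(tt, vv, xout = t, rule = 2)$y)
  }
  stop("ref_tac must be a function or a tac")
}

#' Outcome measures from 2TCM rate constants
#'
#' `BPND = k3/k4`, `VND = K1/k2`, `BPP = BPND * VND`, `VT = VND + BPP`, and
#' `BPF = BPP / fP` when the plasma-free fraction is supplied.
#'
#' @param params A [tcm2_params()] with positive rates.
#' @param fP Optional plasma-free fraction, `> 0`.
#' @return A named list of class `outcome_set` (`BPF` is `NA` without
#'   `fP`).
#' @export
outcomes_from_rates <- function(params, fP = NULL) {
  stopifnot(inherits(params, "tcm2_params"))
  if (params$k2 <= 0 || params$k4 <= 0) stop("k2 and k4 must be positive")
  if (!is.null(fP) && fP <= 0) stop("fP must be positive when supplied")
  BPND <- params$k3 / params$k4
  VND <- params$K1 / params$k2
  BPP <- BPND * VND
  structure(list(BPND = BPND, VND = VND, BPP = BPP, VT = VND + BPP,
                 BPF = if (is.null(fP)) NA_real_ else BPP / fP),
            class = "outcome_set")
}

#' Remove the decay correction from a TAC
#'
#' Stored activities are decay-corrected to injection time; this multiplies
#' each frame by `exp(-log(2) * t_mid / half_life)` using the frame
#' mid-times, recovering the activity actually measured.
#'
#' @param tac A [tac()].
#' @param half_life Isotope half-life in minutes (default: carbon-11,
#'   20.364 min).
#' @return Numeric vector of uncorrected frame activities.
#' @export
decay_uncorrect <- function(tac, half_life = 20.364) {
  stopifnot(inherits(tac, "tac"), half_life > 0)
  tac$activity * exp(-log(2) * tac$schedule$mid / half_life)
}

#' Frame weights for weighted NLS
#'
#' `w_i = sqrt(duration_i * uncorrected_activity_i)` where the uncorrected
#' activity is the frame value after removing the decay correction
#' (negative frames are floored at zero before the square root). Weights
#' are normalized to mean 1 across the curve. An all-zero curve yields
#' uniform weights with a warning.
#'
#' @param schedule A [frame_schedule()] (taken from `tac` if missing).
#' @param tac A [tac()].
#' @param half_life Isotope half-life in minutes.
#' @return Numeric vector of weights with mean 1.
#' @export
compute_weights <- function(schedule = NULL, tac, half_life = 20.364) {
  schedule <- schedule %||% tac$schedule
  uncorr <- pmax(decay_uncorrect(tac, half_life), 0)
  w <- sqrt(schedule$dur * uncorr)
  if (all(w == 0)) {
    warning("all-zero TAC: using uniform weights")
    return(rep(1, length(w)))
  }
  w / mean(w)
}
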