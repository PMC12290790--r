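test_that("default schedule has 20 contiguous frames over 110 min", {
  s <- default_frame_schedule()
  expect_length(s$dur, 20)
  expect_equal(sum(s$dur), 110)
  expect_equal(s$start[-1], (s$start + s$dur)[-20])
  expect_error(frame_schedule(c(0, 1), c(2, 1)), "contiguous")
  expect_error(frame_schedule(0, -1), "positive")
})

test_that("2TCM collapses correctly in degenerate cases", {
  s <- default_frame_schedule()
  inp <- smooth_input()
  # no tissue uptake: curve is vB times frame-averaged whole plasma
  p0 <- tcm2_params(K1 = 0, k2 = 0.2, k3 = 0.05, k4 = 0.03, vB = 0.05)
  out <- solve_2tcm(p0, inp, s, dt = 1 / 480)
  wb_only <- fravg(pmax(inp$c_wholeplasma(seq(0, 110, 1 / 480)), 0),
                   1 / 480, s$start, s$dur)
  expect_equal(out$activity, 0.05 * wb_only, tolerance = 1e-10)
  # k3 = 0: one-tissue solution
  p1 <- tcm2_params(K1 = 0.3, k2 = 0.15, k3 = 0, k4 = 0.03, vB = 0)
  one_tc <- solve_2tcm(p1, inp, s)
  oracle <- ode_2tcm_frames(p1, inp$cp_parent, inp$c_wholeplasma, s)
  expect_equal(one_tc$activity, oracle, tolerance = 1e-6)
})

test_that("analytic 2TCM matches ODE oracle over random parameter sets", {
  s <- default_frame_schedule()
  inp <- smooth_input()
  set.seed(101)
  worst <- 0
  for (i in 1:12) {
    p <- tcm2_params(K1 = runif(1, 0.05, 0.5), k2 = runif(1, 0.05, 0.4),
                     k3 = runif(1, 0.01, 0.3), k4 = runif(1, 0.01, 0.1),
                     vB = runif(1, 0, 0.1))
    mod <- solve_2tcm(p, inp, s)$activity
    oracle <- ode_2tcm_frames(p, inp$cp_parent, inp$c_wholeplasma, s)
    worst <- max(worst, max(abs(mod - oracle) / abs(oracle)))
  }
  expect_lt(worst, 1e-6)
})

test_that("SRTM matches convolution oracle and collapses for R1=1, BPND=0", {
  s <- default_frame_schedule()
  ref <- function(t) t * exp(-0.2 * t)
  p <- srtm_params(R1 = 0.9, k2prime = 0.15, BPND = 2)
  mod <- solve_srtm(p, ref, s)$activity
  oracle <- conv_srtm_frames(p, ref, s)
  expect_lt(max(abs(mod - oracle) / abs(oracle)), 1e-6)
  # identity collapse: R1 = 1, BPND = 0 gives back the reference curve
  pid <- srtm_params(R1 = 1, k2prime = 0.15, BPND = 0)
  out <- solve_srtm(pid, ref, s, dt = 1 / 480)$activity
  ref_frames <- fravg(ref(seq(0, 110, 1 / 480)), 1 / 480, s$start,
                      s$dur)
  expect_equal(out, ref_frames, tolerance = 1e-10)
})

test_that("input scaling maps K1 and VND but leaves BPND, k4, vB", {
  s <- default_frame_schedule()
  inp <- smooth_input()
  p <- tcm2_params(K1 = 0.12, k2 = 0.2, k3 = 0.12, k4 = 0.04, vB = 0.05)
  base <- solve_2tcm(p, inp, s, dt = 1 / 30)
  scaled <- solve_2tcm(p, inp, s, scale_input_by_fp = TRUE, dt = 1 / 30)
  f1 <- fit_2tcm_nls(base, inp, "bpnd", dt = 1 / 30)
  cs <- 0.5   # constant input rescaling
  inp2 <- arterial_input(function(t) inp$cp_parent(t) * cs,
                         inp$c_wholeplasma, fP = inp$fP)
  f2 <- fit_2tcm_nls(base, inp2, "bpnd", dt = 1 / 30)
  # tissue term linear in input: K1 and VND rescale by 1/c
  expect_equal(unname(f2$estimate_log[1] - f1$estimate_log[1]),
               -log(cs), tolerance = 1e-3)
  expect_equal(unname(f2$estimate_log[2] - f1$estimate_log[2]),
               -log(cs), tolerance = 1e-3)
  expect_equal(unname(f2$estimate_log[3:5]),
               unname(f1$estimate_log[3:5]), tolerance = 1e-3)
  # the vB term is never scaled by fP
  wb_frames <- fravg(pmax(inp$c_wholeplasma(seq(0, 110, 1 / 30)), 0),
                     1 / 30, s$start, s$dur)
  expect_equal(scaled$activity,
               inp$fP * (base$activity - 0.05 * wb_frames) +
                 0.05 * wb_frames,
               tolerance = 1e-6)
})

test_that("frame averaging approaches point evaluation for short frames", {
  inp <- smooth_input()
  p <- tcm2_params(K1 = 0.2, k2 = 0.2, k3 = 0.08, k4 = 0.04, vB = 0.03)
  t0 <- 30
  point <- tcm2_curve_cpp(p$K1, p$k2, p$k3, p$k4, p$vB,
                          pmax(inp$cp_parent(seq(0, 40, 1 / 480)), 0),
                          pmax(inp$c_wholeplasma(seq(0, 40, 1 / 480)), 0),
                          1 / 480)[t0 * 480 + 1]
  for (d in c(1, 0.1, 0.01)) {
    s <- frame_schedule(c(0, t0 - d / 2), c(t0 - d / 2, d))
    avg <- solve_2tcm(p, inp, s)$activity[2]
    expect_equal(avg, point, tolerance = d^2)
  }
})

test_that("outcome algebra satisfies its defining identities", {
  p <- tcm2_params(K1 = 0.1, k2 = 0.05, k3 = 0.02, k4 = 0.01)
  o <- outcomes_from_rates(p, fP = 0.08)
  expect_equal(o$BPND, 2)
  expect_equal(o$VND, 2)
  expect_equal(o$BPP, 4)
  expect_equal(o$VT, 6)
  expect_equal(o$BPF, 50)
  expect_error(outcomes_from_rates(p, fP = -1), "positive")
  set.seed(7)
  for (i in 1:20) {
    r <- exp(rnorm(4, -2, 1))
    p <- tcm2_params(r[1], r[2], r[3], r[4], vB = 0.05)
    o <- outcomes_from_rates(p)
    expect_equal(o$BPP, o$BPND * o$VND)
    expect_equal(o$VT, o$VND + o$BPP)
  }
})

test_that("decay un-correction halves activity per half-life", {
  hl <- 20.364
  s <- frame_schedule(c(0, 2 * hl), c(2 * hl, 2 * hl))  # mids: hl, 3*hl
  x <- tac("s", "r", s, c(8, 8))
  u <- decay_uncorrect(x, hl)
  expect_equal(u, c(4, 1), tolerance = 1e-12)
  s0 <- frame_schedule(0, 1e-9)
  expect_equal(decay_uncorrect(tac("s", "r", s0, 8), hl), 8,
               tolerance = 1e-9)
})

test_that("weights follow sqrt(duration x uncorrected activity), mean one", {
  s <- default_frame_schedule()
  # constant uncorrected activity: weights differ only via durations
  act <- 3 / exp(-log(2) * s$mid / 20.364)
  x <- tac("s", "r", s, act)
  w <- compute_weights(s, x)
  expect_equal(mean(w), 1)
  expect_equal(w / w[1], sqrt(s$dur / s$dur[1]), tolerance = 1e-12)
  # doubling one duration at fixed activity scales that weight by sqrt(2)
  s2 <- frame_schedule(c(0, 1), c(1, 2))
  hl <- 20.364
  a2 <- c(5, 5) / exp(-log(2) * s2$mid / hl)
  w2 <- compute_weights(s2, tac("s", "r", s2, a2))
  expect_equal(w2[2] / w2[1], sqrt(2), tolerance = 1e-12)
  # independent element-wise re-evaluation on a realistic simulated TAC
  st <- tiny_cohort(seed = 3, n = c(1, 1, 1), regions = "ACC")
  y <- st$tacs$activity[1:20]
  xt <- tac("a", "ACC", st$schedule, y)
  uncorr <- pmax(y * exp(-log(2) * st$schedule$mid / 20.364), 0)
  w_ref <- sqrt(st$schedule$dur * uncorr)
  w_ref <- w_ref / mean(w_ref)
  expect_equal(compute_weights(st$schedule, xt), w_ref)
  expect_warning(compute_weights(s2, tac("s", "r", s2, c(0, 0))),
                 "all-zero")
})

test_that("blood tables are validated and interpolated as documented", {
  expect_error(blood_data(c(1, 1, 2), c(1, 1, 1), c(1, 1, 1)),
               "strictly increasing")
  expect_error(blood_data(c(1, 2), c(-1, 1), c(1, 1)), "non-negative")
  expect_error(blood_data(c(1, 2), c(1, 1), c(1, 1.2)), "\\[0, 1\\]")
  bd <- blood_data(c(0.5, 1, 2, 4, 8), c(1, 10, 6, 3, 1.2),
                   c(1, 0.95, 0.8, 0.6, 0.4))
  ai <- arterial_input_from_blood(bd, fP = 0.07)
  # linear before the peak
  expect_equal(ai$c_wholeplasma(0.75), (1 + 10) / 2)
  # log-linear after the peak
  expect_equal(ai$c_wholeplasma(1.5), exp(mean(log(c(10, 6)))))
  # parent plasma = whole plasma x parent fraction at samples
  expect_equal(ai$cp_parent(2), 6 * 0.8, tolerance = 1e-12)
  # constant extrapolation beyond the last sample warns once
  expect_warning(v <- ai$c_wholeplasma(10), "constant extrapolation")
  expect_equal(v, 1.2)
})
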