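# Shared fixtures: small deterministic inputs built in code.

smooth_input <- function(decay = 0.1) {
  arterial_input(cp_parent = function(t) exp(-decay * t),
                 c_wholeplasma = function(t) 1.4 * exp(-decay * 0.8 * t),
                 fP = 0.07)
}

# frame averages of a continuous model curve via a high-resolution ODE
# solution of the 2TCM state equations (independent oracle)
ode_2tcm_frames <- function(params, cp_fun, wb_fun, schedule,
                            tol = 1e-12) {
  rhs <- function(t, y, parms) {
    cp <- cp_fun(t)
    list(c(params$K1 * cp - (params$k2 + params$k3) * y[1] +
             params$k4 * y[2],
           params$k3 * y[1] - params$k4 * y[2],
           (1 - params$vB) * (y[1] + y[2]) + params$vB * wb_fun(t)))
  }
  tout <- sort(unique(c(0, schedule$start, schedule$end)))
  sol <- deSolve::ode(c(0, 0, 0), tout, rhs, NULL, method = "lsoda",
                      atol = tol, rtol = tol)
  Fint <- sol[, 4]
  idx_a <- match(schedule$start, tout)
  idx_b <- match(schedule$end, tout)
  (Fint[idx_b] - Fint[idx_a]) / schedule$dur
}

fravg <- function(...) as.vector(frame_avg_cpp(...))

# frame averages of the SRTM solution via fine-grid trapezoid convolution
# (independent oracle); dt chosen so frame boundaries fall on grid nodes
conv_srtm_frames <- function(params, ref_fun, schedule, dt = 1 / 1500) {
  tg <- seq(0, max(schedule$end), by = dt)
  refg <- ref_fun(tg)
  k2 <- params$R1 * params$k2prime
  k2a <- k2 / (1 + params$BPND)
  E <- exp(-k2a * dt)
  I <- numeric(length(tg))
  for (i in 2:length(tg)) {
    I[i] <- I[i - 1] * E + 0.5 * dt * (refg[i] + refg[i - 1] * E)
  }
  crv <- params$R1 * refg + (k2 - params$R1 * k2a) * I
  Fc <- cumsum(c(0, 0.5 * dt * (crv[-1] + crv[-length(crv)])))
  Fat <- approxfun(tg, Fc)
  (Fat(schedule$end) - Fat(schedule$start)) / schedule$dur
}

tiny_cohort <- function(seed = 42, n = c(4, 4, 4),
                        regions = c("ACC", "HIP", "RN"), ...) {
  simulate_cohort(cohort_config(n_hv = n[1], n_nrm = n[2], n_ae = n[3],
                                regions = regions, ...), seed = seed)
}

fast_mcmc <- function(seed = 1, chains = 2, warmup = 250, iter = 250) {
  mcmc_control(chains = chains, warmup = warmup, iter = iter, seed = seed)
}

rmvnorm_chol_test <- function(n, mean, sigma) {
  drop(mean + t(chol(sigma)) %*% rnorm(length(mean)))
}
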