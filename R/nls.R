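#' @name nls_fit
#' @title Conventional per-TAC weighted nonlinear least squares
#' @description Per-curve quantification by weighted NLS on the natural-log
#'   scale of the model parameters, used both as the conventional comparator
#'   method and as the input stage for the multivariate analysis of
#'   pre-estimated parameters. Optimization uses bounded Levenberg-Marquardt
#'   with multiple jittered starts; the best residual sum of squares wins,
#'   ties broken toward the smaller binding potential.
NULL

# Box bounds on the log parameters: rates in [1e-4, 5], vB in
# [1e-4, 0.3]. Product parameters (BPP) and the fP-scaled bpf set get
# correspondingly wider upper bounds.
nls_bounds <- function(n_par, variant = "bpnd", fp = NA) {
  lower <- rep(log(1e-4), n_par)
  upper <- rep(log(5), n_par)
  if (n_par == 5) {
    upper[5] <- log(0.3)   # vB
    if (variant == "bpp") upper[3] <- log(25)
    if (variant == "bpf") {
      upper[1:2] <- upper[1:2] - log(fp)
      upper[3] <- log(25) - log(fp)
    }
  }
  list(lower = lower, upper = upper)
}

variant_code <- function(variant) {
  switch(variant, bpnd = 1L, bpp = 2L, bpf = 2L,
         stop("unknown variant: ", variant))
}

# Data-driven start: early-frame uptake for K1, late tissue-to-plasma AUC
# ratio for the distribution volume.
tcm2_init <- function(y, schedule, gcp) {
  tm <- schedule$mid
  auc_y <- sum(y * schedule$dur)
  auc_cp <- sum(gcp$cp[-1] * gcp$dt)
  early <- schedule$end <= 3
  cp_early <- sum(gcp$cp[gcp$t <= 3] * gcp$dt)
  K1 <- if (any(early) && cp_early > 0) {
    max(1e-3, sum(y[early] * schedule$dur[early]) / (3 * cp_early) * 3)
  } else 0.1
  VT <- if (auc_cp > 0) max(0.2, auc_y / auc_cp) else 2
  VND <- max(0.1, 0.25 * VT)
  BP <- max(0.3, VT / VND - 1)
  c(log(min(K1, 2)), log(min(VND, 4)), log(min(BP, 4)), log(0.04),
    log(0.05))
}

run_nlslm <- function(start, resid_fun, bounds) {
  minpack.lm::nls.lm(
    par = pmin(pmax(start, bounds$lower + 1e-6), bounds$upper - 1e-6),
    fn = resid_fun, lower = bounds$lower, upper = bounds$upper,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)
  )
}

multistart_fit <- function(init, resid_fun, bounds, n_starts, jitter_sd,
                           bp_index) {
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) init else init + rnorm(length(init), 0, jitter_sd)
    fit <- tryCatch(run_nlslm(start, resid_fun, bounds),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$deviance < best$deviance - 1e-12 ||
        (abs(fit$deviance - best$deviance) <= 1e-12 &&
         fit$par[bp_index] < best$par[bp_index])) {
      best <- fit
    }
  }
  best
}

nls_result <- function(fit, par_names, y) {
  if (is.null(fit) || all(y == 0)) {
    return(structure(list(
      estimate_log = setNames(rep(NA_real_, length(par_names)), par_names),
      se_log = setNames(rep(NA_real_, length(par_names)), par_names),
      rss = NA_real_, converged = FALSE), class = "nls_result"))
  }
  est <- setNames(fit$par, par_names)
  se <- tryCatch({
    sm <- summary(fit)
    setNames(sm$coefficients[, "Std. Error"], par_names)
  }, error = function(e) setNames(rep(NA_real_, length(par_names)),
                                  par_names))
  conv <- fit$info %in% 1:4 && all(is.finite(est))
  structure(list(estimate_log = est, se_log = se, rss = fit$deviance,
                 converged = conv),
            class = "nls_result")
}

#' Weighted NLS fit of the 2TCM to one TAC
#'
#' Fits the five log-parameters `log K1`, `log VND`, `log BP`, `log k4`,
#' `log vB`, where the binding-potential parameter is `BPND` (`variant =
#' "bpnd"`), `BPP` (`"bpp"`), or `BPF` (`"bpf"`, fitted against the
#' fP-scaled free-ligand input so that the fitted transfer parameters are
#' `K1/fP` and `VND/fP`).
#'
#' @param tac A [tac()].
#' @param input An [arterial_input()]; `variant = "bpf"` requires `fP`.
#' @param variant One of `"bpnd"`, `"bpp"`, `"bpf"`.
#' @param weights Per-frame weights (default [compute_weights()]).
#' @param init Optional start for the log-parameter vector.
#' @param n_starts Number of multi-start runs (first unjittered).
#' @param jitter_sd SD of the start jitter on the log scale.
#' @param dt Model grid spacing.
#' @return An `nls_result`: log-scale estimates and standard errors,
#'   residual sum of squares, convergence flag. Non-convergence is flagged,
#'   never thrown.
#' @export
fit_2tcm_nls <- function(tac, input, variant = c("bpnd", "bpp", "bpf"),
                         weights = NULL, init = NULL, n_starts = 5,
                         jitter_sd = 0.3, dt = 1 / 30) {
  variant <- match.arg(variant)
  stopifnot(inherits(tac, "tac"), inherits(input, "arterial_input"))
  if (variant == "bpf" && is.na(input$fP)) {
    stop("variant 'bpf' requires fP on the input")
  }
  schedule <- tac$schedule
  w <- weights %||% tac$weights %||% compute_weights(schedule, tac)
  g <- input_grids(input, schedule, dt)
  cp <- if (variant == "bpf") g$cp * input$fP else g$cp
  vcode <- variant_code(variant)
  y <- tac$activity
  resid_fun <- function(theta) {
    w * (y - tcm2_frames_cpp(exp(theta), vcode, cp, g$wb, g$dt,
                             schedule$start, schedule$dur))
  }
  par_names <- c("logK1", "logVND",
                 switch(variant, bpnd = "logBPND", bpp = "logBPP",
                        bpf = "logBPF"),
                 "logk4", "logvB")
  if (all(y == 0)) return(nls_result(NULL, par_names, y))
  init <- init %||% tcm2_init(y, schedule, list(cp = cp, t = g$t, dt = g$dt))
  fit <- multistart_fit(init, resid_fun,
                        nls_bounds(5, variant, input$fP), n_starts,
                        jitter_sd, bp_index = 3)
  nls_result(fit, par_names, y)
}

#' Weighted NLS fit of SRTM to one TAC
#'
#' Fits `log R1`, `log k2prime`, `log BPND` against a reference-region
#' curve.
#'
#' @inheritParams fit_2tcm_nls
#' @param ref_tac Reference-region curve: function of time or a [tac()].
#' @return An `nls_result`.
#' @export
fit_srtm_nls <- function(tac, ref_tac, weights = NULL, init = NULL,
                         n_starts = 5, jitter_sd = 0.3, dt = 1 / 30) {
  stopifnot(inherits(tac, "tac"))
  schedule <- tac$schedule
  w <- weights %||% tac$weights %||% compute_weights(schedule, tac)
  ref_fun <- as_ref_fun(ref_tac)
  tmax <- max(schedule$end)
  tg <- seq(0, tmax, by = dt)
  if (tg[length(tg)] < tmax - 1e-9) tg <- c(tg, tmax)
  refg <- pmax(ref_fun(tg), 0)
  y <- tac$activity
  resid_fun <- function(theta) {
    p <- exp(theta)
    w * (y - srtm_frames_cpp(p[1], p[2], p[3], refg, dt, schedule$start,
                             schedule$dur))
  }
  par_names <- c("logR1", "logk2prime", "logBPND")
  if (all(y == 0)) return(nls_result(NULL, par_names, y))
  init <- init %||% c(log(0.9), log(0.15), log(1.5))
  fit <- multistart_fit(init, resid_fun, nls_bounds(3), n_starts, jitter_sd,
                        bp_index = 3)
  nls_result(fit, par_names, y)
}

#' Fit every TAC of a study by NLS
#'
#' Applies [fit_2tcm_nls()] or [fit_srtm_nls()] to every subject x region
#' curve of a (synthetic or loaded) study and returns a tidy long table of
#' log-scale estimates. For `model = "srtm"` the reference region
#' (`study$config$reference_region`) is excluded from the targets and its
#' measured TAC is used as the reference curve.
#'
#' @param study A `synthetic_study` (see [simulate_cohort()]) or a study
#'   bundle from [read_study()].
#' @param model `"2tcm"` or `"srtm"`.
#' @param variant 2TCM outcome parameterization (ignored for SRTM).
#' @param n_starts Multi-start count per TAC.
#' @param seed Seed for the start jitter (the fit is deterministic given
#'   the seed).
#' @param dt Model grid spacing.
#' @return A tibble: `subject_id`, `region`, `model`, `variant`,
#'   `parameter`, `estimate_log`, `se_log`, `converged`.
#' @export
fit_cohort_nls <- function(study, model = c("2tcm", "srtm"),
                           variant = "bpnd", n_starts = 5, seed = 1,
                           dt = 1 / 30) {
  model <- match.arg(model)
  tt <- study$tacs
  sched <- study$schedule
  subjects <- study$participants$subject_id
  regions <- unique(tt$region)
  ref <- study$config$reference_region %||% "CWM"
  targets <- if (model == "srtm") setdiff(regions, ref) else regions
  rows <- list()
  k <- 0
  for (sid in subjects) {
    sub <- tt[tt$subject_id == sid, , drop = FALSE]
    ref_curve <- NULL
    if (model == "srtm") {
      rr <- sub[sub$region == ref, , drop = FALSE]
      if (nrow(rr) == 0) stop("reference region '", ref, "' missing for ",
                              sid)
      ref_curve <- tac(sid, ref, sched,
                       rr$activity[order(rr$frame)])
    }
    for (reg in targets) {
      rws <- sub[sub$region == reg, , drop = FALSE]
      if (nrow(rws) == 0) next
      y <- rws$activity[order(rws$frame)]
      curve <- tac(sid, reg, sched, y)
      k <- k + 1
      # per-TAC seed: each fit is reproducible in isolation, so one
      # degenerate curve cannot perturb the others
      tac_seed <- (seed + 7919 * k) %% 2147483647
      res <- with_seed(tac_seed, {
        if (model == "2tcm") {
          fit_2tcm_nls(curve, study$aif[[sid]], variant,
                       n_starts = n_starts, dt = dt)
        } else {
          fit_srtm_nls(curve, ref_curve, n_starts = n_starts, dt = dt)
        }
      })
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sid, region = reg, model = model,
        variant = if (model == "2tcm") variant else "srtm",
        parameter = names(res$estimate_log),
        estimate_log = unname(res$estimate_log),
        se_log = unname(res$se_log),
        converged = res$converged)
    }
  }
  do.call(rbind, rows)
}
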