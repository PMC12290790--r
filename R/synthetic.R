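#' Configuration of a synthetic PET cohort
#'
#' Defines the statistical structure of a simulated multi-group study:
#' group sizes, region set, true region-mean log kinetic parameters,
#' between-subject variation and its cross-parameter correlation, group
#' effects on log binding potential, the plasma-free-fraction model
#' (group offsets and/or smooth scan-date drift), the heteroscedastic TAC
#' noise model, and the input-function settings.
#'
#' Defaults emulate a serotonin-1A-antagonist-like tracer: low
#' non-displaceable distribution volume, a small raphe-like high-noise
#' region (`RN`, noise x3) whose group effect is double that of the
#' projection regions, and an fP assay whose measured values can drift
#' smoothly over the study years while groups are sampled inhomogeneously
#' in time.
#'
#' @param n_hv,n_nrm,n_ae Group sizes (healthy volunteers,
#'   not-recently-medicated and antidepressant-exposed patients).
#' @param regions Region names; `rn_region` marks the raphe-like region.
#' @param include_reference Append cerebellar grey/white-matter-like
#'   regions `CGM` and `CWM` (the latter used as the SRTM reference).
#' @param effect_nrm_rn,effect_nrm_proj Log-scale NRM-vs-HV effects on
#'   binding potential in the raphe-like and projection regions.
#' @param effect_ae_rn,effect_ae_proj Same for AE-vs-HV.
#' @param fp_confound If `TRUE`, measured fP has no true group offsets but
#'   drifts smoothly over scan date while groups are sampled
#'   inhomogeneously over the years (healthy volunteers earliest); if
#'   `FALSE`, scan dates are homogeneous and fP group offsets are applied
#'   directly.
#' @param fp_base Baseline plasma-free fraction.
#' @param fp_offsets Named log-scale group offsets used when
#'   `fp_confound = FALSE`.
#' @param fp_drift_amp Total log-scale amplitude of the smooth assay
#'   drift.
#' @param fp_noise_sd Log-scale SD of fP measurement noise.
#' @param noise_cv Frame-noise scale: the SD of frame `i` is
#'   `noise_cv * region_multiplier * mean(TAC) / w_i` with `w` the
#'   mean-one NLS weights.
#' @param noise_region_mult Named multipliers (default `RN = 3`).
#' @param between_sd Between-subject SDs of the log parameters
#'   (K1, VND, BPND, k4, vB).
#' @param between_cor 5x5 correlation matrix of the individual-level log
#'   parameters.
#' @param tac_jitter_sd Region x individual (TAC-level) log-parameter
#'   jitter SD.
#' @param cwm_contamination Small specific-binding contamination of the
#'   white-matter-like reference region (log BPND added on top of its low
#'   default), exercising reference-tissue bias.
#' @param reference_region Name of the SRTM reference region.
#' @param dt Model grid spacing used to generate curves.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_hv = 57, n_nrm = 50, n_ae = 53,
                          regions = c("DLPFC", "MPFC", "ACC", "PCC", "INS",
                                      "HIP", "AMY", "RN"),
                          include_reference = FALSE,
                          effect_nrm_rn = 0.15, effect_nrm_proj = 0.075,
                          effect_ae_rn = 0, effect_ae_proj = 0,
                          fp_confound = TRUE, fp_base = 0.07,
                          fp_offsets = c(HV = 0.13, AE = 0, NRM = -0.15),
                          fp_drift_amp = 0.5, fp_noise_sd = 0.18,
                          noise_cv = 0.05,
                          noise_region_mult = c(RN = 3),
                          between_sd = c(K1 = 0.15, VND = 0.20, BP = 0.25,
                                         k4 = 0.10, vB = 0.15),
                          between_cor = default_between_cor(),
                          tac_jitter_sd = c(K1 = 0.03, VND = 0.05,
                                            BP = 0.05, k4 = 0.03,
                                            vB = 0.05),
                          cwm_contamination = 0,
                          reference_region = "CWM",
                          dt = 1 / 30) {
  stopifnot(n_hv > 0, n_nrm > 0, n_ae > 0, all(between_sd > 0))
  ev <- eigen(between_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("between_cor must be positive-definite")
  rn <- "RN"
  if (!rn %in% regions) rn <- regions[length(regions)]
  all_regions <- regions
  if (include_reference) all_regions <- c(all_regions, "CGM",
                                          reference_region)
  structure(list(
    n_hv = n_hv, n_nrm = n_nrm, n_ae = n_ae,
    regions = all_regions, target_regions = regions,
    rn_region = rn, projection_regions = setdiff(regions, rn),
    include_reference = include_reference,
    reference_region = reference_region,
    region_means = default_region_means(all_regions, reference_region,
                                        cwm_contamination),
    effects = list(NRM = c(rn = effect_nrm_rn, proj = effect_nrm_proj),
                   AE = c(rn = effect_ae_rn, proj = effect_ae_proj)),
    fp = list(confound = fp_confound, base = fp_base, offsets = fp_offsets,
              drift_amp = fp_drift_amp, noise_sd = fp_noise_sd),
    noise_cv = noise_cv, noise_region_mult = noise_region_mult,
    between_sd = between_sd, between_cor = between_cor,
    tac_jitter_sd = tac_jitter_sd, dt = dt),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_between_cor <- function() {
  cm <- diag(5)
  dimnames(cm) <- list(c("K1", "VND", "BP", "k4", "vB"),
                       c("K1", "VND", "BP", "k4", "vB"))
  cm["K1", "VND"] <- cm["VND", "K1"] <- 0.5
  cm["K1", "BP"] <- cm["BP", "K1"] <- 0.2
  cm["VND", "BP"] <- cm["BP", "VND"] <- 0.3
  cm["VND", "k4"] <- cm["k4", "VND"] <- -0.2
  cm["BP", "k4"] <- cm["k4", "BP"] <- -0.1
  cm
}

# True region-mean log parameters (K1, VND, BPND, k4, vB). Low VND
# throughout; the raphe-like region has lower flow and VND; the
# white-matter-like reference has very low specific binding.
default_region_means <- function(regions, reference_region,
                                 cwm_contamination = 0) {
  base <- rbind(
    DLPFC = c(0.11, 0.60, 2.5, 0.04, 0.05),
    MPFC  = c(0.12, 0.62, 3.0, 0.04, 0.05),
    ACC   = c(0.12, 0.62, 3.0, 0.04, 0.05),
    PCC   = c(0.13, 0.63, 2.8, 0.04, 0.05),
    INS   = c(0.13, 0.62, 2.7, 0.04, 0.05),
    HIP   = c(0.10, 0.60, 3.5, 0.04, 0.05),
    AMY   = c(0.09, 0.58, 3.2, 0.04, 0.05),
    RN    = c(0.08, 0.50, 2.2, 0.04, 0.05),
    CGM   = c(0.11, 0.53, 0.45, 0.04, 0.05)
  )
  colnames(base) <- c("K1", "VND", "BP", "k4", "vB")
  ref_row <- matrix(c(0.06, 0.39, 0.15 * exp(cwm_contamination), 0.04,
                      0.05), 1, 5,
                    dimnames = list(reference_region, colnames(base)))
  tab <- rbind(base, ref_row)
  missing <- setdiff(regions, rownames(tab))
  if (length(missing)) {
    extra <- matrix(rep(c(0.11, 0.60, 2.8, 0.04, 0.05), length(missing)),
                    ncol = 5, byrow = TRUE,
                    dimnames = list(missing, colnames(tab)))
    tab <- rbind(tab, extra)
  }
  log(tab[regions, , drop = FALSE])
}

#' Simulate an arterial input function
#'
#' Whole plasma follows a Feng-type shape: linear rise from injection
#' onset to a peak scaled by injected dose, then tri-exponential decay.
#' The parent fraction is a Hill-type decreasing function of time in
#' \[0, 1\]; metabolite-corrected parent plasma is their product.
#'
#' @param dose Injected dose (mCi), `> 0`; the curve scales linearly
#'   with it.
#' @param fP Plasma-free fraction to attach to the input.
#' @return An [arterial_input()].
#' @export
simulate_aif <- function(dose, fP = NA_real_) {
  stopifnot(dose > 0)
  t0 <- 0.5
  tp <- 1.25
  peak <- 20 * dose / 7
  wp <- function(t) {
    out <- numeric(length(t))
    rising <- t > t0 & t <= tp
    out[rising] <- peak * (t[rising] - t0) / (tp - t0)
    late <- t > tp
    s <- t[late] - tp
    out[late] <- peak * (0.55 * exp(-3.5 * s) + 0.35 * exp(-0.25 * s) +
                         0.10 * exp(-0.012 * s))
    out
  }
  pf <- function(t) {
    0.05 + 0.95 / (1 + (pmax(t, 0) / 8)^1.8)
  }
  arterial_input(cp_parent = function(t) wp(t) * pf(t),
                 c_wholeplasma = wp, fP = fP)
}

fp_drift_fun <- function(amp) {
  function(year) -amp * pnorm((year - 2004) / 2.5)
}

#' Simulate measured plasma-free fractions
#'
#' `fP = base * exp(group_offset + drift(scan_date) + noise)`, clipped to
#' (0.01, 0.3). Under the drift confound, offsets are zero and the smooth
#' drift combined with inhomogeneous group sampling over time induces
#' apparent group differences.
#'
#' @param group Character vector of group labels (`HV`, `NRM`, `AE`).
#' @param scan_date Numeric scan dates (decimal years).
#' @param config A [cohort_config()] (its `fp` block is used).
#' @return Numeric vector of measured fP values.
#' @export
simulate_fp <- function(group, scan_date, config) {
  fp <- config$fp
  offsets <- if (fp$confound) c(HV = 0, AE = 0, NRM = 0) else fp$offsets
  drift <- if (fp$confound) fp_drift_fun(fp$drift_amp) else function(y) 0
  lf <- log(fp$base) + unname(offsets[group]) + drift(scan_date) +
    rnorm(length(group), 0, fp$noise_sd)
  pmin(pmax(exp(lf), 0.01), 0.3)
}

#' Simulate a complete synthetic study
#'
#' Draws participants (group, age, sex, scan date, injected dose, measured
#' fP), per-subject input functions, subject x region true 2TCM
#' log-parameters from the multivariate hierarchy (region means +
#' correlated individual deviations + TAC-level jitter), applies group
#' effects to log BPND (K1 and VND distributions are group-invariant), and
#' builds decay-corrected noisy TACs with heteroscedastic frame noise
#' (SD proportional to 1/weight, largest in the raphe-like region).
#' Regeneration with the same config and seed is bit-identical.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed governing all randomness.
#' @param tacs If `FALSE`, skip TAC generation (parameter draws only; used
#'   for fast statistical checks of the generator itself).
#' @return A `synthetic_study`: `participants` tibble, `aif` (per-subject
#'   [arterial_input()]), `tacs` long tibble, `schedule`, `truth` ledger
#'   (true log-parameter array, injected effects, fP decomposition) and
#'   the `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1,
                            tacs = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  sched <- default_frame_schedule()
  regions <- config$regions
  R <- length(regions)
  with_seed(seed, {
    groups <- c(rep("HV", config$n_hv), rep("NRM", config$n_nrm),
                rep("AE", config$n_ae))
    S <- length(groups)
    ids <- sprintf("S%03d", seq_len(S))
    age <- pmin(pmax(rnorm(S, 38, 13), 18), 70)
    sex <- stats::rbinom(S, 1, 0.56)   # 1 = female
    year_mean <- c(HV = 2002, AE = 2004, NRM = 2006)
    year <- if (config$fp$confound) {
      pmin(pmax(rnorm(S, year_mean[groups], 2.2), 1999), 2009)
    } else {
      runif(S, 1999, 2009)
    }
    dose <- pmin(pmax(rlnorm(S, log(7), 0.4), 1.5), 20)
    fP <- simulate_fp(groups, year, config)

    # group effects on log BP per region
    eff <- matrix(0, 3, R, dimnames = list(c("HV", "NRM", "AE"), regions))
    for (g in c("NRM", "AE")) {
      eff[g, config$rn_region] <- config$effects[[g]]["rn"]
      eff[g, config$projection_regions] <- config$effects[[g]]["proj"]
    }

    sigma_btw <- diag(config$between_sd) %*% config$between_cor %*%
      diag(config$between_sd)
    indiv <- rmvnorm_chol(S, rep(0, 5), sigma_btw)
    lambda <- array(NA_real_, c(S, R, 5),
                    dimnames = list(ids, regions,
                                    c("K1", "VND", "BP", "k4", "vB")))
    for (s in seq_len(S)) {
      jit <- matrix(rnorm(R * 5, 0, rep(config$tac_jitter_sd, each = R)),
                    R, 5)
      lam <- config$region_means + matrix(indiv[s, ], R, 5, byrow = TRUE) +
        jit
      lam[, "BP"] <- lam[, "BP"] + eff[groups[s], ]
      lam[, "vB"] <- pmin(lam[, "vB"], log(0.5))
      lambda[s, , ] <- lam
    }

    participants <- tibble::tibble(
      subject_id = ids, group = groups, age = age, sex = sex,
      scan_date = year, fP = fP, injected_dose = dose)

    aif <- lapply(seq_len(S), function(s) simulate_aif(dose[s], fP[s]))
    names(aif) <- ids

    tac_tab <- NULL
    if (tacs) {
      mult <- rep(1, R)
      names(mult) <- regions
      known <- intersect(names(config$noise_region_mult), regions)
      mult[known] <- config$noise_region_mult[known]
      rows <- vector("list", S * R)
      k <- 0
      for (s in seq_len(S)) {
        for (r in seq_len(R)) {
          lam <- lambda[s, r, ]
          p <- tcm2_params(K1 = exp(lam["K1"]),
                           k2 = exp(lam["K1"]) / exp(lam["VND"]),
                           k3 = exp(lam["BP"]) * exp(lam["k4"]),
                           k4 = exp(lam["k4"]), vB = exp(lam["vB"]))
          model <- solve_2tcm(p, aif[[s]], sched, dt = config$dt,
                              subject_id = ids[s], region = regions[r])
          w <- compute_weights(sched, model)
          # zero-weight (pre-arrival) frames still carry a little noise
          sdv <- config$noise_cv * mult[r] * mean(model$activity) /
            pmax(w, 0.1)
          act <- model$activity + rnorm(length(w), 0, sdv)
          k <- k + 1
          rows[[k]] <- tibble::tibble(
            subject_id = ids[s], region = regions[r],
            frame = seq_along(act), frame_start_min = sched$start,
            frame_dur_min = sched$dur, activity_kBq_mL = act)
        }
      }
      tac_tab <- do.call(rbind, rows)
      names(tac_tab)[names(tac_tab) == "activity_kBq_mL"] <- "activity"
    }

    structure(list(
      participants = participants, aif = aif, tacs = tac_tab,
      schedule = sched,
      truth = list(lambda = lambda, group_effects = eff,
                   fp = list(confound = config$fp$confound,
                             base = config$fp$base,
                             offsets = if (config$fp$confound) NULL else
                               config$fp$offsets,
                             drift_amp = if (config$fp$confound)
                               config$fp$drift_amp else 0)),
      config = config, seed = seed),
      class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects x %d regions (seed %d)\n",
              nrow(x$participants), length(x$config$regions), x$seed))
  invisible(x)
}
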