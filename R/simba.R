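#' @name hier_bayes
#' @title Simultaneous hierarchical multivariate quantification
#' @description All time-activity curves of a study are fitted at once:
#'   each curve's five log 2TCM parameters (log K1, log VND, log BP,
#'   log k4, log vB) are latent quantities decomposed into fixed effects,
#'   partially pooled region and individual deviations, and a TAC-level
#'   deviation, with the individual-level deviations correlated across
#'   parameters. The measurement model is Student-t on the frame scale with
#'   per-curve error scales tied to the NLS weighting scheme. Sampling is
#'   Metropolis-within-Gibbs: adaptive random-walk updates of the per-curve
#'   latent parameter blocks against the analytic 2TCM frame likelihood,
#'   with all linear-Gaussian hierarchy levels updated by their conjugate
#'   full conditionals.
NULL

#' MCMC settings
#'
#' @param chains Number of chains (run sequentially).
#' @param warmup Adaptation sweeps discarded per chain.
#' @param iter Kept sweeps per chain.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param nrep Metropolis proposals per TAC per sweep.
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1,
                         nrep = 2) {
  structure(list(chains = chains, warmup = warmup, iter = iter,
                 seed = seed, nrep = nrep), class = "mcmc_control")
}

param_labels <- c("K1", "VND", "BP", "k4", "vB")

# Fixed-effect design for the binding-potential parameter:
# region intercepts + sex + age + group-by-region effects (no overall
# group term), or the raphe-vs-projection parameterization with random
# slopes over projection regions.
make_bp_design <- function(meta, regions,
                           parameterization = c("group_region",
                                                "rn_projection"),
                           rn_region = "RN",
                           projection_regions = NULL) {
  parameterization <- match.arg(parameterization)
  T <- nrow(meta)
  Xr <- sapply(regions, function(r) as.numeric(meta$region == r))
  colnames(Xr) <- paste0("bp.mu[", regions, "]")
  X <- cbind(Xr, "bp.sex" = meta$sex, "bp.age" = meta$age_dec)
  psd <- c(rep(1, length(regions)), 0.5, 0.5)
  groups_present <- setdiff(unique(meta$group), "HV")
  groups_present <- groups_present[order(match(groups_present,
                                               c("NRM", "AE")))]
  Z <- NULL
  if (parameterization == "group_region") {
    for (g in groups_present) {
      Xg <- sapply(regions, function(r)
        as.numeric(meta$region == r & meta$group == g))
      colnames(Xg) <- paste0("bp.eff[", g, ":", regions, "]")
      X <- cbind(X, Xg)
      psd <- c(psd, rep(0.2, length(regions)))
    }
  } else {
    proj <- projection_regions %||% setdiff(regions, rn_region)
    for (g in groups_present) {
      X <- cbind(X,
                 as.numeric(meta$region == rn_region & meta$group == g),
                 as.numeric(meta$region %in% proj & meta$group == g))
      colnames(X)[ncol(X) - 1:0] <- paste0("bp.eff[", g, ":",
                                           c("RN", "proj"), "]")
      psd <- c(psd, 0.2, 0.2)
    }
    zc <- list()
    for (g in groups_present) {
      for (r in proj) {
        zc[[paste0("bp.slope[", g, ":", r, "]")]] <-
          as.numeric(meta$region == r & meta$group == g)
      }
    }
    Z <- do.call(cbind, zc)
  }
  keep <- colSums(abs(X)) > 0 &
    (apply(X, 2, function(v) sd(v) > 0) |
       seq_len(ncol(X)) <= length(regions))
  list(X = X[, keep, drop = FALSE], prior_sd = psd[keep],
       intercept_cols = which(colnames(X)[keep] %in% colnames(Xr)),
       Z = Z)
}

make_covar_design <- function(meta, prefix, covariates = TRUE) {
  X <- matrix(1, nrow(meta), 1,
              dimnames = list(NULL, paste0(prefix, ".int")))
  psd <- 1
  if (covariates) {
    X <- cbind(X, meta$sex, meta$age_dec)
    colnames(X)[2:3] <- paste0(prefix, c(".sex", ".age"))
    psd <- c(psd, 0.5, 0.5)
  }
  keep <- c(TRUE, if (ncol(X) > 1)
    apply(X[, -1, drop = FALSE], 2, function(v) sd(v) > 0))
  list(X = X[, keep, drop = FALSE], prior_sd = psd[keep],
       intercept_cols = 1L)
}

#' Build the simultaneous hierarchical model for a study
#'
#' Assembles data matrices, design matrices, priors and NLS-based
#' initial values. Global intercept priors default to pooled quick NLS
#' estimates of the same data (medians, wide SDs). The `bpf` outcome
#' scales each subject's tissue input by the measured plasma-free
#' fraction; the blood-volume term always uses unscaled whole plasma.
#'
#' @param study A `synthetic_study` or study bundle ([read_study()]) with
#'   complete metadata (group, age, sex) and per-subject blood input.
#' @param outcome `"bpnd"`, `"bpp"` or `"bpf"`.
#' @param regions Regions to include (default: the study's target
#'   regions, excluding reference regions).
#' @param subjects Subjects to include (default all).
#' @param parameterization Group-effect structure for BP:
#'   `"group_region"` (one coefficient per non-reference group per
#'   region) or `"rn_projection"` (overall raphe and projection effects
#'   per group, with random slopes over projection regions).
#' @param priors Optional list overriding elements of the default priors
#'   (see Details in the package vignette).
#' @param dt Model grid spacing (minutes).
#' @param init_starts Multi-starts for the per-TAC NLS initialization.
#' @return A `simba_model` object for [fit_simba()].
#' @export
build_simba_model <- function(study, outcome = c("bpnd", "bpp", "bpf"),
                              regions = NULL, subjects = NULL,
                              parameterization = c("group_region",
                                                   "rn_projection"),
                              priors = NULL, dt = 1 / 30,
                              init_starts = 2) {
  outcome <- match.arg(outcome)
  parameterization <- match.arg(parameterization)
  part <- study$participants
  if (!is.null(subjects)) part <- part[part$subject_id %in% subjects, ]
  if (any(is.na(part$group)) || any(is.na(part$age)) ||
      any(is.na(part$sex))) {
    stop("complete group, age and sex metadata required")
  }
  regions <- regions %||% study$config$target_regions %||%
    unique(study$tacs$region)
  tt <- study$tacs
  tt <- tt[tt$subject_id %in% part$subject_id & tt$region %in% regions, ]
  sched <- study$schedule
  Fn <- n_frames(sched)
  key <- unique(tt[, c("subject_id", "region")])
  T <- nrow(key)
  y <- w <- matrix(NA_real_, T, Fn)
  for (t in seq_len(T)) {
    rws <- tt[tt$subject_id == key$subject_id[t] &
                tt$region == key$region[t], ]
    yy <- rws$activity[order(rws$frame)]
    if (length(yy) != Fn) stop("mismatched schedules for ",
                               key$subject_id[t])
    y[t, ] <- yy
    w[t, ] <- compute_weights(sched, tac(key$subject_id[t], key$region[t],
                                         sched, yy))
  }
  sids <- part$subject_id
  subj_idx <- match(key$subject_id, sids)
  region_idx <- match(key$region, regions)
  age_dec_s <- (part$age - mean(part$age)) / 10
  meta <- data.frame(subject_id = key$subject_id, region = key$region,
                     group = part$group[subj_idx],
                     sex = part$sex[subj_idx],
                     age_dec = age_dec_s[subj_idx],
                     stringsAsFactors = FALSE)

  g <- input_grids(study$aif[[sids[1]]], sched, dt)
  G <- length(g$t)
  cp <- wb <- matrix(NA_real_, G, length(sids))
  for (s in seq_along(sids)) {
    gi <- input_grids(study$aif[[sids[s]]], sched, dt)
    fp_s <- study$aif[[sids[s]]]$fP
    if (outcome == "bpf") {
      if (is.na(fp_s)) stop("outcome 'bpf' requires fP for every subject")
      cp[, s] <- gi$cp * fp_s
    } else {
      cp[, s] <- gi$cp
    }
    wb[, s] <- gi$wb
  }
  vcode <- if (outcome == "bpnd") 1L else 2L

  # quick NLS for initialization and intercept priors; cp is already
  # fP-scaled for bpf, so its parameter vector is fitted in the bpp form
  init_variant <- if (outcome == "bpnd") "bpnd" else "bpp"
  lam_init <- matrix(NA_real_, T, 5)
  s_init <- numeric(T)
  for (t in seq_len(T)) {
    curve <- tac(key$subject_id[t], key$region[t], sched, y[t, ])
    res <- with_seed(1000 + t, fit_2tcm_nls(
      curve, local_input(cp[, subj_idx[t]], wb[, subj_idx[t]], g$t),
      variant = init_variant,
      weights = w[t, ], n_starts = init_starts, dt = dt))
    est <- res$estimate_log
    if (!res$converged || any(!is.finite(est))) {
      est <- c(log(0.1), log(0.6), log(2), log(0.04), log(0.05))
    }
    lam_init[t, ] <- pmin(pmax(est, -9), c(6.5, 6.5, 6.5, 0.5, log(0.4)))
    mu <- tcm2_frames_cpp(exp(lam_init[t, ]), vcode, cp[, subj_idx[t]],
                          wb[, subj_idx[t]], dt, sched$start, sched$dur)
    s_init[t] <- max(sqrt(mean((w[t, ] * (y[t, ] - mu))^2)), 1e-3)
  }

  bp_prior_mu <- vapply(regions, function(r) {
    v <- lam_init[region_idx == match(r, regions), 3]
    stats::median(v)
  }, numeric(1))
  bp_des <- make_bp_design(meta, regions, parameterization,
                           rn_region = study$config$rn_region %||% "RN",
                           projection_regions =
                             study$config$projection_regions)
  des <- list(
    make_covar_design(meta, "k1"),
    make_covar_design(meta, "vnd"),
    bp_des,
    make_covar_design(meta, "k4", covariates = FALSE),
    make_covar_design(meta, "vb", covariates = FALSE)
  )
  prior_mean <- list(
    c(stats::median(lam_init[, 1]), rep(0, ncol(des[[1]]$X) - 1)),
    c(stats::median(lam_init[, 2]), rep(0, ncol(des[[2]]$X) - 1)),
    { pm <- rep(0, ncol(des[[3]]$X))
      pm[des[[3]]$intercept_cols] <- pmin(pmax(bp_prior_mu, -2), 2.5)
      pm },
    c(stats::median(lam_init[, 4]), rep(0, ncol(des[[4]]$X) - 1)),
    c(pmin(pmax(stats::median(lam_init[, 5]), log(0.01)), log(0.2)),
      rep(0, ncol(des[[5]]$X) - 1))
  )
  pri <- list(
    beta_mean = prior_mean,
    beta_sd = lapply(des, function(d) d$prior_sd),
    sd_gamma_scale = c(0.3, 0.3, 0.3, 0.2, 0.2),
    sd_upsilon_scale = c(0.3, 0.3, 0.2, 0.2),
    sd_slope_scale = 0.1,
    tau_df = 8, tau_scale_sd = 0.2,
    ms_mean = log(stats::median(s_init)), ms_sd = 1,
    sds_scale = 0.5, nu_rate = 0.1
  )
  if (!is.null(priors)) pri[names(priors)] <- priors

  structure(list(
    y = y, w = w, meta = meta, subj_idx = subj_idx,
    region_idx = region_idx, subjects = sids, regions = regions,
    groups = part$group, cp = cp, wb = wb, dt = dt,
    fstart = sched$start, fdur = sched$dur, vcode = vcode,
    outcome = outcome, parameterization = parameterization,
    des = des, priors = pri, lambda_init = lam_init, s_init = s_init,
    rn_region = study$config$rn_region %||% "RN"),
    class = "simba_model")
}

# minimal arterial_input wrapping precomputed grid values (linear interp)
local_input <- function(cpv, wbv, tg) {
  arterial_input(
    cp_parent = function(t) approx(tg, cpv, xout = t, rule = 2)$y,
    c_wholeplasma = function(t) approx(tg, wbv, xout = t, rule = 2)$y)
}

draw_beta <- function(Xt_X, Xt_r, prior_mean, prior_sd, sigma2) {
  prec <- Xt_X / sigma2 + diag(1 / prior_sd^2, length(prior_sd))
  rhs <- Xt_r / sigma2 + prior_mean / prior_sd^2
  U <- chol(prec)
  mu <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
  mu + backsolve(U, rnorm(length(mu)))
}

mh_log_sd <- function(cur, ss, n, scale, step = 0.15) {
  # target over sigma: -n log sigma - ss/(2 sigma^2) + half-normal prior,
  # sampled on the log scale (Jacobian included)
  lcur <- log(cur)
  lp <- function(ls) {
    s <- exp(ls)
    -n * ls - ss / (2 * s^2) + log_dhalfnorm(s, scale) + ls
  }
  lprop <- lcur + step * rnorm(1)
  if (log(runif(1)) < lp(lprop) - lp(lcur)) exp(lprop) else cur
}

#' Fit the simultaneous hierarchical model
#'
#' Runs the Metropolis-within-Gibbs sampler. Per-TAC proposal scales are
#' adapted during warmup toward an acceptance rate of ~0.3 and then
#' frozen. Chains run sequentially; split R-hat and a crude effective
#' sample size are reported for every scalar parameter, with a warning if
#' any fixed effect has R-hat above 1.01.
#'
#' @param model A `simba_model` from [build_simba_model()].
#' @param control An [mcmc_control()].
#' @return A `pet_draws` object: `draws` (matrix of scalar draws, all
#'   chains stacked), `tau` (draws x subject x parameter individual
#'   deviations), `upsilon` (draws x region x parameter regional
#'   deviations, sum-to-zero per draw), `lambda_mean` (posterior-mean
#'   per-TAC log parameters), `meta`, and `diagnostics`.
#' @export
fit_simba <- function(model, control = mcmc_control()) {
  stopifnot(inherits(model, "simba_model"))
  chains <- lapply(seq_len(control$chains), function(ch) {
    with_seed(control$seed + ch - 1,
              simba_chain(model, control, chain_id = ch))
  })
  combine_chains(model, chains, control)
}

simba_chain <- function(model, control, chain_id = 1) {
  y <- model$y; w <- model$w
  T <- nrow(y); Fn <- ncol(y); S <- length(model$subjects)
  R <- length(model$regions)
  P <- 5
  pri <- model$priors
  des <- model$des
  has_z <- !is.null(des[[3]]$Z)
  Z <- des[[3]]$Z
  ups_pidx <- c(1, 2, 4, 5)

  lam <- model$lambda_init
  beta <- lapply(1:P, function(p) {
    b <- pri$beta_mean[[p]]
    X <- des[[p]]$X
    fit <- tryCatch(qr.coef(qr(X), lam[, p]), error = function(e) b)
    fit[!is.finite(fit)] <- b[!is.finite(fit)]
    # keep group effects at prior mean initially
    fit
  })
  bslope <- if (has_z) rep(0, ncol(Z)) else numeric(0)
  sd_slope <- 0.05
  # initialize the hierarchy by decomposing the NLS estimates; starting
  # at the complete-pooling mode (all deviations zero, tiny TAC scale)
  # makes the random-walk latent updates very slow to escape it
  resid0 <- lam
  for (p in 1:P) resid0[, p] <- lam[, p] - des[[p]]$X %*% beta[[p]]
  ups <- matrix(0, R, length(ups_pidx))
  for (j in seq_along(ups_pidx)) {
    p <- ups_pidx[j]
    m_r <- tapply(resid0[, p], model$region_idx, mean)
    ups[as.integer(names(m_r)), j] <- m_r
    ups[, j] <- ups[, j] - mean(ups[, j])
    resid0[, p] <- resid0[, p] - ups[model$region_idx, j]
  }
  tau <- matrix(0, S, P)
  for (p in 1:P) {
    m_i <- tapply(resid0[, p], model$subj_idx, mean)
    tau[as.integer(names(m_i)), p] <- m_i
    tau[, p] <- tau[, p] - mean(tau[, p])
    resid0[, p] <- resid0[, p] - tau[model$subj_idx, p]
  }
  sd_gamma <- pmax(apply(resid0, 2, sd), 0.03)
  sd_ups <- pmax(apply(ups, 2, sd), 0.03)
  Sigma <- stats::cov(tau) + diag(0.02^2, P)
  s_t <- model$s_init
  m_s <- pri$ms_mean; sd_s <- 0.5
  nu <- 10
  u <- matrix(1, T, Fn)
  step <- rep(0.08, T)
  pstep <- c(0.3, 0.3, 1, 1, 1)

  Xt_X <- lapply(des, function(d) crossprod(d$X))
  n_sub <- tabulate(model$subj_idx, S)
  n_reg <- tabulate(model$region_idx, R)

  n_keep <- control$iter
  total <- control$warmup + n_keep
  # storage
  scalar_names <- c(unlist(lapply(1:P, function(p) colnames(des[[p]]$X))),
                    if (has_z) "bp.sd_slope",
                    paste0("sd_gamma[", param_labels, "]"),
                    paste0("sd_upsilon[", param_labels[ups_pidx], "]"),
                    paste0("tau_sd[", param_labels, "]"),
                    apply(utils::combn(param_labels, 2), 2, function(pr)
                      paste0("tau_cor[", pr[1], ",", pr[2], "]")),
                    "nu", "m_s", "sd_s")
  draws <- matrix(NA_real_, n_keep, length(scalar_names),
                  dimnames = list(NULL, scalar_names))
  tau_draws <- array(NA_real_, c(n_keep, S, P))
  ups_draws <- array(NA_real_, c(n_keep, R, length(ups_pidx)))
  lam_sum <- matrix(0, T, P)
  acc_sum <- 0

  fixed <- matrix(0, T, P)
  compose_fixed <- function() {
    for (p in 1:P) fixed[, p] <<- des[[p]]$X %*% beta[[p]]
    if (has_z) fixed[, 3] <<- fixed[, 3] + Z %*% bslope
  }
  compose_fixed()

  tstep <- c(0.02, 0.02, 0.04, 0.08, 0.08)  # per-axis translation steps
  subj0 <- as.integer(model$subj_idx - 1L)

  for (it in seq_len(total)) {
    base <- fixed + tau[model$subj_idx, , drop = FALSE]
    base[, ups_pidx] <- base[, ups_pidx] +
      ups[model$region_idx, , drop = FALSE]
    sw <- simba_sweep_cpp(lam, base, sd_gamma, y, w, u, s_t, model$cp,
                          model$wb, subj0,
                          model$dt, model$fstart, model$fdur, model$vcode,
                          step, pstep, control$nrep)
    lam <- sw$lambda
    preds <- sw$preds
    ll_vec <- sw$loglik
    if (it <= control$warmup) {
      rate <- min(0.1, 5 / it)
      step <- pmin(pmax(step * exp(rate * (sw$accept - 0.3)), 1e-4), 2)
    }

    # global translation move: shift one whole log-parameter column and
    # its intercept(s) together. The per-TAC random walk diffuses these
    # global levels very slowly; this move targets them directly (only
    # the likelihood and the intercept priors change).
    ax <- ((it - 1) %% P) + 1
    delta <- rep(0, P)
    delta[ax] <- tstep[ax] * rnorm(1)
    lam_prop <- sweep(lam, 2, delta, "+")
    t_acc <- 0
    cap <- c(7, 7, 7, 7, log(0.9))
    if (all(lam_prop[, ax] >= -12) && all(lam_prop[, ax] <= cap[ax])) {
      ev <- simba_eval_cpp(lam_prop, y, w, u, s_t, model$cp, model$wb,
                           subj0, model$dt, model$fstart, model$fdur,
                           model$vcode)
      ic <- des[[ax]]$intercept_cols
      dprior <-
        sum(dnorm(beta[[ax]][ic] + delta[ax], pri$beta_mean[[ax]][ic],
                  pri$beta_sd[[ax]][ic], log = TRUE)) -
        sum(dnorm(beta[[ax]][ic], pri$beta_mean[[ax]][ic],
                  pri$beta_sd[[ax]][ic], log = TRUE))
      if (log(runif(1)) < sum(ev$loglik) - sum(ll_vec) + dprior) {
        lam <- lam_prop
        preds <- ev$preds
        ll_vec <- ev$loglik
        beta[[ax]][ic] <- beta[[ax]][ic] + delta[ax]
        compose_fixed()
        t_acc <- 1
      }
    }
    if (it <= control$warmup) {
      tstep[ax] <- min(max(tstep[ax] *
                             exp(min(0.2, 10 / it) * (t_acc - 0.35)),
                           1e-3), 2)
    }

    # latent t-scales
    z2 <- ((y - preds) * w / s_t)^2
    u <- matrix(rgamma(T * Fn, (nu + 1) / 2, rate = (nu + z2) / 2), T, Fn)

    # per-TAC error scales (lognormal hierarchy, MH on log s)
    ss_t <- rowSums(u * (w * (y - preds))^2)
    ls <- log(s_t)
    lsp <- ls + 0.2 * rnorm(T)
    lpost <- function(l) -Fn * l - ss_t / (2 * exp(2 * l)) +
      dnorm(l, m_s, sd_s, log = TRUE)
    acc <- log(runif(T)) < lpost(lsp) - lpost(ls)
    s_t[acc] <- exp(lsp[acc])
    # hyperparameters of the error-scale distribution
    prec_ms <- T / sd_s^2 + 1 / pri$ms_sd^2
    mu_ms <- (sum(log(s_t)) / sd_s^2 + pri$ms_mean / pri$ms_sd^2) / prec_ms
    m_s <- rnorm(1, mu_ms, 1 / sqrt(prec_ms))
    sd_s <- mh_log_sd(sd_s, sum((log(s_t) - m_s)^2), T, pri$sds_scale)

    # degrees of freedom of the t measurement model (nu > 3)
    lu_sum <- sum(log(u)); u_sum <- sum(u); n_u <- T * Fn
    lnu <- function(nv) {
      n_u * (nv / 2 * log(nv / 2) - lgamma(nv / 2)) +
        (nv / 2 - 1) * lu_sum - nv / 2 * u_sum - pri$nu_rate * (nv - 3)
    }
    eta <- log(nu - 3)
    etap <- eta + 0.3 * rnorm(1)
    if (log(runif(1)) < lnu(exp(etap) + 3) + etap - lnu(nu) - eta) {
      nu <- exp(etap) + 3
    }

    # fixed effects (conjugate given latents)
    rand <- tau[model$subj_idx, , drop = FALSE]
    rand[, ups_pidx] <- rand[, ups_pidx] + ups[model$region_idx, ,
                                               drop = FALSE]
    for (p in 1:P) {
      r <- lam[, p] - rand[, p]
      if (p == 3 && has_z) r <- r - as.vector(Z %*% bslope)
      beta[[p]] <- draw_beta(Xt_X[[p]], crossprod(des[[p]]$X, r),
                             pri$beta_mean[[p]], pri$beta_sd[[p]],
                             sd_gamma[p]^2)
    }
    if (has_z) {
      r3 <- lam[, 3] - des[[3]]$X %*% beta[[3]] - rand[, 3]
      nz <- colSums(Z)
      prec <- nz / sd_gamma[3]^2 + 1 / sd_slope^2
      mu_b <- as.vector(crossprod(Z, r3)) / sd_gamma[3]^2 / prec
      bslope <- rnorm(length(bslope), mu_b, 1 / sqrt(prec))
      sd_slope <- mh_log_sd(sd_slope, sum(bslope^2), length(bslope),
                            pri$sd_slope_scale)
    }
    compose_fixed()

    # region deviations (non-BP parameters), centered per draw
    for (j in seq_along(ups_pidx)) {
      p <- ups_pidx[j]
      r <- lam[, p] - fixed[, p] - tau[model$subj_idx, p]
      rs <- tapply(r, model$region_idx, sum)
      rs_full <- rep(0, R)
      rs_full[as.integer(names(rs))] <- rs
      prec <- n_reg / sd_gamma[p]^2 + 1 / sd_ups[j]^2
      ups[, j] <- rnorm(R, (rs_full / sd_gamma[p]^2) / prec,
                        1 / sqrt(prec))
      m <- mean(ups[, j])
      ups[, j] <- ups[, j] - m
      beta[[p]][des[[p]]$intercept_cols] <-
        beta[[p]][des[[p]]$intercept_cols] + m
      sd_ups[j] <- mh_log_sd(sd_ups[j], sum(ups[, j]^2), R,
                             pri$sd_upsilon_scale[j])
    }
    compose_fixed()

    # individual deviations, multivariate across parameters
    E <- lam - fixed
    E[, ups_pidx] <- E[, ups_pidx] - ups[model$region_idx, , drop = FALSE]
    Sig_inv <- chol2inv(chol(Sigma))
    for (i in seq_len(S)) {
      rows <- model$subj_idx == i
      prec <- Sig_inv + diag(n_sub[i] / sd_gamma^2, P)
      rhs <- colSums(E[rows, , drop = FALSE]) / sd_gamma^2
      U <- chol(prec)
      mu_i <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
      tau[i, ] <- mu_i + backsolve(U, rnorm(P))
    }
    mt <- colMeans(tau)
    tau <- sweep(tau, 2, mt)
    for (p in 1:P) {
      beta[[p]][des[[p]]$intercept_cols] <-
        beta[[p]][des[[p]]$intercept_cols] + mt[p]
    }
    compose_fixed()
    Sigma <- riwish(pri$tau_df + S,
                    diag(pri$tau_scale_sd^2 * (pri$tau_df - P - 1), P) +
                      crossprod(tau))

    # TAC-level deviation scales
    Gm <- lam - fixed - tau[model$subj_idx, , drop = FALSE]
    Gm[, ups_pidx] <- Gm[, ups_pidx] - ups[model$region_idx, ,
                                           drop = FALSE]
    for (p in 1:P) {
      sd_gamma[p] <- mh_log_sd(sd_gamma[p], sum(Gm[, p]^2), T,
                               pri$sd_gamma_scale[p])
    }

    if (it > control$warmup) {
      k <- it - control$warmup
      tsd <- sqrt(diag(Sigma))
      tc <- Sigma / tcrossprod(tsd)
      draws[k, ] <- c(unlist(beta), if (has_z) sd_slope, sd_gamma, sd_ups,
                      tsd, tc[lower.tri(tc)][lt_order(P)], nu, m_s, sd_s)
      tau_draws[k, , ] <- tau
      ups_draws[k, , ] <- ups
      lam_sum <- lam_sum + lam
      acc_sum <- acc_sum + mean(sw$accept)
    }
  }
  list(draws = draws, tau = tau_draws, ups = ups_draws,
       lam_mean = lam_sum / n_keep, accept = acc_sum / n_keep)
}

# lower.tri of a correlation matrix is column-major; reorder to match
# combn(labels, 2) pair order
lt_order <- function(P) {
  idx <- which(lower.tri(matrix(0, P, P)))
  pairs <- utils::combn(P, 2)
  target <- (pairs[1, ] - 1) * P + pairs[2, ]
  match(target, idx)
}

combine_chains <- function(model, chains, control) {
  ndraw <- nrow(chains[[1]]$draws)
  nms <- colnames(chains[[1]]$draws)
  all_draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  rhat <- vapply(seq_along(nms), function(j) {
    split_rhat(sapply(chains, function(ch) ch$draws[, j]))
  }, numeric(1))
  names(rhat) <- nms
  ess <- vapply(seq_along(nms), function(j)
    sum(sapply(chains, function(ch) ess_basic(ch$draws[, j]))),
    numeric(1))
  names(ess) <- nms
  fixed <- grepl("^(bp|k1|vnd|k4|vb)\\.", nms)
  if (any(rhat[fixed] > 1.01, na.rm = TRUE)) {
    warning(sprintf("max split R-hat for fixed effects is %.3f (> 1.01); consider more iterations",
                    max(rhat[fixed], na.rm = TRUE)), call. = FALSE)
  }
  tau <- do.call(abind1, lapply(chains, `[[`, "tau"))
  ups_list <- lapply(chains, `[[`, "ups")
  ups <- if (!is.null(ups_list[[1]])) do.call(abind1, ups_list) else NULL
  lam_mean <- Reduce(`+`, lapply(chains, `[[`, "lam_mean")) /
    length(chains)
  structure(list(
    draws = all_draws, tau = tau, upsilon = ups, lambda_mean = lam_mean,
    meta = list(subjects = model$subjects, regions = model$regions,
                groups = model$groups, outcome = model$outcome,
                parameterization = model$parameterization,
                param_labels = param_labels,
                ups_params = param_labels[c(1, 2, 4, 5)],
                tac_key = model$meta[, c("subject_id", "region")],
                rn_region = model$rn_region),
    diagnostics = list(
      rhat = rhat, ess = ess,
      accept = mean(sapply(chains, `[[`, "accept")),
      chains = control$chains, iter = control$iter)),
    class = "pet_draws")
}

abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(sapply(arrs, function(a) dim(a)[1])),
                           d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @export
print.pet_draws <- function(x, ...) {
  cat(sprintf("<pet_draws> %s, %d draws (%d chains), %d scalar parameters\n",
              x$meta$outcome %||% "fit", nrow(x$draws),
              x$diagnostics$chains, ncol(x$draws)))
  cat(sprintf("  max R-hat %.3f, mean MH acceptance %.2f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              x$diagnostics$accept %||% NA))
  invisible(x)
}

#' Partially pooled individual-level deviations
#'
#' Posterior mean and SD of each subject's deviation for one model
#' parameter, after removal of fixed-effect (covariate, group, region)
#' and regional contributions — the model's individual-level random
#' effects.
#'
#' @param draws A `pet_draws`.
#' @param parameter One of the model's parameter labels (e.g. `"BP"`,
#'   `"VND"`, `"K1"`).
#' @return Tibble with `subject_id`, `group`, `post_mean`, `post_sd`.
#' @export
extract_individual_effects <- function(draws, parameter = "BP") {
  labs <- draws$meta$param_labels
  p <- match(parameter, labs)
  if (is.na(p)) stop("unknown parameter '", parameter, "'; available: ",
                     paste(labs, collapse = ", "))
  m <- apply(draws$tau[, , p, drop = FALSE], 2, mean)
  s <- apply(draws$tau[, , p, drop = FALSE], 2, sd)
  tibble::tibble(subject_id = draws$meta$subjects,
                 group = draws$meta$groups,
                 post_mean = as.vector(m), post_sd = as.vector(s))
}

#' Regional deviations of the non-displaceable distribution volume
#'
#' Summaries of the partially pooled regional deviations of log VND,
#' expressed as percent deviation from the across-region mean
#' (`100 * (exp(upsilon) - 1)`) with 95% credible intervals. The
#' deviations satisfy a sum-to-zero constraint in every draw.
#'
#' @param draws A `pet_draws` from [fit_simba()].
#' @return Tibble with `region`, `percent`, `lo95`, `hi95`.
#' @export
region_vnd_deviations <- function(draws) {
  if (is.null(draws$upsilon)) stop("no regional deviations in this fit")
  p <- match("VND", draws$meta$ups_params)
  x <- 100 * (exp(draws$upsilon[, , p, drop = FALSE]) - 1)
  tibble::tibble(
    region = draws$meta$regions,
    percent = apply(x, 2, mean),
    lo95 = apply(x, 2, quantile, 0.025),
    hi95 = apply(x, 2, quantile, 0.975))
}
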