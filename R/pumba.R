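#' @name pumba
#' @title Multivariate hierarchical analysis of pre-estimated parameters
#' @description Treats each subject x region vector of NLS log-parameter
#'   estimates as a multivariate-normal response (no TAC likelihood):
#'   fixed effects as in the simultaneous model, partially pooled region
#'   and individual deviations with full individual-level cross-parameter
#'   correlation, and a full residual covariance across the parameters at
#'   the TAC level. All conditionals are conjugate (Gibbs), apart from
#'   random-effect SDs (scalar Metropolis on the log scale). Estimation
#'   uncertainty of the NLS inputs is not propagated: estimates enter as
#'   data, a deliberate simplification shared with the method's design.
NULL

#' Assemble the input table for the multivariate parameter analysis
#'
#' Joins a tidy NLS parameter table (long format, as produced by
#' [fit_cohort_nls()]) with participant metadata and reshapes it to one
#' complete parameter vector per subject x region.
#'
#' @param nls_table Long table with `subject_id`, `region`, `parameter`,
#'   `estimate_log`, `converged`.
#' @param participants Metadata with `subject_id`, `group`, `age`, `sex`.
#' @param parameters Parameter names to use, in order; the binding
#'   potential must be last by convention of the default
#'   (`c("logR1", "logk2prime", "logBPND")` for SRTM).
#' @param require_converged Drop subject x region vectors with any
#'   non-converged component.
#' @return A `pumba_input` list with the response matrix and metadata.
#' @export
pumba_input <- function(nls_table, participants,
                        parameters = c("logR1", "logk2prime", "logBPND"),
                        require_converged = TRUE) {
  tt <- nls_table[nls_table$parameter %in% parameters, ]
  if (require_converged) tt <- tt[tt$converged, ]
  key <- unique(tt[, c("subject_id", "region")])
  Y <- matrix(NA_real_, nrow(key), length(parameters),
              dimnames = list(NULL, parameters))
  for (i in seq_len(nrow(key))) {
    sub <- tt[tt$subject_id == key$subject_id[i] &
                tt$region == key$region[i], ]
    Y[i, ] <- sub$estimate_log[match(parameters, sub$parameter)]
  }
  ok <- stats::complete.cases(Y)
  key <- key[ok, , drop = FALSE]
  Y <- Y[ok, , drop = FALSE]
  if (nrow(Y) == 0) stop("no complete parameter vectors")
  part <- participants[participants$subject_id %in% key$subject_id, ]
  structure(list(Y = Y, key = key, participants = part,
                 parameters = parameters),
            class = "pumba_input")
}

#' Fit the multivariate hierarchical model to estimated parameters
#'
#' @param input A [pumba_input()] (default parameter set: SRTM
#'   `logR1`, `logk2prime`, `logBPND`; a 2TCM parameter set such as
#'   `c("logK1","logVND","logBPND","logk4","logvB")` is equally valid).
#' @param bp_param Name of the binding-potential column (gets the full
#'   region + sex + age + group-by-region fixed-effect structure with the
#'   Normal(0, 0.2) group-difference prior).
#' @param covar_params Columns receiving age and sex fixed effects
#'   (default `logk2prime`; all non-BP columns receive region random
#'   deviations).
#' @param parameterization As in [build_simba_model()].
#' @param rn_region,projection_regions Region roles for the
#'   raphe-vs-projection parameterization.
#' @param priors Optional named overrides of the default priors.
#' @param control An [mcmc_control()].
#' @return A `pet_draws` (same draw naming as [fit_simba()]; the
#'   residual covariance appears as `res_sd[...]` / `res_cor[...]`).
#' @export
fit_pumba <- function(input, bp_param = "logBPND",
                      covar_params = "logk2prime",
                      parameterization = c("group_region",
                                           "rn_projection"),
                      rn_region = "RN", projection_regions = NULL,
                      priors = NULL, control = mcmc_control()) {
  stopifnot(inherits(input, "pumba_input"))
  parameterization <- match.arg(parameterization)
  Y <- input$Y
  P <- ncol(Y)
  labs <- sub("^log", "", input$parameters)
  bp_idx <- match(bp_param, input$parameters)
  if (is.na(bp_idx)) stop("bp_param not among input parameters")
  part <- input$participants
  sids <- part$subject_id
  subj_idx <- match(input$key$subject_id, sids)
  regions <- sort(unique(input$key$region))
  region_idx <- match(input$key$region, regions)
  meta <- data.frame(
    subject_id = input$key$subject_id, region = input$key$region,
    group = part$group[subj_idx], sex = part$sex[subj_idx],
    age_dec = ((part$age - mean(part$age)) / 10)[subj_idx],
    stringsAsFactors = FALSE)

  des <- vector("list", P)
  for (p in seq_len(P)) {
    if (p == bp_idx) {
      des[[p]] <- make_bp_design(meta, regions, parameterization,
                                 rn_region, projection_regions)
    } else {
      des[[p]] <- make_covar_design(
        meta, tolower(labs[p]),
        covariates = input$parameters[p] %in% covar_params)
    }
  }
  ups_pidx <- setdiff(seq_len(P), bp_idx)
  prior_mean <- lapply(seq_len(P), function(p) {
    pm <- rep(0, ncol(des[[p]]$X))
    if (p == bp_idx) {
      med <- vapply(regions, function(r)
        stats::median(Y[region_idx == match(r, regions), p]), numeric(1))
      pm[des[[p]]$intercept_cols] <- pmin(pmax(med, -3), 3)
    } else {
      pm[des[[p]]$intercept_cols] <- stats::median(Y[, p])
    }
    pm
  })
  pri <- list(
    beta_mean = prior_mean,
    beta_sd = lapply(des, function(d) d$prior_sd),
    sd_upsilon_scale = rep(0.3, length(ups_pidx)),
    sd_slope_scale = 0.1,
    tau_df = P + 3, tau_scale_sd = 0.2,
    res_df = P + 3, res_scale_sd = 0.1
  )
  if (!is.null(priors)) pri[names(priors)] <- priors

  model <- list(Y = Y, des = des, subj_idx = subj_idx,
                region_idx = region_idx, subjects = sids,
                regions = regions, groups = part$group, labs = labs,
                bp_idx = bp_idx, ups_pidx = ups_pidx, priors = pri,
                parameterization = parameterization,
                meta = meta, rn_region = rn_region)
  chains <- lapply(seq_len(control$chains), function(ch) {
    with_seed(control$seed + ch - 1, pumba_chain(model, control))
  })
  out <- combine_pumba(model, chains, control)
  out
}

pumba_chain <- function(model, control) {
  Y <- model$Y
  T <- nrow(Y); P <- ncol(Y)
  S <- length(model$subjects); R <- length(model$regions)
  des <- model$des; pri <- model$priors
  bp <- model$bp_idx; ups_pidx <- model$ups_pidx
  has_z <- !is.null(des[[bp]]$Z)
  Z <- des[[bp]]$Z

  beta <- lapply(seq_len(P), function(p) {
    fit <- tryCatch(qr.coef(qr(des[[p]]$X), Y[, p]),
                    error = function(e) pri$beta_mean[[p]])
    fit[!is.finite(fit)] <- pri$beta_mean[[p]][!is.finite(fit)]
    fit
  })
  bslope <- if (has_z) rep(0, ncol(Z)) else numeric(0)
  sd_slope <- 0.05
  tau <- matrix(0, S, P)
  ups <- matrix(0, R, length(ups_pidx))
  sd_ups <- rep(0.1, length(ups_pidx))
  Sigma <- diag(0.15^2, P)
  Sres <- diag(0.1^2, P)
  n_sub <- tabulate(model$subj_idx, S)
  n_reg <- tabulate(model$region_idx, R)
  Xt_X <- lapply(des, function(d) crossprod(d$X))

  labs <- model$labs
  scalar_names <- c(
    unlist(lapply(seq_len(P), function(p) colnames(des[[p]]$X))),
    if (has_z) "bp.sd_slope",
    paste0("sd_upsilon[", labs[ups_pidx], "]"),
    paste0("tau_sd[", labs, "]"),
    if (P > 1) apply(utils::combn(labs, 2), 2, function(pr)
      paste0("tau_cor[", pr[1], ",", pr[2], "]")),
    paste0("res_sd[", labs, "]"),
    if (P > 1) apply(utils::combn(labs, 2), 2, function(pr)
      paste0("res_cor[", pr[1], ",", pr[2], "]")))
  n_keep <- control$iter
  draws <- matrix(NA_real_, n_keep, length(scalar_names),
                  dimnames = list(NULL, scalar_names))
  tau_draws <- array(NA_real_, c(n_keep, S, P))
  ups_draws <- array(NA_real_, c(n_keep, R, max(length(ups_pidx), 1)))

  fixed <- matrix(0, T, P)
  compose_fixed <- function() {
    for (p in seq_len(P)) fixed[, p] <<- des[[p]]$X %*% beta[[p]]
    if (has_z) fixed[, bp] <<- fixed[, bp] + Z %*% bslope
  }
  compose_fixed()
  expand_rand <- function() {
    rand <- tau[model$subj_idx, , drop = FALSE]
    if (length(ups_pidx)) {
      rand[, ups_pidx] <- rand[, ups_pidx] +
        ups[model$region_idx, , drop = FALSE]
    }
    rand
  }

  for (it in seq_len(control$warmup + n_keep)) {
    rand <- expand_rand()
    Om <- chol2inv(chol(Sres))
    # fixed effects: conditional regression for each parameter given the
    # other parameters' residuals (exact Gibbs step under MVN residuals)
    for (p in seq_len(P)) {
      Eps <- Y - fixed - rand
      if (P > 1) {
        So <- Sres[-p, -p, drop = FALSE]
        sv <- Sres[p, -p, drop = FALSE]
        A <- sv %*% chol2inv(chol(So))
        cond_off <- as.vector(Eps[, -p, drop = FALSE] %*% t(A))
        v <- Sres[p, p] - as.vector(A %*% t(sv))
      } else {
        cond_off <- 0
        v <- Sres[1, 1]
      }
      r <- Y[, p] - rand[, p] - cond_off
      if (p == bp && has_z) r <- r - as.vector(Z %*% bslope)
      beta[[p]] <- draw_beta(Xt_X[[p]], crossprod(des[[p]]$X, r),
                             pri$beta_mean[[p]], pri$beta_sd[[p]], v)
      compose_fixed()
      if (p == bp && has_z) {
        Eps <- Y - fixed - rand
        r3 <- Eps[, p] + as.vector(Z %*% bslope) - cond_off
        nz <- colSums(Z)
        prec <- nz / v + 1 / sd_slope^2
        mu_b <- as.vector(crossprod(Z, r3)) / v / prec
        bslope <- rnorm(length(bslope), mu_b, 1 / sqrt(prec))
        sd_slope <- mh_log_sd(sd_slope, sum(bslope^2), length(bslope),
                              pri$sd_slope_scale)
        compose_fixed()
      }
    }

    # region deviations for non-BP parameters
    for (j in seq_along(ups_pidx)) {
      p <- ups_pidx[j]
      rand <- expand_rand()
      Eps <- Y - fixed - rand
      if (P > 1) {
        So <- Sres[-p, -p, drop = FALSE]
        sv <- Sres[p, -p, drop = FALSE]
        A <- sv %*% chol2inv(chol(So))
        cond_off <- as.vector(Eps[, -p, drop = FALSE] %*% t(A))
        v <- Sres[p, p] - as.vector(A %*% t(sv))
      } else {
        cond_off <- 0; v <- Sres[1, 1]
      }
      r <- Y[, p] - fixed[, p] - tau[model$subj_idx, p] - cond_off
      rs <- rep(0, R)
      agg <- tapply(r, model$region_idx, sum)
      rs[as.integer(names(agg))] <- agg
      prec <- n_reg / v + 1 / sd_ups[j]^2
      ups[, j] <- rnorm(R, (rs / v) / prec, 1 / sqrt(prec))
      m <- mean(ups[, j])
      ups[, j] <- ups[, j] - m
      beta[[p]][des[[p]]$intercept_cols] <-
        beta[[p]][des[[p]]$intercept_cols] + m
      sd_ups[j] <- mh_log_sd(sd_ups[j], sum(ups[, j]^2), R,
                             pri$sd_upsilon_scale[j])
      compose_fixed()
    }

    # individual deviations (multivariate) and covariances
    D <- Y - fixed
    if (length(ups_pidx)) {
      D[, ups_pidx] <- D[, ups_pidx] - ups[model$region_idx, ,
                                           drop = FALSE]
    }
    Sig_inv <- chol2inv(chol(Sigma))
    Om <- chol2inv(chol(Sres))
    for (i in seq_len(S)) {
      rows <- model$subj_idx == i
      prec <- Sig_inv + n_sub[i] * Om
      rhs <- Om %*% colSums(D[rows, , drop = FALSE])
      U <- chol(prec)
      mu_i <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
      tau[i, ] <- mu_i + backsolve(U, rnorm(P))
    }
    mt <- colMeans(tau)
    tau <- sweep(tau, 2, mt)
    for (p in seq_len(P)) {
      beta[[p]][des[[p]]$intercept_cols] <-
        beta[[p]][des[[p]]$intercept_cols] + mt[p]
    }
    compose_fixed()
    Sigma <- riwish(pri$tau_df + S,
                    diag(pri$tau_scale_sd^2 * (pri$tau_df - P - 1), P) +
                      crossprod(tau))
    Eps <- Y - fixed - expand_rand()
    Sres <- riwish(pri$res_df + T,
                   diag(pri$res_scale_sd^2 * (pri$res_df - P - 1), P) +
                     crossprod(Eps))

    if (it > control$warmup) {
      k <- it - control$warmup
      tsd <- sqrt(diag(Sigma)); tc <- Sigma / tcrossprod(tsd)
      rsd <- sqrt(diag(Sres)); rc <- Sres / tcrossprod(rsd)
      draws[k, ] <- c(unlist(beta), if (has_z) sd_slope, sd_ups, tsd,
                      if (P > 1) tc[lower.tri(tc)], rsd,
                      if (P > 1) rc[lower.tri(rc)])
      tau_draws[k, , ] <- tau
      if (length(ups_pidx)) ups_draws[k, , ] <- ups
    }
  }
  list(draws = draws, tau = tau_draws,
       ups = if (length(ups_pidx)) ups_draws else NULL)
}

combine_pumba <- function(model, chains, control) {
  nms <- colnames(chains[[1]]$draws)
  all_draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  rhat <- vapply(seq_along(nms), function(j)
    split_rhat(sapply(chains, function(ch) ch$draws[, j])), numeric(1))
  names(rhat) <- nms
  tau <- do.call(abind1, lapply(chains, `[[`, "tau"))
  ups <- if (!is.null(chains[[1]]$ups))
    do.call(abind1, lapply(chains, `[[`, "ups")) else NULL
  structure(list(
    draws = all_draws, tau = tau, upsilon = ups, lambda_mean = NULL,
    meta = list(subjects = model$subjects, regions = model$regions,
                groups = model$groups, outcome = "pumba",
                parameterization = model$parameterization,
                param_labels = model$labs,
                ups_params = model$labs[model$ups_pidx],
                tac_key = model$meta[, c("subject_id", "region")],
                rn_region = model$rn_region),
    diagnostics = list(rhat = rhat,
                       ess = setNames(rep(NA_real_, length(nms)), nms),
                       chains = control$chains, iter = control$iter)),
    class = "pet_draws")
}
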