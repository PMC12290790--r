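#' @name contrasts_power
#' @title Group-level inference and power utilities
NULL

summarize_contrast <- function(draws_vec) {
  pct <- 100 * (exp(draws_vec) - 1)
  list(percent = mean(pct),
       est_log = mean(draws_vec),
       lo80 = unname(quantile(pct, 0.10)),
       hi80 = unname(quantile(pct, 0.90)),
       lo95 = unname(quantile(pct, 0.025)),
       hi95 = unname(quantile(pct, 0.975)),
       p_gt0 = mean(draws_vec > 0))
}

#' Group contrasts on binding potential
#'
#' Transforms group-by-region coefficients of a fitted model to percent
#' differences (`100 * (exp(beta) - 1)`) and summarizes with 80% and 95%
#' intervals and the directional probability `P[beta > 0]`. Works on
#' posterior draws (`pet_draws`) or on a univariate mixed-model fit
#' (`lme_contrast`, normal approximation with confidence intervals).
#'
#' @param fit A `pet_draws` or `lme_contrast`.
#' @param comparisons Character vector among `"NRM-HV"`, `"AE-HV"`,
#'   `"NRM-AE"`.
#' @param regions Regions to report (default all in the fit).
#' @return Tibble with `region`, `comparison`, `percent`, `est_log`,
#'   `lo80`, `hi80`, `lo95`, `hi95`, `p_gt0`.
#' @export
group_contrasts <- function(fit, comparisons = c("NRM-HV", "AE-HV",
                                                 "NRM-AE"),
                            regions = NULL) {
  UseMethod("group_contrasts")
}

contrast_draws <- function(draws, g, region) {
  nm <- paste0("bp.eff[", g, ":", region, "]")
  if (!nm %in% colnames(draws)) {
    stop("missing coefficient ", nm, " in the fit")
  }
  draws[, nm]
}

#' @export
group_contrasts.pet_draws <- function(fit, comparisons = c("NRM-HV",
                                                           "AE-HV",
                                                           "NRM-AE"),
                                      regions = NULL) {
  if (fit$meta$parameterization == "rn_projection") {
    regions <- regions %||% c("RN", "proj")
  } else {
    regions <- regions %||% fit$meta$regions
  }
  rows <- list()
  for (reg in regions) {
    for (cmp in comparisons) {
      parts <- strsplit(cmp, "-", fixed = TRUE)[[1]]
      d <- numeric(nrow(fit$draws))
      if (parts[1] != "HV") d <- d + contrast_draws(fit$draws, parts[1],
                                                    reg)
      if (parts[2] != "HV") d <- d - contrast_draws(fit$draws, parts[2],
                                                    reg)
      s <- summarize_contrast(d)
      rows[[length(rows) + 1]] <- tibble::tibble(
        region = reg, comparison = cmp, percent = s$percent,
        est_log = s$est_log, lo80 = s$lo80, hi80 = s$hi80, lo95 = s$lo95,
        hi95 = s$hi95, p_gt0 = s$p_gt0)
    }
  }
  do.call(rbind, rows)
}

#' @export
group_contrasts.lme_contrast <- function(fit, comparisons = c("NRM-HV",
                                                              "AE-HV",
                                                              "NRM-AE"),
                                         regions = NULL) {
  regions <- regions %||% fit$regions
  rows <- list()
  for (reg in regions) {
    for (cmp in comparisons) {
      parts <- strsplit(cmp, "-", fixed = TRUE)[[1]]
      v <- rep(0, length(fit$coef))
      names(v) <- names(fit$coef)
      add_term <- function(v, g, sgn) {
        nm <- paste0("region", reg, ":is", g)
        if (!nm %in% names(v)) nm <- paste0("is", g)  # single-region fit
        if (!nm %in% names(v)) stop("missing coefficient for group ", g)
        v[nm] <- v[nm] + sgn
        v
      }
      if (parts[1] != "HV") v <- add_term(v, parts[1], 1)
      if (parts[2] != "HV") v <- add_term(v, parts[2], -1)
      est <- sum(v * fit$coef)
      se <- sqrt(as.numeric(t(v) %*% fit$vcov %*% v))
      z80 <- qnorm(0.90); z95 <- qnorm(0.975)
      rows[[length(rows) + 1]] <- tibble::tibble(
        region = reg, comparison = cmp,
        percent = 100 * (exp(est) - 1), est_log = est,
        lo80 = 100 * (exp(est - z80 * se) - 1),
        hi80 = 100 * (exp(est + z80 * se) - 1),
        lo95 = 100 * (exp(est - z95 * se) - 1),
        hi95 = 100 * (exp(est + z95 * se) - 1),
        p_gt0 = pnorm(est / se))
    }
  }
  do.call(rbind, rows)
}

#' Univariate linear mixed-effects comparator
#'
#' Fits `log BP ~ 0 + region + sex + age + region:group + (1 | subject)`
#' (no overall group term; group entering only through the
#' region-interaction indicators) with lme4, the conventional univariate
#' analysis the hierarchical models are compared against.
#'
#' @param bp_table Table with `subject_id`, `region`, `group`, `sex`,
#'   `age`, `logBP` (one value per subject x region).
#' @return An `lme_contrast`: coefficient vector, covariance, the lme4
#'   fit, and the region set; use [group_contrasts()] to extract
#'   contrasts.
#' @export
fit_univariate_lme <- function(bp_table) {
  d <- as.data.frame(bp_table)
  stopifnot(all(c("subject_id", "region", "group", "sex", "age",
                  "logBP") %in% names(d)))
  d$region <- factor(d$region)
  d$age_dec <- (d$age - mean(d$age)) / 10
  d$isNRM <- as.numeric(d$group == "NRM")
  d$isAE <- as.numeric(d$group == "AE")
  if (nlevels(d$region) > 1) {
    terms <- c("0", "region", "sex", "age_dec",
               if (any(d$isNRM > 0)) "region:isNRM",
               if (any(d$isAE > 0)) "region:isAE")
  } else {
    terms <- c("1", "sex", "age_dec",
               if (any(d$isNRM > 0)) "isNRM",
               if (any(d$isAE > 0)) "isAE")
  }
  if (max(table(d$subject_id)) < 2) {
    # one observation per subject: the random intercept is not
    # estimable and the model collapses to ordinary regression
    fit <- lm(stats::as.formula(paste("logBP ~",
                                      paste(terms, collapse = " + "))),
              data = d)
    return(structure(list(coef = coef(fit), vcov = vcov(fit), fit = fit,
                          regions = levels(d$region)),
                     class = "lme_contrast"))
  }
  fml <- stats::as.formula(paste("logBP ~", paste(terms, collapse = " + "),
                                 "+ (1 | subject_id)"))
  fit <- lme4::lmer(fml, data = d, REML = TRUE)
  if (lme4::isSingular(fit)) {
    warning("singular mixed-model fit", call. = FALSE)
  }
  structure(list(coef = lme4::fixef(fit),
                 vcov = as.matrix(vcov(fit)),
                 fit = fit, regions = levels(d$region)),
            class = "lme_contrast")
}

#' Raphe-versus-projection contrast
#'
#' Refits the binding-potential group structure with one overall effect
#' for the raphe-like region and one for the mean of the projection
#' regions per patient group, plus random slopes over projection regions,
#' then reports the posterior probability that the raphe effect exceeds
#' the mean projection effect, the projection-mean contrast, and the
#' random-slope SD.
#'
#' @param study A `synthetic_study` or study bundle.
#' @param method `"pumba"` (NLS + multivariate analysis of SRTM or
#'   supplied parameters) or `"simba"` (simultaneous model).
#' @param outcome Outcome passed to the fitting routine (2TCM variant for
#'   `"simba"`).
#' @param comparison `"NRM-HV"` or `"AE-HV"`.
#' @param nls_table For `method = "pumba"`: optional precomputed
#'   [fit_cohort_nls()] table (SRTM).
#' @param control An [mcmc_control()].
#' @param ... Passed to the model builder.
#' @return List with `p_rn_gt_proj`, `rn`, `proj` (contrast summaries),
#'   `sd_slope` (posterior mean and 95% CrI) and the fitted `pet_draws`.
#' @export
rn_vs_projection <- function(study, method = c("simba", "pumba"),
                             outcome = "bpnd", comparison = "NRM-HV",
                             nls_table = NULL,
                             control = mcmc_control(), ...) {
  method <- match.arg(method)
  g <- strsplit(comparison, "-", fixed = TRUE)[[1]][1]
  if (method == "simba") {
    model <- build_simba_model(study, outcome = outcome,
                               parameterization = "rn_projection", ...)
    draws <- fit_simba(model, control)
  } else {
    nls_table <- nls_table %||% fit_cohort_nls(study, "srtm")
    inp <- pumba_input(nls_table, study$participants)
    draws <- fit_pumba(inp, parameterization = "rn_projection",
                       rn_region = study$config$rn_region %||% "RN",
                       projection_regions =
                         study$config$projection_regions,
                       control = control, ...)
  }
  b_rn <- contrast_draws(draws$draws, g, "RN")
  b_proj <- contrast_draws(draws$draws, g, "proj")
  sl <- draws$draws[, "bp.sd_slope"]
  list(p_rn_gt_proj = mean(b_rn - b_proj > 0),
       rn = summarize_contrast(b_rn),
       proj = summarize_contrast(b_proj),
       sd_slope = c(mean = mean(sl), lo95 = unname(quantile(sl, 0.025)),
                    hi95 = unname(quantile(sl, 0.975))),
       draws = draws)
}

#' Smooth-drift analysis of the plasma-free fraction
#'
#' Regresses log fP on group with and without a penalized cubic-spline
#' smooth of scan date (basis dimension 10, smoothing parameter chosen by
#' generalized cross-validation), and reports the group test from both
#' models — the logic used to probe whether apparent group differences in
#' fP could be explained by assay drift over the study years.
#'
#' @param fp Measured plasma-free fractions (> 0).
#' @param dates Numeric scan dates (decimal years).
#' @param groups Group labels.
#' @return List with `group_test_no_smooth` and `group_test_smooth`
#'   (F statistic, df, p-value), `smooth_test` (F, edf, p-value) and the
#'   two fits.
#' @export
fp_drift_analysis <- function(fp, dates, groups) {
  stopifnot(length(fp) == length(dates), length(fp) == length(groups))
  if (length(fp) < 20) stop("at least 20 observations required")
  if (sd(dates) == 0) stop("all dates identical")
  d <- data.frame(lfp = log(fp), date = dates,
                  group = factor(groups))
  lm_fit <- lm(lfp ~ group, data = d)
  an <- anova(lm_fit)
  gam_fit <- mgcv::gam(lfp ~ group + s(date, k = 10, bs = "cr"),
                       data = d, method = "GCV.Cp")
  sm <- summary(gam_fit)
  pt <- sm$pTerms.table
  st <- sm$s.table
  list(
    group_test_no_smooth = c(F = an["group", "F value"],
                             df = an["group", "Df"],
                             p = an["group", "Pr(>F)"]),
    group_test_smooth = c(F = unname(pt["group", "F"]),
                          df = unname(pt["group", "df"]),
                          p = unname(pt["group", "p-value"])),
    smooth_test = c(F = unname(st[1, "F"]), edf = unname(st[1, "edf"]),
                    p = unname(st[1, "p-value"])),
    lm_fit = lm_fit, gam_fit = gam_fit)
}

#' Prior mass of the group-difference prior
#'
#' Probability mass that a Normal(0, `sd`) prior on a log-scale group
#' difference assigns to percent differences below (or above) a cutoff.
#' `two_sided_log` returns `P(|beta| < log(1 + pct))`; `one_sided`
#' returns `P(beta > log(1 + pct))`.
#'
#' @param sd Prior SD on the log scale (> 0).
#' @param pct Percent difference cutoff as a fraction (0.2 = 20%), > 0.
#' @param sided `"two_sided_log"` or `"one_sided"`.
#' @return Probability.
#' @export
prior_mass <- function(sd = 0.2, pct, sided = c("two_sided_log",
                                                "one_sided")) {
  sided <- match.arg(sided)
  stopifnot(sd > 0, pct > 0)
  cut <- log(1 + pct)
  if (sided == "two_sided_log") {
    2 * pnorm(cut / sd) - 1
  } else {
    1 - pnorm(cut / sd)
  }
}

#' Sample size per group for a two-sample t-test
#'
#' Smallest integer n per group giving at least the target power for a
#' two-sided two-sample t-test at effect size d, computed by noncentral-t
#' iteration: with df = 2n - 2 and noncentrality `d * sqrt(n / 2)`,
#' power = `P(|T| > t_crit)`.
#'
#' @param d Cohen's d, > 0.
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param n_max Search cap.
#' @return Integer n per group.
#' @export
power_n_per_group <- function(d, power = 0.8, alpha = 0.05,
                              n_max = 1e7) {
  if (d <= 0) stop("d must be positive")
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1)
  pow <- function(n) {
    df <- 2 * n - 2
    tc <- qt(1 - alpha / 2, df)
    ncp <- d * sqrt(n / 2)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  }
  lo <- 2; hi <- 2
  while (pow(hi) < power) {
    hi <- hi * 2
    if (hi > n_max) stop("required n exceeds n_max")
  }
  while (hi - lo > 0) {
    mid <- (lo + hi) %/% 2
    if (pow(mid) >= power) hi <- mid else lo <- mid + 1
  }
  as.integer(hi)
}

#' Probability of superiority for a standardized effect
#'
#' The probability that a random member of the shifted group exceeds a
#' random member of the reference group under normality with common
#' variance: `Phi(d / sqrt(2))`.
#'
#' @param d Cohen's d (finite).
#' @return Probability.
#' @export
prob_superiority <- function(d) {
  stopifnot(is.finite(d))
  pnorm(d / sqrt(2))
}

#' Per-subgroup individual-level correlation matrices
#'
#' Fits the hierarchical model to each subgroup of a study independently
#' and compares the estimated individual-level cross-parameter
#' correlation matrices — a check of the shared-correlation assumption of
#' the multivariate models.
#'
#' @param study A `synthetic_study` or study bundle.
#' @param groups Subgroups to fit (default all).
#' @param method `"simba"` (default, binding-potential outcome from the
#'   simultaneous model) or `"pumba"`.
#' @param outcome 2TCM variant for `"simba"`.
#' @param nls_table Precomputed SRTM NLS table for `"pumba"`.
#' @param control An [mcmc_control()].
#' @param min_n Smallest subgroup size that will be fitted.
#' @return List with `matrices` (posterior-mean correlation matrix per
#'   group), `max_abs_diff` and `frobenius` (pairwise comparison tables).
#' @export
subgroup_correlations <- function(study, groups = NULL,
                                  method = c("simba", "pumba"),
                                  outcome = "bpnd", nls_table = NULL,
                                  control = mcmc_control(), min_n = 5) {
  method <- match.arg(method)
  groups <- groups %||% unique(study$participants$group)
  mats <- list()
  for (g in groups) {
    sids <- study$participants$subject_id[study$participants$group == g]
    if (length(sids) < min_n) {
      stop("group ", g, " has fewer than ", min_n, " subjects")
    }
    if (method == "simba") {
      model <- build_simba_model(study, outcome = outcome,
                                 subjects = sids)
      draws <- fit_simba(model, control)
    } else {
      nls_table <- nls_table %||% fit_cohort_nls(study, "srtm")
      sub_tab <- nls_table[nls_table$subject_id %in% sids, ]
      part <- study$participants[study$participants$subject_id %in% sids, ]
      inp <- pumba_input(sub_tab, part)
      draws <- fit_pumba(inp, control = control)
    }
    labs <- draws$meta$param_labels
    P <- length(labs)
    M <- diag(1, P)
    dimnames(M) <- list(labs, labs)
    pairs <- utils::combn(labs, 2)
    for (j in seq_len(ncol(pairs))) {
      nm <- paste0("tau_cor[", pairs[1, j], ",", pairs[2, j], "]")
      val <- mean(draws$draws[, nm])
      M[pairs[1, j], pairs[2, j]] <- M[pairs[2, j], pairs[1, j]] <- val
    }
    mats[[g]] <- M
  }
  gp <- names(mats)
  cmp <- list()
  if (length(gp) > 1) {
    pr <- utils::combn(gp, 2)
    cmp <- lapply(seq_len(ncol(pr)), function(j) {
      D <- mats[[pr[1, j]]] - mats[[pr[2, j]]]
      tibble::tibble(group1 = pr[1, j], group2 = pr[2, j],
                     max_abs_diff = max(abs(D)),
                     frobenius = sqrt(sum(D^2)))
    })
    cmp <- do.call(rbind, cmp)
  }
  list(matrices = mats, comparison = cmp)
}
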