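test_that("prior mass matches closed-form normal probabilities", {
  expect_equal(prior_mass(0.2, 0.2), 2 * pnorm(log(1.2) / 0.2) - 1,
               tolerance = 1e-12)
  expect_equal(prior_mass(0.2, 0.3, "one_sided"),
               1 - pnorm(log(1.3) / 0.2), tolerance = 1e-12)
  expect_equal(round(prior_mass(0.2, 0.2), 2), 0.64)
  expect_equal(round(prior_mass(0.2, 0.3), 2), 0.81)
  expect_equal(round(prior_mass(0.2, 0.3, "one_sided"), 2), 0.09)
  # the two conventions for a 10% difference (documented discrepancy)
  expect_equal(round(prior_mass(0.2, 0.1, "one_sided"), 2), 0.32)
  expect_equal(round(prior_mass(0.2, 0.1), 2), 0.37)
  expect_error(prior_mass(-1, 0.2))
})

test_that("contrast summaries match a direct quantile oracle", {
  set.seed(99)
  b <- rnorm(10000, 0.1, 0.05)
  draws <- matrix(b, ncol = 1,
                  dimnames = list(NULL, "bp.eff[NRM:RN]"))
  fit <- structure(list(draws = draws,
                        meta = list(regions = "RN",
                                    parameterization = "group_region")),
                   class = "pet_draws")
  ctr <- group_contrasts(fit, "NRM-HV", regions = "RN")
  pct <- 100 * (exp(b) - 1)
  expect_equal(ctr$percent, mean(pct))
  expect_equal(ctr$lo95, unname(quantile(pct, 0.025)))
  expect_equal(ctr$hi80, unname(quantile(pct, 0.90)))
  expect_equal(ctr$p_gt0, mean(b > 0))
  # interval nesting and degenerate cases
  expect_true(ctr$lo95 <= ctr$lo80 && ctr$hi80 <= ctr$hi95)
  draws0 <- matrix(rep(0, 100), ncol = 1,
                   dimnames = list(NULL, "bp.eff[NRM:RN]"))
  fit0 <- structure(list(draws = draws0,
                         meta = list(regions = "RN",
                                     parameterization = "group_region")),
                    class = "pet_draws")
  c0 <- group_contrasts(fit0, "NRM-HV", regions = "RN")
  expect_equal(c0$percent, 0)
  draws1 <- matrix(rep(log(1.1), 100), ncol = 1,
                   dimnames = list(NULL, "bp.eff[NRM:RN]"))
  fit1 <- structure(list(draws = draws1,
                         meta = list(regions = "RN",
                                     parameterization = "group_region")),
                    class = "pet_draws")
  c1 <- group_contrasts(fit1, "NRM-HV", regions = "RN")
  expect_equal(c1$percent, 10, tolerance = 1e-9)
  expect_equal(c1$p_gt0, 1)
  # monotone transform preserves draw ordering
  expect_equal(order(b), order(100 * (exp(b) - 1)))
})

test_that("univariate LME collapses to ordinary regression for one region", {
  set.seed(12)
  n <- 30
  d <- data.frame(
    subject_id = sprintf("s%02d", 1:(2 * n)),
    region = "RN", group = rep(c("HV", "NRM"), each = n),
    sex = rbinom(2 * n, 1, 0.5), age = runif(2 * n, 20, 60))
  d$logBP <- 0.5 + 0.2 * (d$group == "NRM") + rnorm(2 * n, 0, 0.1)
  fit <- suppressWarnings(fit_univariate_lme(d))
  ctr <- group_contrasts(fit, "NRM-HV", regions = "RN")
  ols <- lm(logBP ~ sex + I((age - mean(age)) / 10) + I(group == "NRM"),
            data = d)
  expect_equal(ctr$est_log, unname(coef(ols)[4]), tolerance = 1e-6)
})

test_that("sample-size iteration matches the independent noncentral-t oracle", {
  oracle <- function(d) {
    ceiling(stats::power.t.test(delta = d, sd = 1, power = 0.8,
                                sig.level = 0.05)$n)
  }
  expect_equal(power_n_per_group(1.0), oracle(1.0))
  expect_equal(power_n_per_group(0.5), oracle(0.5))
  expect_equal(power_n_per_group(1.0), 17L)
  expect_equal(power_n_per_group(0.5), 64L)
  ds <- seq(0.2, 1.4, by = 0.1)
  ns <- sapply(ds, power_n_per_group)
  expect_true(all(diff(ns) <= 0))
  expect_error(power_n_per_group(0), "positive")
})

test_that("probability of superiority is Phi(d / sqrt(2))", {
  expect_equal(prob_superiority(0), 0.5)
  expect_equal(prob_superiority(0.32), pnorm(0.32 / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(round(prob_superiority(0.32), 3), 0.59)
  expect_gt(prob_superiority(8), 1 - 1e-8)
  # numerical integration oracle for the defining two-sample probability
  f <- function(x) dnorm(x, 0.32) * pnorm(x)
  expect_equal(prob_superiority(0.32),
               integrate(f, -Inf, Inf, rel.tol = 1e-12)$value,
               tolerance = 1e-10)
})

test_that("fP drift analysis separates drift from true group offsets", {
  set.seed(4)
  n <- 60
  # true offsets, homogeneous dates: group test significant both ways
  cfg_off <- cohort_config(fp_confound = FALSE)
  g <- rep(c("HV", "NRM", "AE"), each = n)
  dates <- runif(3 * n, 1999, 2009)
  fp <- simulate_fp(g, dates, cfg_off)
  res <- fp_drift_analysis(fp, dates, g)
  expect_lt(res$group_test_no_smooth["p"], 0.01)
  expect_lt(res$group_test_smooth["p"], 0.01)
  # pure drift + inhomogeneous sampling: attenuated once smooth included
  cfg_dr <- cohort_config(fp_confound = TRUE, fp_noise_sd = 0.10)
  dates2 <- pmin(pmax(rnorm(3 * n, rep(c(2001, 2006.5, 2004), each = n),
                            1.2), 1999), 2009)
  fp2 <- simulate_fp(g, dates2, cfg_dr)
  res2 <- fp_drift_analysis(fp2, dates2, g)
  expect_lt(res2$group_test_no_smooth["p"], 0.01)
  expect_lt(res2$smooth_test["p"], 0.01)
  expect_gt(res2$group_test_smooth["p"] / res2$group_test_no_smooth["p"],
            10)
  # constant fP: flat smooth, null-calibrated group test
  fp3 <- rep(0.07, 3 * n) * exp(rnorm(3 * n, 0, 0.05))
  res3 <- fp_drift_analysis(fp3, dates, g)
  expect_lt(res3$smooth_test["edf"], 3)
  expect_gt(res3$group_test_smooth["p"], 0.01)
  expect_error(fp_drift_analysis(fp3[1:10], dates[1:10], g[1:10]),
               "at least 20")
  expect_error(fp_drift_analysis(fp3, rep(2000, 3 * n), g), "identical")
})

test_that("subgroup correlation matrices are compared faithfully", {
  set.seed(55)
  n_per <- 20
  part <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:(3 * n_per)),
    group = rep(c("HV", "NRM", "AE"), each = n_per),
    age = runif(3 * n_per, 25, 60), sex = rbinom(3 * n_per, 1, 0.5))
  regions <- c("ACC", "HIP", "RN")
  # HV and NRM share a +0.7 R1/BP correlation; AE has -0.7 (antithetic)
  mk_rows <- function(sid, rho) {
    Sig <- diag(c(0.15, 0.1, 0.25)^2)
    Sig[1, 3] <- Sig[3, 1] <- rho * 0.15 * 0.25
    tau_i <- rmvnorm_chol_test(1, rep(0, 3), Sig)
    do.call(rbind, lapply(regions, function(r) {
      y <- c(log(0.9), log(0.15), log(2.5)) + tau_i + rnorm(3, 0, 0.05)
      tibble::tibble(subject_id = sid, region = r,
                     parameter = c("logR1", "logk2prime", "logBPND"),
                     estimate_log = y, converged = TRUE)
    }))
  }
  tab <- do.call(rbind, lapply(seq_len(3 * n_per), function(i) {
    mk_rows(part$subject_id[i],
            if (part$group[i] == "AE") -0.7 else 0.7)
  }))
  study <- list(participants = part, config = list(rn_region = "RN"))
  res <- subgroup_correlations(study, method = "pumba", nls_table = tab,
                               control = fast_mcmc(seed = 7, warmup = 200,
                                                   iter = 200))
  for (M in res$matrices) expect_equal(unname(diag(M)), rep(1, 3))
  cmp <- res$comparison
  d_hv_nrm <- cmp$max_abs_diff[cmp$group1 == "HV" & cmp$group2 == "NRM"]
  d_hv_ae <- cmp$max_abs_diff[cmp$group1 == "HV" & cmp$group2 == "AE"]
  # matched-correlation groups agree; the antithetic group stands out
  expect_lt(d_hv_nrm, 0.4)
  expect_gt(d_hv_ae, 2 * d_hv_nrm)
  expect_gt(res$matrices$HV["R1", "BPND"], 0.2)
  expect_lt(res$matrices$AE["R1", "BPND"], -0.2)
  expect_error(subgroup_correlations(study, groups = "HV",
                                     method = "pumba", nls_table = tab,
                                     min_n = 50), "fewer than")
})
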