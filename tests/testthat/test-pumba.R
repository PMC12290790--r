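# Multivariate analysis of pre-estimated parameters: generative
# self-consistency, structural collapse, and the RN-vs-projection
# parameterization.

test_that("input assembly keeps only complete converged vectors", {
  tab <- tibble::tibble(
    subject_id = rep(c("a", "a", "b"), each = 3),
    region = rep(c("R1", "R2", "R1"), each = 3),
    parameter = rep(c("logR1", "logk2prime", "logBPND"), 3),
    estimate_log = rnorm(9),
    converged = c(rep(TRUE, 6), TRUE, FALSE, TRUE))
  part <- tibble::tibble(subject_id = c("a", "b"), group = c("HV", "NRM"),
                         age = c(30, 40), sex = c(0, 1))
  inp <- pumba_input(tab, part)
  expect_equal(nrow(inp$Y), 2)   # b/R1 dropped: one component unconverged
  expect_equal(colnames(inp$Y), c("logR1", "logk2prime", "logBPND"))
})

test_that("fixed effects are recovered from the generative model", {
  # simulate directly from the multivariate response model
  set.seed(33)
  S <- 45; regions <- c("ACC", "HIP", "RN")
  part <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:S),
    group = rep(c("HV", "NRM", "AE"), each = 15),
    age = runif(S, 25, 60), sex = rbinom(S, 1, 0.5))
  mu <- c(logR1 = log(0.9), logk2prime = log(0.15), logBPND = log(2.5))
  Sig_ind <- diag(c(0.1, 0.1, 0.2)^2)
  Sig_res <- diag(c(0.05, 0.05, 0.1)^2)
  eff_rn <- 0.25
  rows <- list()
  for (i in 1:S) {
    tau_i <- as.vector(rmvnorm_chol_test(1, rep(0, 3), Sig_ind))
    for (r in regions) {
      y <- mu + tau_i + as.vector(rmvnorm_chol_test(1, rep(0, 3),
                                                    Sig_res))
      if (part$group[i] == "NRM" && r == "RN") y[3] <- y[3] + eff_rn
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = part$subject_id[i], region = r,
        parameter = names(mu), estimate_log = unname(y),
        converged = TRUE)
    }
  }
  inp <- pumba_input(do.call(rbind, rows), part)
  dr <- fit_pumba(inp, control = fast_mcmc(seed = 3, warmup = 400,
                                           iter = 400))
  ctr <- group_contrasts(dr, "NRM-HV", regions = "RN")
  # injected effect inside the 95% interval and clearly positive
  expect_gt(ctr$p_gt0, 0.9)
  expect_gt(ctr$hi95, 100 * (exp(eff_rn) - 1) - 10)
  expect_lt(ctr$lo95, 100 * (exp(eff_rn) - 1) + 10)
  # null regions stay near zero
  c0 <- group_contrasts(dr, "AE-HV", regions = "ACC")
  expect_lt(abs(c0$est_log), 0.15)
  # residual and individual-level scales separate
  d <- dr$draws
  expect_lt(mean(d[, "res_sd[BPND]"]), mean(d[, "tau_sd[BPND]"]))
})

test_that("a single region degrades to subject-level regression", {
  set.seed(44)
  S <- 24
  part <- tibble::tibble(subject_id = sprintf("s%02d", 1:S),
                         group = rep(c("HV", "NRM"), each = 12),
                         age = runif(S, 25, 60), sex = rbinom(S, 1, 0.5))
  tab <- tibble::tibble(
    subject_id = rep(part$subject_id, each = 3),
    region = "RN",
    parameter = rep(c("logR1", "logk2prime", "logBPND"), S),
    estimate_log = rnorm(3 * S, rep(c(0, -1.9, 0.8), S), 0.1) +
      rep(0.3 * (part$group == "NRM"), each = 3) *
        rep(c(0, 0, 1), S),
    converged = TRUE)
  inp <- pumba_input(tab, part)
  dr <- fit_pumba(inp, control = fast_mcmc(seed = 4))
  ctr <- group_contrasts(dr, "NRM-HV", regions = "RN")
  expect_gt(ctr$p_gt0, 0.95)
  expect_lt(abs(ctr$est_log - 0.3), 0.12)
})

test_that("srtm pipeline feeds pumba and supports rn_projection", {
  st <- tiny_cohort(seed = 13, n = c(5, 5, 4),
                    regions = c("ACC", "HIP", "AMY", "RN"),
                    include_reference = TRUE)
  srtm <- fit_cohort_nls(st, "srtm", seed = 6, n_starts = 3)
  expect_false("CWM" %in% srtm$region)
  inp <- pumba_input(srtm, st$participants)
  res <- rn_vs_projection(st, method = "pumba", nls_table = srtm,
                          control = fast_mcmc(seed = 5))
  expect_true(res$p_rn_gt_proj >= 0 && res$p_rn_gt_proj <= 1)
  expect_true(all(res$sd_slope >= 0))
  expect_true(is.finite(res$rn$percent))
})
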