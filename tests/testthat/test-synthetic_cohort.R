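test_that("simulated input function has the documented structure", {
  a1 <- simulate_aif(7)
  expect_equal(a1$c_wholeplasma(0), 0)
  expect_equal(a1$cp_parent(0), 0)
  a2 <- simulate_aif(14)
  tt <- c(0.5, 1, 2, 5, 20, 60, 110)
  expect_equal(a2$c_wholeplasma(tt), 2 * a1$c_wholeplasma(tt))
  # parent fraction monotone non-increasing
  pf <- a1$cp_parent(tt) / pmax(a1$c_wholeplasma(tt), 1e-12)
  pf <- pf[a1$c_wholeplasma(tt) > 0]
  expect_true(all(diff(pf) <= 1e-12))
  expect_true(all(pf >= 0 & pf <= 1))
  expect_error(simulate_aif(-1))
})

test_that("fP simulation reproduces offsets and the drift confound", {
  cfg_off <- cohort_config(fp_confound = FALSE)
  set.seed(2)
  n <- 4000
  g <- rep(c("HV", "NRM"), each = n)
  dates <- runif(2 * n, 1999, 2009)
  fp <- simulate_fp(g, dates, cfg_off)
  ratio <- mean(fp[g == "NRM"]) / mean(fp[g == "HV"])
  want <- exp(cfg_off$fp$offsets["NRM"] - cfg_off$fp$offsets["HV"])
  expect_equal(unname(ratio), unname(want), tolerance = 0.03)
  # zero offsets, zero drift, zero noise: constant fP
  cfg0 <- cohort_config(fp_confound = FALSE,
                        fp_offsets = c(HV = 0, AE = 0, NRM = 0),
                        fp_noise_sd = 0)
  expect_equal(simulate_fp(c("HV", "AE"), c(2000, 2008), cfg0),
               rep(cfg0$fp$base, 2))
  # drift-only: inhomogeneous sampling induces apparent group differences
  cfg_dr <- cohort_config(fp_confound = TRUE)
  d_hv <- pmin(pmax(rnorm(n, 2002, 2.2), 1999), 2009)
  d_nrm <- pmin(pmax(rnorm(n, 2006, 2.2), 1999), 2009)
  fp2 <- simulate_fp(rep(c("HV", "NRM"), each = n), c(d_hv, d_nrm),
                     cfg_dr)
  expect_lt(mean(fp2[(n + 1):(2 * n)]), 0.93 * mean(fp2[1:n]))
})

test_that("cohort generation is deterministic and moment-faithful", {
  cfg <- cohort_config(n_hv = 3, n_nrm = 3, n_ae = 3,
                       regions = c("ACC", "RN"))
  s1 <- simulate_cohort(cfg, seed = 77)
  s2 <- simulate_cohort(cfg, seed = 77)
  expect_identical(s1$tacs, s2$tacs)
  expect_identical(s1$participants, s2$participants)
  s3 <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(s1$tacs$activity, s3$tacs$activity))

  # moments of the generated parameters match the configuration
  big <- cohort_config(n_hv = 400, n_nrm = 300, n_ae = 300,
                       regions = c("ACC", "HIP", "RN"))
  st <- simulate_cohort(big, seed = 5, tacs = FALSE)
  lam <- st$truth$lambda
  g <- st$participants$group
  hv_bp <- lam[g == "HV", "ACC", "BP"]
  expect_equal(mean(hv_bp), big$region_means["ACC", "BP"],
               tolerance = 0.05)
  expect_equal(sd(hv_bp),
               sqrt(big$between_sd["BP"]^2 + big$tac_jitter_sd["BP"]^2),
               tolerance = 0.05, ignore_attr = TRUE)
  # injected group effects recovered from the truth ledger (3 sigma of
  # the group-mean difference of correlated subject deviations)
  expect_lt(abs(mean(lam[g == "NRM", "RN", "BP"]) -
                  mean(lam[g == "HV", "RN", "BP"]) - 0.15), 0.06)
  expect_lt(abs(mean(lam[g == "NRM", "ACC", "BP"]) -
                  mean(lam[g == "HV", "ACC", "BP"]) - 0.075), 0.06)
  expect_lt(abs(mean(lam[g == "AE", "RN", "BP"]) -
                  mean(lam[g == "HV", "RN", "BP"])), 0.06)
  # the RN-minus-projection contrast cancels the shared deviations and
  # pins the regional specificity tightly
  rn_minus_acc <- (mean(lam[g == "NRM", "RN", "BP"]) -
                     mean(lam[g == "NRM", "ACC", "BP"])) -
    (mean(lam[g == "HV", "RN", "BP"]) -
       mean(lam[g == "HV", "ACC", "BP"]))
  expect_equal(rn_minus_acc, 0.075, tolerance = 0.3)
})

test_that("generated cross-parameter correlations match the config", {
  big <- cohort_config(n_hv = 250, n_nrm = 150, n_ae = 150,
                       regions = c("ACC", "HIP", "AMY", "RN"))
  st <- simulate_cohort(big, seed = 6, tacs = FALSE)
  lam <- st$truth$lambda
  # average across regions isolates the individual-level deviation
  indiv <- apply(lam, c(1, 3), mean)
  C <- cor(indiv)
  expect_lt(max(abs(C - big$between_cor)), 0.1)
})

test_that("zero noise reproduces exact model curves and null effects hold", {
  cfg <- cohort_config(n_hv = 2, n_nrm = 2, n_ae = 2,
                       regions = c("ACC", "RN"), noise_cv = 0,
                       effect_nrm_rn = 0, effect_nrm_proj = 0)
  st <- simulate_cohort(cfg, seed = 8)
  sid <- st$participants$subject_id[1]
  lam <- st$truth$lambda[sid, "ACC", ]
  p <- tcm2_params(exp(lam["K1"]), exp(lam["K1"]) / exp(lam["VND"]),
                   exp(lam["BP"]) * exp(lam["k4"]), exp(lam["k4"]),
                   exp(lam["vB"]))
  model <- solve_2tcm(p, st$aif[[sid]], st$schedule, dt = cfg$dt)
  obs <- st$tacs$activity[st$tacs$subject_id == sid &
                            st$tacs$region == "ACC"]
  expect_equal(obs, model$activity, tolerance = 1e-12)
  expect_equal(unname(st$truth$group_effects["NRM", ]), c(0, 0),
               ignore_attr = TRUE)
})
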