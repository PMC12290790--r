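# Hierarchical simultaneous model: structural checks use a small cohort
# and short adaptive chains; statistical recovery checks use generous
# tolerances consistent with those settings.

simba_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- tiny_cohort(seed = 42, n = c(4, 4, 4),
                        regions = c("ACC", "HIP", "RN"))
      m <- build_simba_model(st, "bpnd")
      dr <- suppressWarnings(fit_simba(m, fast_mcmc(seed = 1)))
      cache <<- list(study = st, model = m, draws = dr)
    }
    cache
  }
})

test_that("model assembly encodes the covariate structure", {
  fx <- simba_fixture()
  m <- fx$model
  bp_cols <- colnames(m$des[[3]]$X)
  expect_true(all(paste0("bp.mu[", m$regions, "]") %in% bp_cols))
  expect_true(all(c("bp.sex", "bp.age") %in% bp_cols))
  # one group:region coefficient per non-reference group per region,
  # no overall group main effect
  expect_setequal(grep("bp.eff", bp_cols, value = TRUE),
                  c(paste0("bp.eff[NRM:", m$regions, "]"),
                    paste0("bp.eff[AE:", m$regions, "]")))
  expect_false("bp.group" %in% bp_cols)
  # age+sex enter K1 and VND, not k4/vB
  expect_true(all(c("k1.sex", "k1.age") %in% colnames(m$des[[1]]$X)))
  expect_true(all(c("vnd.sex", "vnd.age") %in% colnames(m$des[[2]]$X)))
  expect_equal(colnames(m$des[[4]]$X), "k4.int")
  expect_equal(colnames(m$des[[5]]$X), "vb.int")
  # group-difference prior SD is 0.2 on every group:region coefficient
  expect_true(all(m$priors$beta_sd[[3]][grep("bp.eff", bp_cols)] == 0.2))
  expect_error(build_simba_model(
    within.list(fx$study, participants$age[1] <- NA), "bpnd"),
    "complete")
})

test_that("posterior recovers latent parameters and injected RN effect", {
  fx <- simba_fixture()
  dr <- fx$draws
  truth <- fx$study$truth$lambda
  key <- dr$meta$tac_key
  lt <- mapply(function(s, r) truth[s, r, "BP"], key$subject_id,
               key$region)
  rmse <- sqrt(mean((dr$lambda_mean[, 3] - lt)^2))
  expect_lt(rmse, 0.35)
  # region intercept posterior means are in the right neighbourhood
  mu <- colMeans(dr$draws[, paste0("bp.mu[", dr$meta$regions, "]")])
  expect_lt(max(abs(mu - fx$study$config$region_means[dr$meta$regions,
                                                      "BP"])), 0.5)
  expect_true(all(is.finite(dr$diagnostics$rhat)))
})

test_that("individual deviations are centered and shrink toward zero", {
  fx <- simba_fixture()
  eff <- extract_individual_effects(fx$draws, "BP")
  expect_equal(nrow(eff), 12)
  expect_equal(mean(eff$post_mean), 0, tolerance = 1e-8)
  expect_true(all(eff$post_sd > 0))
  # shrinkage: posterior-mean deviations are less dispersed than the raw
  # per-subject mean NLS deviations they pool
  nls <- fit_cohort_nls(fx$study, "2tcm", "bpnd", seed = 2, n_starts = 2)
  bp <- nls[nls$parameter == "logBPND", ]
  raw_dev <- tapply(bp$estimate_log, bp$subject_id, mean) -
    mean(bp$estimate_log)
  expect_lt(sd(eff$post_mean), sd(raw_dev) + 0.05)
  expect_error(extract_individual_effects(fx$draws, "nope"), "unknown")
})

test_that("regional VND deviations sum to zero per draw", {
  fx <- simba_fixture()
  p <- match("VND", fx$draws$meta$ups_params)
  sums <- apply(fx$draws$upsilon[, , p], 1, sum)
  expect_lt(max(abs(sums)), 1e-10)
  tab <- region_vnd_deviations(fx$draws)
  expect_equal(tab$region, fx$draws$meta$regions)
  expect_true(all(tab$lo95 <= tab$percent & tab$percent <= tab$hi95))
})

test_that("a region simulated with lower VND shows a negative deviation", {
  cfg <- cohort_config(n_hv = 4, n_nrm = 4, n_ae = 4,
                       regions = c("ACC", "HIP", "RN"))
  cfg$region_means["RN", "VND"] <- cfg$region_means["RN", "VND"] +
    log(0.65)   # extra 35% lower
  st <- simulate_cohort(cfg, seed = 10)
  m <- build_simba_model(st, "bpnd")
  dr <- suppressWarnings(fit_simba(m, fast_mcmc(seed = 2)))
  tab <- region_vnd_deviations(dr)
  rn <- tab[tab$region == "RN", ]
  expect_lt(rn$percent, 0)
  expect_lt(rn$hi95, 0)
})

test_that("posterior means of the error model are sane", {
  fx <- simba_fixture()
  d <- fx$draws$draws
  expect_gt(min(d[, "nu"]), 3)
  expect_true(all(d[, grep("sd_", colnames(d))] > 0))
  cors <- d[, grep("tau_cor", colnames(d)), drop = FALSE]
  expect_true(all(cors > -1 & cors < 1))
})

test_that("raphe-vs-projection refit reports the regional specificity", {
  st <- tiny_cohort(seed = 15, n = c(5, 5, 4),
                    regions = c("ACC", "HIP", "RN"))
  res <- suppressWarnings(
    rn_vs_projection(st, method = "simba",
                     control = mcmc_control(chains = 1, warmup = 200,
                                            iter = 200, seed = 3)))
  d <- res$draws$draws
  expect_true(all(c("bp.eff[NRM:RN]", "bp.eff[NRM:proj]",
                    "bp.eff[AE:RN]", "bp.eff[AE:proj]",
                    "bp.sd_slope") %in% colnames(d)))
  expect_true(res$p_rn_gt_proj >= 0 && res$p_rn_gt_proj <= 1)
  expect_true(all(res$sd_slope >= 0))
  expect_true(is.finite(res$rn$percent) && is.finite(res$proj$percent))
  ctr <- group_contrasts(res$draws, "NRM-HV")
  expect_setequal(ctr$region, c("RN", "proj"))
})
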