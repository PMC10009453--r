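test_that("panel estimation recovers per-trait causal effects", {
  cfg <- sim_config(n_snp = 80, panel_n_traits = 3, panel_rho = 0.2,
                    panel_theta = c(0.3, 0, -0.2), seed = 61)
  sim <- simulate_study(cfg, components = "panel")
  p <- run_panel(sim$exposure, sim$panel, methods = "ivw", seed = 1,
                 scale = FALSE)
  est <- vapply(p$fits, function(f) f$estimates$ivw$beta, numeric(1))
  ses <- vapply(p$fits, function(f) f$estimates$ivw$se, numeric(1))
  expect_lt(abs(est[["trait_01"]] - 0.3), 4 * ses[["trait_01"]])
  expect_lt(abs(est[["trait_02"]] - 0), 4 * ses[["trait_02"]])
  expect_lt(abs(est[["trait_03"]] + 0.2), 4 * ses[["trait_03"]])
})

test_that("a single-outcome panel equals a direct fit and reruns are identical", {
  cfg <- sim_config(n_snp = 40, seed = 67)
  sim <- simulate_study(cfg, components = "outcome")
  p <- run_panel(sim$exposure, list(outcome_1 = sim$outcome),
                 n_boot = 150, seed = 10)
  h <- harmonise(sim$exposure, sim$outcome)
  direct <- mr_fit(h, n_boot = 150, seed = revmr:::child_seed(10, 1))
  expect_equal(coef(p$fits$outcome_1), coef(direct))

  p2 <- run_panel(sim$exposure, list(outcome_1 = sim$outcome),
                  n_boot = 150, seed = 10)
  expect_identical(as.data.frame(p), as.data.frame(p2))
})

test_that("failures on individual outcomes are recorded, not fatal", {
  cfg <- sim_config(n_snp = 40, seed = 71)
  sim <- simulate_study(cfg, components = "outcome")
  # an outcome sharing no variants with the exposure cannot be harmonised
  alien <- make_ss(beta = c(0.1, 0.2, 0.1), se = 0.02,
                   rsid = paste0("rsX", 1:3), trait_type = "continuous",
                   trait_name = "alien")
  p <- run_panel(sim$exposure,
                 list(good = sim$outcome, broken = alien),
                 methods = "ivw", seed = 1)
  expect_named(p$fits, "good")
  expect_named(p$failures, "broken")

  expect_error(run_panel(sim$exposure, list(a = alien, b = alien),
                         methods = "ivw", seed = 1),
               "panel error")
})

test_that("stratum contrasts follow the two-sample z formula", {
  a <- make_panel(betas = c(0.2, 0.1), ses = c(0.05, 0.05),
                  stratum = "young")
  b <- make_panel(betas = c(0, 0.1), ses = c(0.05, 0.05), stratum = "old")
  sc <- stratum_contrast(a, b)
  expect_equal(sc$delta, c(0.2, 0))
  expect_equal(sc$z[1], 0.2 / sqrt(2 * 0.05^2))
  expect_equal(sc$z[1], 2.828, tolerance = 1e-3)
  expect_equal(sc$pval[2], 1)

  same <- stratum_contrast(a, a)
  expect_equal(same$delta, c(0, 0))
  expect_equal(same$pval, c(1, 1))

  c_mismatch <- make_panel(betas = 0.1, ses = 0.05)
  expect_error(stratum_contrast(a, c_mismatch), "alignment error")
})

test_that("contrast p-values are uniform when strata share the same effect", {
  n_rep <- 300
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_snp = 50, theta = 0.2, strata_modifier = 0,
                      n_out = 30000, seed = 1000 + r)
    sim <- simulate_study(cfg, components = "strata")
    pa <- run_panel(sim$exposure,
                    stats::setNames(sim$strata[1], "out"),
                    methods = "ivw", seed = 1, scale = FALSE,
                    stratum_label = "young")
    pb <- run_panel(sim$exposure,
                    stats::setNames(sim$strata[3], "out"),
                    methods = "ivw", seed = 1, scale = FALSE,
                    stratum_label = "old")
    pvals[r] <- stratum_contrast(pa, pb)$pval
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.6)
})

test_that("effective tests come from the eigen-spectrum of the trait correlation", {
  eye <- diag(20); dimnames(eye) <- NULL
  eff <- effective_tests_threshold(eye, 0.95, 0.05)
  expect_equal(eff$n_components, 19L)  # ceil(0.95 * 20) equal eigenvalues

  ones <- matrix(1, 10, 10)
  expect_equal(effective_tests_threshold(ones)$n_components, 1L)

  # alpha 0.05 over 33 components: 0.0015..., one significant figure 0.002
  eff33 <- effective_tests_threshold(diag(34), variance_fraction = 0.95,
                                     alpha = 0.05)
  expect_equal(eff33$n_components, 33L)
  expect_equal(eff33$threshold, 0.05 / 33)
  expect_equal(eff33$threshold_rounded, 0.002)

  # invariant to trait ordering
  set.seed(73)
  m <- cov2cor(crossprod(matrix(rnorm(200), 10, 20)))
  perm <- sample(20)
  expect_equal(effective_tests_threshold(m)$n_components,
               effective_tests_threshold(m[perm, perm])$n_components)

  expect_error(effective_tests_threshold(matrix(c(1, 0.2, 0.4, 1), 2)),
               "symmetric")
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(effective_tests_threshold(bad), "matrix error")
})

test_that("profile comparison is OLS across shared traits", {
  x <- seq(-0.2, 0.2, length.out = 10)
  p1 <- make_panel(betas = x, ses = rep(0.02, 10), exposure = "d1")
  p2 <- make_panel(betas = x, ses = rep(0.02, 10), exposure = "d2")
  pc <- profile_comparison(p1, p2)
  expect_equal(pc$slope, 1)
  expect_equal(pc$r2, 1)
  expect_equal(pc$n_traits, 10)

  set.seed(79)
  xr <- rnorm(200, 0, 0.1)
  yr <- rnorm(200, 0, 0.1)   # unrelated profiles
  pc2 <- profile_comparison(make_panel(xr, rep(0.02, 200)),
                            make_panel(yr, rep(0.02, 200)))
  expect_lt(abs(pc2$slope), 0.2)
  expect_lt(pc2$r2, 0.05)
  # matches lm directly
  expect_equal(pc2$slope, unname(coef(lm(yr ~ xr))[2]))

  # subsetting commutes with comparing
  sub <- paste0("trait_", 1:5)
  pc_sub <- profile_comparison(p1, p2, trait_subset = sub)
  p1s <- make_panel(betas = x[1:5], ses = rep(0.02, 5), exposure = "d1")
  p2s <- make_panel(betas = x[1:5], ses = rep(0.02, 5), exposure = "d2")
  pc_sub2 <- profile_comparison(p1s, p2s)
  expect_equal(pc_sub$slope, pc_sub2$slope)
  expect_equal(pc_sub$r2, pc_sub2$r2)

  expect_error(profile_comparison(make_panel(1:2 / 10, c(0.1, 0.1)),
                                  make_panel(1:2 / 10, c(0.1, 0.1))),
               "insufficient-traits")
})
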