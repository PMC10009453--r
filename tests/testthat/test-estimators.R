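test_that("Wald ratios follow the first-order formula", {
  h <- make_harmonised(bx = 0.2, sx = 0.01, by = 0.1, so = 0.02)
  wr <- wald_ratio(h)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wr$ci_low, 0.5 - qnorm(0.975) * 0.1)

  h1 <- make_harmonised(bx = 1, sx = 0.01, by = 0.37, so = 0.02)
  expect_equal(wald_ratio(h1)$ratio, 0.37)
  expect_equal(wald_ratio(h1)$se, 0.02)

  hneg <- make_harmonised(bx = -0.2, sx = 0.01, by = -0.1, so = 0.02)
  expect_equal(wald_ratio(hneg)$ratio, 0.5)

  h0 <- make_harmonised(bx = 0, sx = 0.01, by = 0.1, so = 0.02)
  expect_error(wald_ratio(h0), "degenerate-instrument")
})

test_that("IVW is exact on proportional data and matches the two-point closed form", {
  h <- make_harmonised(bx = c(0.1, 0.2, 0.4), sx = 0.01,
                       by = c(0.03, 0.06, 0.12), so = c(0.02, 0.05, 0.01))
  r <- mr_ivw(h)
  expect_equal(r$estimate$beta, 0.3)
  expect_equal(r$heterogeneity$q, 0)
  expect_equal(r$heterogeneity$df, 2)

  h1 <- make_harmonised(bx = 0.1, sx = 0.01, by = 0.05, so = 0.02)
  expect_error(mr_ivw(h1), "insufficient-instruments")

  h2 <- make_harmonised(bx = c(0.1, 0.3), sx = 0.01, by = c(0.02, 0.12),
                        so = c(0.02, 0.03))
  ratios <- c(0.02 / 0.1, 0.12 / 0.3)
  wts <- c(0.1, 0.3)^2 / c(0.02, 0.03)^2
  expect_equal(mr_ivw(h2)$estimate$beta, weighted.mean(ratios, wts))
})

test_that("IVW equals the weighted least-squares oracle on random sets", {
  set.seed(21)
  for (i in 1:5) {
    J <- 50
    bx <- rnorm(J, 0.1, 0.04)
    so <- runif(J, 0.01, 0.05)
    by <- 0.25 * bx + rnorm(J, 0, so)
    h <- make_harmonised(bx = bx, sx = 0.01, by = by, so = so)
    r <- mr_ivw(h)
    fit <- lm(by ~ 0 + bx, weights = 1 / so^2)
    expect_equal(r$estimate$beta, unname(coef(fit)[1]), tolerance = 1e-12)
    sig <- summary(fit)$sigma
    se_fixed <- summary(fit)$coefficients[1, 2] / sig
    expect_equal(r$estimate$se / max(1, sqrt(r$heterogeneity$q / (J - 2))),
                 se_fixed, tolerance = 1e-12)
    # algebraic identity with the weighted mean of Wald ratios
    expect_equal(r$estimate$beta,
                 weighted.mean(by / bx, bx^2 / so^2), tolerance = 1e-12)
    # fixed-effect variant
    expect_equal(mr_ivw(h, re_model = "fixed")$estimate$se, se_fixed,
                 tolerance = 1e-12)
  }
})

test_that("Q vanishes exactly when all ratios agree and is order-invariant", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h_eq <- make_harmonised(bx = bx, sx = 0.01, by = 0.4 * bx,
                          so = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(mr_ivw(h_eq)$heterogeneity$q, 0)

  set.seed(3)
  by <- 0.4 * bx + rnorm(4, 0, 0.05)
  h <- make_harmonised(bx = bx, sx = 0.01, by = by, so = 0.03)
  expect_gt(mr_ivw(h)$heterogeneity$q, 0)
  perm <- sample(4)
  hp <- make_harmonised(bx = bx[perm], sx = 0.01, by = by[perm], so = 0.03)
  expect_equal(mr_ivw(hp)$heterogeneity$q, mr_ivw(h)$heterogeneity$q)
})

test_that("Egger recovers exact linear pleiotropy and matches the WLS oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- make_harmonised(bx = bx, sx = 0.01, by = 0.01 + 0.2 * bx, so = 0.02)
  r <- mr_egger(h)
  expect_equal(r$intercept$beta, 0.01, tolerance = 1e-12)
  expect_equal(r$slope$beta, 0.2, tolerance = 1e-12)
  expect_equal(r$heterogeneity$q, 0, tolerance = 1e-20)

  expect_error(mr_egger(make_harmonised(bx = c(0.1, 0.2), sx = 0.01,
                                        by = c(0.1, 0.2), so = 0.02)),
               "insufficient-instruments")

  set.seed(22)
  for (i in 1:5) {
    J <- 40
    bx <- abs(rnorm(J, 0.1, 0.04)) + 0.01
    so <- runif(J, 0.01, 0.05)
    by <- 0.015 + 0.3 * bx + rnorm(J, 0, so)
    h <- make_harmonised(bx = bx, sx = 0.01, by = by, so = so)
    r <- mr_egger(h)
    fit <- lm(by ~ bx, weights = 1 / so^2)
    expect_equal(r$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-12)
    expect_equal(r$slope$beta, unname(coef(fit)[2]), tolerance = 1e-12)
    sig <- summary(fit)$sigma
    infl <- max(1, sig)
    expect_equal(r$slope$se,
                 summary(fit)$coefficients[2, 2] / sig * infl,
                 tolerance = 1e-12)
    expect_equal(r$intercept$se,
                 summary(fit)$coefficients[1, 2] / sig * infl,
                 tolerance = 1e-12)
  }
})

test_that("Egger intercept is centred at zero under balanced pleiotropy", {
  set.seed(31)
  J <- 200
  reps <- 60
  icept <- numeric(reps)
  for (r in 1:reps) {
    bx <- abs(rnorm(J, 0.08, 0.03))
    alpha <- rnorm(J, 0, 0.02)   # balanced: mean zero
    so <- runif(J, 0.005, 0.02)
    by <- 0.3 * bx + alpha + rnorm(J, 0, so)
    icept[r] <- mr_egger(make_harmonised(bx, 0.005, by, so))$intercept$beta
  }
  expect_lt(abs(mean(icept)), 2 * sd(icept) / sqrt(reps))
})

test_that("weighted median interpolates the cumulative-weight percentile", {
  h <- make_harmonised(bx = c(1, 1, 1), sx = 0.01,
                       by = c(0.1, 0.2, 0.3), so = 0.02)
  est <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.2)

  h_same <- make_harmonised(bx = c(0.1, 0.2, 0.3), sx = 0.005,
                            by = 0.4 * c(0.1, 0.2, 0.3), so = 0.001)
  est2 <- mr_weighted_median(h_same, n_boot = 200, seed = 2)
  expect_equal(est2$beta, 0.4)
  expect_lt(est2$se, 0.05)

  set.seed(9)
  for (i in 1:20) {
    bx <- rnorm(15, 0.1, 0.04)
    so <- runif(15, 0.01, 0.05)
    by <- rnorm(15, 0.02, 0.05)
    h <- make_harmonised(bx = bx, sx = 0.01, by = by, so = so)
    est <- mr_weighted_median(h, n_boot = 100, seed = i)
    expect_equal(est$beta, oracle_weighted_median(by / bx, bx^2 / so^2),
                 tolerance = 1e-10)
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  h_point <- make_harmonised(bx = c(0.1, 0.2, 0.5), sx = 0.01,
                             by = -0.2 * c(0.1, 0.2, 0.5), so = 0.02)
  est <- mr_weighted_mode(h_point, n_boot = 100, seed = 1)
  expect_equal(est$beta, -0.2)

  set.seed(13)
  bx <- rep(1, 100)
  by <- c(rnorm(70, 0.3, 0.01), runif(30, -2, 2))
  h <- make_harmonised(bx = bx, sx = 1e-6, by = by, so = 1)
  est <- mr_weighted_mode(h, n_boot = 100, seed = 1)
  grid_step <- (diff(range(by)) + 6 * 0.9 * min(sd(by), mad(by)) /
                  100^(1 / 5)) / 511
  expect_lt(abs(est$beta - 0.3), 2 * grid_step + 0.02)
  expect_equal(est$beta, oracle_weighted_mode(by / bx, bx^2 / 1^2),
               tolerance = 1e-10)

  # permutation invariance of the point estimate
  perm <- sample(100)
  hp <- make_harmonised(bx = bx[perm], sx = 1e-6, by = by[perm], so = 1)
  expect_equal(mr_weighted_mode(hp, n_boot = 100, seed = 5)$beta, est$beta)

  expect_error(mr_weighted_mode(h, phi = 0, n_boot = 100, seed = 1),
               "parameter error")
})

test_that("per-doubling scaling multiplies by ln 2 and preserves p-values", {
  h <- make_harmonised(bx = c(0.1, 0.2, 0.3), sx = 0.01,
                       by = c(0.04, 0.07, 0.1), so = 0.02)
  e <- mr_ivw(h)$estimate
  s <- scale_per_doubling(e)
  expect_equal(s$beta, e$beta * log(2))
  expect_equal(s$se, e$se * log(2))
  expect_equal(round(log(2), 3), 0.693)
  expect_equal(s$pval, e$pval)  # z unchanged
  expect_true(s$scaled_per_doubling)
  expect_error(scale_per_doubling(s), "state error")

  e0 <- mr_ivw(make_harmonised(bx = c(0.1, 0.2, 0.3), sx = 0.01,
                               by = c(0, 0, 0), so = 0.02))$estimate
  expect_equal(scale_per_doubling(e0)$beta, 0)
})

test_that("the full fit returns five labelled estimates that agree on clean data", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  h <- make_harmonised(bx = bx, sx = 1e-4, by = 0.25 * bx, so = 0.02,
                       exposure_type = "continuous")
  fit <- mr_fit(h, n_boot = 200, seed = 4)
  expect_named(fit$estimates,
               c("ivw", "egger_slope", "egger_intercept",
                 "weighted_median", "weighted_mode"))
  betas <- coef(fit)
  expect_equal(unname(betas[c("ivw", "weighted_median", "weighted_mode")]),
               rep(0.25, 3), tolerance = 1e-6)
  expect_equal(unname(betas["egger_slope"]), 0.25, tolerance = 1e-6)
  expect_equal(unname(betas["egger_intercept"]), 0, tolerance = 1e-8)
  expect_false(fit$scaled_per_doubling)

  # binary exposure: scaled by default
  hb <- make_harmonised(bx = bx, sx = 1e-4, by = 0.25 * bx, so = 0.02)
  fitb <- mr_fit(hb, n_boot = 200, seed = 4)
  expect_true(fitb$scaled_per_doubling)
  expect_equal(unname(coef(fitb)["ivw"]), 0.25 * log(2), tolerance = 1e-6)

  df <- as.data.frame(fitb)
  expect_equal(nrow(df), 5)
  expect_true(all(df$ci_low <= df$beta & df$beta <= df$ci_high))
})

test_that("estimators are invariant to joint sign flips of instrument subsets", {
  set.seed(8)
  J <- 30
  bx <- rnorm(J, 0.1, 0.05)
  so <- runif(J, 0.01, 0.04)
  by <- 0.2 * bx + rnorm(J, 0, so)
  flip <- sample(c(1, -1), J, replace = TRUE)
  h <- make_harmonised(bx, 0.01, by, so)
  hf <- make_harmonised(bx * flip, 0.01, by * flip, so)

  expect_equal(mr_ivw(hf)$estimate$beta, mr_ivw(h)$estimate$beta)
  expect_equal(mr_ivw(hf)$heterogeneity$q, mr_ivw(h)$heterogeneity$q)
  expect_equal(mr_egger(hf)$slope$beta, mr_egger(h)$slope$beta)
  expect_equal(mr_weighted_median(hf, n_boot = 100, seed = 2)$beta,
               mr_weighted_median(h, n_boot = 100, seed = 2)$beta)
  expect_equal(mr_weighted_mode(hf, n_boot = 100, seed = 2)$beta,
               mr_weighted_mode(h, n_boot = 100, seed = 2)$beta)
})

test_that("directional pleiotropy biases IVW but not the Egger slope", {
  set.seed(17)
  J <- 200
  bx <- abs(rnorm(J, 0.08, 0.03))
  alpha <- c(rep(0, 140), rnorm(60, 0.02, 0.005))[sample(J)]
  so <- rep(0.004, J)
  by <- 0.3 * bx + alpha + rnorm(J, 0, so)
  h <- make_harmonised(bx, 0.004, by, so)
  ivw <- mr_ivw(h)$estimate
  egg <- mr_egger(h)
  predicted_bias <- sum(bx * alpha / so^2) / sum(bx^2 / so^2)
  expect_equal(ivw$beta - 0.3, predicted_bias, tolerance = 0.35)
  expect_gt(ivw$beta, 0.3)  # biased upward by directional pleiotropy
  expect_lt(abs(egg$slope$beta - 0.3), 2 * egg$slope$se)
  expect_lt(abs(egg$intercept$beta - mean(alpha)),
            2 * egg$intercept$se)
})
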