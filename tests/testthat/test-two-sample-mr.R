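test_that("Wald ratios follow the first-order delta method", {
  d <- make_harmonised_df(bx = c(0.1, -0.1), sx = 0.01,
                          by = c(0.05, 0.05), sy = 0.01)
  r <- wald_ratios(d)
  expect_equal(r$ratio, c(0.5, -0.5))
  expect_equal(r$se, c(0.1, 0.1))

  # elementwise oracle on random records
  set.seed(1)
  d2 <- make_harmonised_df(bx = rnorm(10, 0.1, 0.03), sx = runif(10, 0.01, 0.02),
                           by = rnorm(10, 0, 0.02), sy = runif(10, 0.005, 0.02))
  r2 <- wald_ratios(d2)
  expect_equal(r2$ratio, d2$beta_outcome / d2$beta_exposure)
  expect_equal(r2$se, d2$se_outcome / abs(d2$beta_exposure))
  expect_equal(r2$weight, 1 / r2$se^2)

  # second-order SE exceeds first-order and propagates the exposure SE
  r2b <- wald_ratios(d2, second_order = TRUE)
  expect_true(all(r2b$se >= r2$se))

  d3 <- d2; d3$beta_exposure[3] <- 0
  expect_warning(r3 <- wald_ratios(d3), "zero exposure beta")
  expect_equal(nrow(r3), 9L)
})

test_that("IVW closed forms: single instrument, replication, Q", {
  one <- data.frame(ratio = 0.5, se = 0.1)
  e1 <- mr_ivw(one)
  expect_equal(e1$beta, 0.5)
  expect_equal(e1$se, 0.1)
  expect_equal(e1$Q, 0)

  two <- data.frame(ratio = c(0.5, 0.5), se = c(0.1, 0.1))
  e2 <- mr_ivw(two, effects = "fixed")
  expect_equal(e2$beta, 0.5)
  expect_equal(e2$se, 0.1 / sqrt(2))
  expect_equal(e2$Q, 0)
  expect_equal(e2$I2, 0)
})

test_that("IVW equals the zero-intercept weighted regression", {
  set.seed(2)
  d <- make_harmonised_df(bx = rnorm(25, 0.1, 0.04), sx = 0.01,
                          by = rnorm(25, -0.02, 0.02),
                          sy = runif(25, 0.005, 0.03))
  est <- mr_ivw(d, effects = "fixed")
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = d,
            weights = 1 / d$se_outcome^2)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  # fixed-effects regression SE = lm SE de-scaled by the residual sd
  se_reg <- summary(fit)$coefficients[1, "Std. Error"] / summary(fit)$sigma
  expect_equal(est$se, se_reg, tolerance = 1e-10)
})

test_that("random-effects IVW floors the dispersion scale at 1", {
  hom <- data.frame(ratio = c(0.50, 0.501, 0.499), se = 10)  # tiny Q
  expect_equal(mr_ivw(hom, "random")$se, mr_ivw(hom, "fixed")$se)
  het <- data.frame(ratio = c(0, 0.4, 0.8), se = 0.01)
  r <- mr_ivw(het, "random"); f <- mr_ivw(het, "fixed")
  expect_equal(r$se, f$se * sqrt(r$Q / (3 - 1)))
  # auto-selection switches to random only under significant heterogeneity
  expect_equal(mr_ivw(het, "auto")$method, "IVW_random")
  expect_equal(mr_ivw(hom, "auto")$method, "IVW_fixed")
})

test_that("MR-Egger recovers slope and intercept in exact configurations", {
  bx <- c(0.05, 0.10, 0.15, 0.20)
  d <- make_harmonised_df(bx = bx, sx = 0.01, by = 0.5 * bx, sy = 0.01)
  e <- mr_egger(d)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0, tolerance = 1e-10)

  d2 <- make_harmonised_df(bx = bx, sx = 0.01, by = 0.5 * bx + 0.02, sy = 0.01)
  e2 <- mr_egger(d2)
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$intercept, 0.02, tolerance = 1e-10)

  # orientation: flipping the sign of a (bx, by) pair changes nothing
  d3 <- d2; d3$beta_exposure[2] <- -d3$beta_exposure[2]
  d3$beta_outcome[2] <- -d3$beta_outcome[2]
  e3 <- mr_egger(d3)
  expect_equal(e3$beta, e2$beta)
  expect_equal(e3$intercept, e2$intercept)

  expect_error(mr_egger(d[1:2, ]), "at least 3")
  d4 <- make_harmonised_df(bx = rep(0.1, 4), sx = 0.01, by = 0.5, sy = 0.01)
  expect_error(mr_egger(d4), "unidentifiable")
})

test_that("Egger with the intercept constrained to zero reduces to IVW", {
  set.seed(3)
  d <- make_harmonised_df(bx = runif(15, 0.05, 0.2), sx = 0.01,
                          by = rnorm(15, 0.02, 0.01),
                          sy = runif(15, 0.005, 0.02))
  noint <- lm(beta_outcome ~ 0 + beta_exposure, data = d,
              weights = 1 / d$se_outcome^2)
  expect_equal(unname(coef(noint)), mr_ivw(d, "fixed")$beta, tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative-weight midpoints", {
  d <- data.frame(ratio = c(0.4, 0.5, 0.6), se = 1)
  wm <- mr_weighted_median(d, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.5)

  # shifting weight towards the largest ratio moves the estimate up
  d2 <- data.frame(ratio = c(0.4, 0.5, 0.6), se = c(1, 1, 1 / sqrt(3)))
  expect_gt(mr_weighted_median(d2, n_boot = 50, seed = 1)$beta, 0.5)

  # equal weights, odd k: equals the sample median
  set.seed(4)
  b <- rnorm(9)
  d3 <- data.frame(ratio = b, se = 1)
  expect_equal(mr_weighted_median(d3, n_boot = 50, seed = 1)$beta, median(b))

  expect_error(mr_weighted_median(d[1:2, ]), "at least 3")
})

test_that("penalised weighted median downweights heterogeneous variants", {
  # identical ratios: no penalty, PWM = WM = the common ratio
  d <- data.frame(ratio = rep(0.3, 5), se = c(0.1, 0.2, 0.1, 0.3, 0.1))
  expect_equal(mr_penalised_weighted_median(d, n_boot = 50, seed = 1)$beta, 0.3)

  # penalty multiplier boundary: p = 0.05 with constant 20 gives exactly 1
  expect_equal(min(1, 20 * 0.05), 1)
  q_boundary <- qchisq(0.95, df = 1)
  expect_equal(pchisq(q_boundary, 1, lower.tail = FALSE) * 20, 1)

  # an extreme outlier is penalised towards the concordant ratios
  conc <- seq(0.28, 0.32, length.out = 10)
  d2 <- data.frame(ratio = c(conc, 5), se = 0.05)
  wm_est <- mr_weighted_median(d2, n_boot = 50, seed = 1)$beta
  pwm_est <- mr_penalised_weighted_median(d2, n_boot = 50, seed = 1)$beta
  expect_true(pwm_est >= min(conc) && pwm_est <= max(conc))
  # hand computation of the outlier's penalised weight
  w <- 1 / d2$se^2
  Qj <- w[11] * (d2$ratio[11] - wm_est)^2
  pj <- pchisq(Qj, 1, lower.tail = FALSE)
  expect_lt(20 * pj, 1)  # outlier really is penalised
})

test_that("median F statistic summarises per-variant instrument strength", {
  one <- data.frame(beta = 0.1, se = 0.02)
  f1 <- median_f_statistic(one)
  expect_equal(f1$F, 25)
  expect_equal(f1$median_F, 25)

  d <- data.frame(beta = c(0.4, 0.5, 0.6), se = 0.1)
  expect_equal(median_f_statistic(d)$median_F, 25)
  expect_error(median_f_statistic(data.frame(beta = 1, se = 0)), "SE")

  # simulated exposure GWAS: median F agrees with explicit per-variant fits
  cfg <- small_config(n_individuals = 3000L, n_variants = 8L, seed = 9L)
  pair <- simulate_sumstats_pair(cfg)
  cfg1 <- cfg; cfg1$seed <- cfg$seed * 2L + 11L
  coh <- simulate_cohort(cfg1)
  x <- as.vector(scale(coh$exposure))
  f_direct <- vapply(attr(coh, "variants")$snp, function(s) {
    cf <- summary(lm(x ~ coh[[s]]))$coefficients
    (cf[2, "Estimate"] / cf[2, "Std. Error"])^2
  }, numeric(1))
  expect_equal(median_f_statistic(pair$exposure_stats)$median_F,
               median(f_direct), tolerance = 0.01)
})

test_that("all estimators are scale-equivariant in the exposure betas", {
  set.seed(5)
  d <- make_harmonised_df(bx = runif(12, 0.05, 0.2), sx = 0.01,
                          by = rnorm(12, -0.02, 0.01),
                          sy = runif(12, 0.005, 0.02))
  cc <- 3.7
  d2 <- d; d2$beta_exposure <- d$beta_exposure * cc
  d2$se_exposure <- d$se_exposure * cc
  expect_equal(mr_ivw(d2, "fixed")$beta, mr_ivw(d, "fixed")$beta / cc)
  expect_equal(mr_egger(d2)$beta, mr_egger(d)$beta / cc)
  expect_equal(mr_weighted_median(d2, n_boot = 50, seed = 2)$beta,
               mr_weighted_median(d, n_boot = 50, seed = 2)$beta / cc)
  expect_equal(mr_penalised_weighted_median(d2, n_boot = 50, seed = 2)$beta,
               mr_penalised_weighted_median(d, n_boot = 50, seed = 2)$beta / cc)
})

test_that("heterogeneity I2 lies in [0, 100) and is 0 for coincident ratios", {
  set.seed(6)
  for (i in 1:20) {
    d <- data.frame(ratio = rnorm(8), se = runif(8, 0.05, 0.3))
    est <- mr_ivw(d, "fixed")
    expect_gte(est$I2, 0)
    expect_lt(est$I2, 100)
  }
  same <- data.frame(ratio = rep(0.2, 6), se = 0.1)
  expect_equal(mr_ivw(same)$I2, 0)
})

test_that("mr_all bundles the four estimators with instrument strength", {
  cfg <- small_config(n_individuals = 3000L, n_variants = 12L)
  pair <- simulate_sumstats_pair(cfg)
  hs <- align_effect_alleles(pair$exposure_stats, pair$outcome_stats)
  res <- mr_all(hs, n_boot = 50, seed = 1)
  expect_setequal(res$method,
                  c("IVW_fixed", "IVW_random", "Egger", "WM", "PWM"))
  expect_true(all(res$se > 0))
  expect_true(is.numeric(attr(res, "median_F")))
  # reported OR columns are consistent transforms of beta/se
  expect_equal(res$or, exp(res$beta))
  expect_equal(res$ci_low, exp(res$beta - qnorm(0.975) * res$se))
})
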