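test_that("rank inverse normal transform uses Blom quantiles", {
  out3 <- rank_inverse_normal(c(1, 2, 3))
  expect_equal(out3[2], 0)
  expect_equal(out3[1], -out3[3])

  # n = 5 distinct values: exactly the Blom quantiles
  x <- c(10, 3, 7, 1, 5)
  expected <- qnorm((rank(x) - 3 / 8) / (5 + 1 / 4))
  expect_equal(rank_inverse_normal(x), expected)

  # invariance under monotone transforms
  expect_equal(rank_inverse_normal(exp(x)), rank_inverse_normal(x))

  # ties share the average rank
  xt <- c(1, 2, 2, 3)
  rt <- rank_inverse_normal(xt)
  expect_equal(rt[2], rt[3])
  expect_equal(rt[2], qnorm((2.5 - 3 / 8) / (4 + 1 / 4)))

  expect_error(rank_inverse_normal(c(1, 1, 1)), "identical")
  expect_error(rank_inverse_normal(1), "2 finite")

  # output of a skewed continuous input passes a normality check
  set.seed(8)
  skew <- rlnorm(150)
  expect_gt(shapiro.test(rank_inverse_normal(skew))$p.value, 0.5)
})

test_that("trait-raising allele coding resolves sex discordance by effect size", {
  # variant 1: raises in both sexes; variant 2: male +0.3, female -0.08,
  # so the male effect decides the coded allele
  gam <- cbind(male = c(0.25, 0.30, 0.15), female = c(0.25, -0.08, 0.15))
  cfg <- sim_config(n_individuals = 6000L, n_variants = 3L,
                    maf = c(0.3, 0.4, 0.2),
                    variant_effects_exposure = gam,
                    n_pcs = 2L, seed = 21L)
  coh <- simulate_cohort(cfg)
  variants <- attr(coh, "variants")
  coding <- code_trait_raising_alleles(coh, variants)

  expect_equal(coding$coding_source_sex[1], "concordant")
  expect_equal(coding$coding_source_sex[2], "male")
  # effect allele raises the trait in the deciding sex -> no flip
  expect_equal(coding$coded_allele[2], variants$effect_allele[2])
  expect_false(coding$flip[2])
  # coded-scale effects are non-negative in the deciding sex
  expect_true(all(ifelse(coding$coding_source_sex == "female",
                         coding$beta_female, coding$beta_male) >= 0))

  # idempotence: re-running on the same data reproduces the coding
  expect_identical(coding, code_trait_raising_alleles(coh, variants))
})

test_that("allele-coding is invariant to dosage/label co-flips", {
  cfg <- small_config(n_individuals = 4000L, n_variants = 6L, seed = 22L)
  coh <- simulate_cohort(cfg)
  variants <- attr(coh, "variants")
  coding <- code_trait_raising_alleles(coh, variants)

  # flip variant 3: recode dosage g -> 2 - g and swap the allele labels
  coh2 <- coh; v <- variants$snp[3]
  coh2[[v]] <- 2 - coh2[[v]]
  variants2 <- variants
  variants2$effect_allele[3] <- variants$other_allele[3]
  variants2$other_allele[3] <- variants$effect_allele[3]
  coding2 <- code_trait_raising_alleles(coh2, variants2)
  expect_equal(coding2$coded_allele, coding$coded_allele)
  expect_equal(coding2$beta_male, coding$beta_male, tolerance = 1e-10)

  w1 <- crossfit_weights(coh, coding, K = 3, seed = 5)
  w2 <- crossfit_weights(coh2, coding2, K = 3, seed = 5)
  g1 <- compute_grs(coh, w1)
  g2 <- compute_grs(coh2, w2)
  expect_equal(g1, g2, tolerance = 1e-10)
  s1 <- instrument_strength(coh, g1)
  s2 <- instrument_strength(coh2, g2)
  expect_equal(s1$r2, s2$r2, tolerance = 1e-10)
  expect_equal(s1$F, s2$F, tolerance = 1e-10)
})

test_that("cross-fitting is honest: weights recompute exactly without own block", {
  cfg <- small_config(n_individuals = 3000L, n_variants = 8L, seed = 23L)
  coh <- simulate_cohort(cfg)
  coding <- code_trait_raising_alleles(coh, attr(coh, "variants"))
  K <- 5L
  w <- crossfit_weights(coh, coding, K = K, seed = 7)

  pcs <- grep("^pc[0-9]+$", names(coh), value = TRUE)
  Gc <- as.matrix(coh[, coding$snp])
  Gc[, coding$flip] <- 2 - Gc[, coding$flip, drop = FALSE]
  for (sex in c("male", "female")) {
    rows <- which(coh$unrelated & coh$sex == sex)
    y <- rank_inverse_normal(coh$exposure[rows])
    bl <- w$block[rows]
    for (b in c(2L, 4L)) {
      keep <- bl != b
      X <- cbind(1, Gc[rows[keep], ], as.matrix(coh[rows[keep], pcs]))
      ref <- lm.fit(X, y[keep])$coefficients[1L + seq_len(nrow(coding))]
      expect_equal(unname(w$weights[, as.character(b), sex]), unname(ref),
                   tolerance = 1e-12)
    }
  }
  # every cohort member has a block; derivation blocks balanced within 1
  expect_true(all(w$block[coh$unrelated] >= 1))
  expect_true(all(w$block[!coh$unrelated] == 0))
  tab <- table(w$block[coh$unrelated])
  expect_lte(diff(range(tab)), 1)
})

test_that("K = 2 cross-fit scores track the full-sample-weight scores", {
  # homogeneous cohort with well-separated per-variant effects so the
  # leave-half-out weight vectors are signal- rather than noise-dominated
  gam_v <- seq(0.05, 0.35, length.out = 8)
  cfg <- sim_config(n_individuals = 16000L, n_variants = 8L, maf = 0.3,
                    variant_effects_exposure = cbind(male = gam_v,
                                                     female = gam_v),
                    unrelated_fraction = 1, n_pcs = 2L, seed = 24L)
  coh <- simulate_cohort(cfg)
  coding <- code_trait_raising_alleles(coh, attr(coh, "variants"))
  w <- crossfit_weights(coh, coding, K = 2, seed = 9)
  g_cf <- compute_grs(coh, w)

  # score everyone with the full-derivation weights (block "0")
  w_full <- w
  for (b in as.character(1:2))
    w_full$weights[, b, ] <- w_full$weights[, "0", ]
  g_full <- compute_grs(coh, w_full)
  expect_gt(cor(g_cf, g_full), 0.99)
  # the two leave-half-out weight vectors agree within sampling error
  expect_gt(cor(w$weights[, "1", "female"], w$weights[, "2", "female"]), 0.8)
})

test_that("variants below the MAF threshold are excluded from weighting", {
  cfg <- small_config(n_individuals = 5000L, n_variants = 6L,
                      maf = c(0.005, 0.2, 0.3, 0.4, 0.25, 0.35), seed = 25L)
  coh <- simulate_cohort(cfg)
  coding <- code_trait_raising_alleles(coh, attr(coh, "variants"))
  w <- crossfit_weights(coh, coding, K = 3, seed = 2)
  rare <- attr(coh, "variants")$snp[1]
  expect_true(rare %in% w$excluded_snps)
  expect_false(rare %in% w$coding$snp)
})

test_that("GRS scoring is a weighted dosage sum with block-specific weights", {
  cfg <- small_config(n_individuals = 2000L, n_variants = 4L, seed = 26L)
  coh <- simulate_cohort(cfg)
  coding <- code_trait_raising_alleles(coh, attr(coh, "variants"))
  w <- crossfit_weights(coh, coding, K = 2, seed = 3)

  w0 <- w; w0$weights[] <- 0
  expect_equal(compute_grs(coh, w0), rep(0, nrow(coh)),
               ignore_attr = TRUE)

  w1 <- w; w1$weights[] <- 0; w1$weights[2, , ] <- 1
  Gc <- as.matrix(coh[, coding$snp])
  Gc[, coding$flip] <- 2 - Gc[, coding$flip, drop = FALSE]
  expect_equal(compute_grs(coh, w1), Gc[, 2], ignore_attr = TRUE)
})

test_that("instrument strength matches its closed form and the analytic r2", {
  set.seed(27)
  x <- rnorm(102)
  y <- x + rnorm(102)
  d <- data.frame(sex = "both", exposure = y)
  s <- instrument_strength(d, x, strata = NULL)
  r2 <- cor(x, y)^2
  expect_equal(s$r2, r2)
  expect_equal(s$F, r2 * (102 - 2) / (1 - r2))

  # simulated cohort: GRS r2 close to the variance-decomposition prediction
  gam <- cbind(male = rep(0.08, 20), female = rep(0.08, 20))
  cfg <- sim_config(n_individuals = 20000L, n_variants = 20L, maf = 0.3,
                    variant_effects_exposure = gam,
                    confounder_effect_exposure = 0, n_pcs = 2L, seed = 28L)
  coh <- simulate_cohort(cfg)
  g <- true_weight_grs(coh)
  s2 <- instrument_strength(coh, g, strata = NULL)
  r2_theory <- 20 * 2 * 0.3 * 0.7 * 0.08^2  # latent variance is ~1
  expect_lt(abs(s2$r2 - r2_theory), 0.015)
})
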