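#' Simulate an individual-level cohort
#'
#' Draws biallelic genotype dosages, a polygenic confounded exposure, a
#' binary depression outcome with optional quadratic exposure effects and
#' direct (pleiotropic) variant effects, region- and sex-structured
#' covariates, and CIDI-style item responses from which the depression
#' phenotypes are derived.
#'
#' The generative model is, per individual i with sex s(i) and region r(i):
#' \deqn{G_{ij} \sim Binomial(2, maf_j)}
#' \deqn{Z_i = \sum_j \gamma_{j,s(i)} G_{ij} + a U_i + e_i, \quad U_i, e_i \sim N(0,1)/N(0,\sigma_e)}
#' \deqn{X^{std}_i = (Z_i - \bar Z)/sd(Z), \qquad X_i = \mu_X + \sigma_X X^{std}_i}
#' \deqn{logit P(Y_i=1) = \beta_0 + \theta X^{std}_i + \theta_2 (X^{std}_i)^2
#'   + \sum_j \delta_j G_{ij} + b U_i + \alpha_{r(i)}}
#' The residual SD \eqn{\sigma_e} is chosen so the latent exposure has
#' approximately unit variance before standardisation, so \eqn{\theta} is
#' the log-odds per 1-SD of exposure in the generated cohort.
#'
#' Item responses are drawn so that derived phenotypes reproduce the case
#' indicator: cases receive at least one trigger-item "yes" and a CIDI-SF
#' symptom count from independent Bernoulli draws; controls answer "no" to
#' all four trigger items.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{data.frame} with one row per individual: \code{id},
#'   \code{sex} ("male"/"female"), \code{region}, \code{urban}, \code{age},
#'   \code{pc1..pcP}, \code{unrelated}, dosage columns named by variant id,
#'   \code{exposure}, trigger/CIDI item columns, \code{depressive_symptoms}
#'   and \code{major_depression}. Variant metadata (snp, effect_allele,
#'   other_allele, maf) is attached as \code{attr(,"variants")} and the
#'   generative truth as \code{attr(,"truth")}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_individuals
  m <- config$n_variants
  maf <- config$maf

  variants <- make_variant_table(m, maf)
  G <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m,
              dimnames = list(NULL, variants$snp))

  sex <- ifelse(runif(n) < config$sex_ratio, "female", "male")
  region <- sample.int(config$n_regions, n, replace = TRUE)
  urban <- region <= config$n_urban
  age <- rnorm(n, config$age_mean, config$age_sd)
  pcs <- matrix(rnorm(n * config$n_pcs), nrow = n,
                dimnames = list(NULL, paste0("pc", seq_len(config$n_pcs))))
  unrelated <- runif(n) < config$unrelated_fraction

  gam <- config$variant_effects_exposure
  gvec <- ifelse(sex == "female",
                 as.vector(G %*% gam[, "female"]),
                 as.vector(G %*% gam[, "male"]))
  a <- config$confounder_effect_exposure
  U <- rnorm(n)
  vg_m <- sum(2 * maf * (1 - maf) * gam[, "male"]^2)
  vg_f <- sum(2 * maf * (1 - maf) * gam[, "female"]^2)
  vg <- (1 - config$sex_ratio) * vg_m + config$sex_ratio * vg_f
  sig_e <- sqrt(max(0.05, 1 - vg - a^2))
  Z <- gvec + a * U + rnorm(n, 0, sig_e)
  if (sd(Z) < .Machine$double.eps^0.5) stop("zero-variance exposure")
  x_std <- (Z - mean(Z)) / sd(Z)
  exposure <- config$exposure_mean + config$exposure_sd * x_std

  eta <- config$baseline_logit +
    config$causal_effect_linear * x_std +
    config$causal_effect_quadratic * x_std^2 +
    as.vector(G %*% config$pleiotropy_effects) +
    config$confounder_effect_outcome * U +
    config$region_intercepts[region]
  y <- rbinom(n, 1L, plogis(eta))

  items <- simulate_depression_items(y, config)
  ph <- derive_depression_phenotypes(items$trigger, items$cidi)

  cohort <- data.frame(id = seq_len(n), sex = sex, region = region,
                       urban = urban, age = age, pcs, unrelated = unrelated,
                       G, exposure = exposure,
                       items$trigger, items$cidi,
                       depressive_symptoms = ph$depressive_symptoms,
                       major_depression = ph$major_depression,
                       check.names = FALSE)
  attr(cohort, "variants") <- variants
  attr(cohort, "truth") <- list(
    theta = config$causal_effect_linear,
    theta2 = config$causal_effect_quadratic,
    gamma = gam, delta = config$pleiotropy_effects,
    confounder = U, x_std = x_std, case = y)
  cohort
}

make_variant_table <- function(m, maf) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, m, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
  data.frame(snp = sprintf("rsim%04d", seq_len(m)),
             effect_allele = ea, other_allele = unname(oa), maf = maf)
}

simulate_depression_items <- function(case, config) {
  n <- length(case)
  trig <- matrix(0L, n, 4L,
                 dimnames = list(NULL, paste0("trigger", 1:4)))
  idx <- which(case == 1L)
  if (length(idx)) {
    draws <- matrix(rbinom(length(idx) * 4L, 1L,
                           rep(config$trigger_probs, each = length(idx))),
                    ncol = 4L)
    none <- rowSums(draws) == 0L
    draws[none, 1L] <- 1L  # cases must endorse at least one trigger
    trig[idx, ] <- draws
  }
  p_cidi <- ifelse(case == 1L, config$cidi_prob_case, config$cidi_prob_control)
  cidi <- matrix(rbinom(n * 7L, 1L, rep(p_cidi, 7L)), n, 7L,
                 dimnames = list(NULL, paste0("cidi", 1:7)))
  list(trigger = trig, cidi = cidi)
}

#' Derive depression phenotypes from questionnaire items
#'
#' Depressive symptoms are defined by endorsing ("yes") one or more of four
#' CIDI trigger items; a major depression episode additionally requires at
#' least 3 of the 7 CIDI-SF symptoms.
#'
#' @param trigger matrix/data.frame of 4 binary trigger responses.
#' @param cidi matrix/data.frame of 7 binary CIDI-SF symptom responses.
#' @return list with integer vectors \code{depressive_symptoms} and
#'   \code{major_depression} (major implies depressive symptoms).
#' @export
derive_depression_phenotypes <- function(trigger, cidi) {
  trigger <- as.matrix(trigger); cidi <- as.matrix(cidi)
  if (ncol(trigger) != 4L || ncol(cidi) != 7L)
    stop("expected 4 trigger items and 7 CIDI-SF items")
  if (!all(trigger %in% c(0, 1)) || !all(cidi %in% c(0, 1)))
    stop("item responses must be binary (0/1)")
  ds <- as.integer(rowSums(trigger) >= 1L)
  md <- as.integer(ds == 1L & rowSums(cidi) >= 3L)
  list(depressive_symptoms = ds, major_depression = md)
}

#' Simulate a two-sample GWAS summary-statistic pair
#'
#' Draws two independent cohorts from the same configuration, runs a
#' marginal (single-variant) linear GWAS of the standardised exposure in
#' sample 1 and a marginal logistic GWAS of the outcome in sample 2, and
#' returns the two summary-statistic tables required for two-sample MR.
#' Exposure betas are on the per-1-SD scale, outcome betas on the log-odds
#' scale, so the true Wald-ratio estimand equals the configured linear
#' causal effect.
#'
#' @param config a \code{\link{sim_config}}; the two samples use seeds
#'   derived from \code{config$seed}.
#' @return list of class \code{sumstats_pair}: \code{exposure_stats} and
#'   \code{outcome_stats} (data.frames with columns snp, effect_allele,
#'   other_allele, eaf, beta, se, pval, n) and \code{true_theta}.
#' @export
simulate_sumstats_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg1 <- config; cfg1$seed <- config$seed * 2L + 11L
  cfg2 <- config; cfg2$seed <- config$seed * 2L + 12L
  coh1 <- with_seed(cfg1$seed, simulate_cohort_impl(cfg1))
  coh2 <- with_seed(cfg2$seed, simulate_cohort_impl(cfg2))
  variants <- attr(coh1, "variants")
  snps <- variants$snp

  G1 <- as.matrix(coh1[, snps, drop = FALSE])
  x1 <- as.vector(scale(coh1$exposure))
  exp_stats <- marginal_linear_gwas(G1, x1)

  G2 <- as.matrix(coh2[, snps, drop = FALSE])
  y2 <- coh2$depressive_symptoms
  out_stats <- marginal_logistic_gwas(G2, y2)

  fmt <- function(stats, G, n) {
    data.frame(snp = snps,
               effect_allele = variants$effect_allele,
               other_allele = variants$other_allele,
               eaf = colMeans(G) / 2,
               beta = stats$beta, se = stats$se, pval = stats$pval,
               n = n)
  }
  out <- list(exposure_stats = fmt(exp_stats, G1, nrow(G1)),
              outcome_stats = fmt(out_stats, G2, nrow(G2)),
              true_theta = config$causal_effect_linear)
  class(out) <- "sumstats_pair"
  out
}

# vectorised per-variant simple linear regression (slope, se, p)
marginal_linear_gwas <- function(G, x) {
  n <- nrow(G)
  gm <- colMeans(G)
  sxx <- colSums(G^2) - n * gm^2
  if (any(sxx <= 0)) stop("monomorphic variant in exposure sample")
  xc <- x - mean(x)
  sxy <- as.vector(crossprod(G, xc))
  beta <- sxy / sxx
  syy <- sum(xc^2)
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  z <- beta / se
  data.frame(beta = beta, se = se, pval = 2 * pt(-abs(z), df = n - 2))
}

# per-variant univariate logistic regression via glm.fit
marginal_logistic_gwas <- function(G, y) {
  n <- nrow(G); m <- ncol(G)
  beta <- se <- numeric(m)
  ones <- rep(1, n)
  fam <- binomial()
  for (j in seq_len(m)) {
    g <- G[, j]
    if (var(g) == 0) stop("monomorphic variant in outcome sample")
    fit <- glm.fit(cbind(ones, g), y, family = fam)
    cf <- fit$coefficients[2L]
    # Wald SE from the weighted cross-product inverse
    w <- fit$weights
    xtx <- matrix(c(sum(w), sum(w * g), sum(w * g), sum(w * g^2)), 2L)
    se[j] <- sqrt(solve(xtx)[2L, 2L])
    beta[j] <- cf
  }
  z <- beta / se
  data.frame(beta = beta, se = se, pval = 2 * pnorm(-abs(z)))
}
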