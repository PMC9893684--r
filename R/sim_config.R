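#' Simulation configuration for a synthetic biobank cohort
#'
#' Builds and validates the parameter set that drives
#' \code{\link{simulate_cohort}} and \code{\link{simulate_sumstats_pair}}.
#' Defaults emulate a large East Asian biobank depression study: 100,377
#' adults (3398 depressive-symptom cases expected under the baseline logit),
#' ten geographically defined regions (five urban, five rural), 56.9\% female,
#' a BMI-like exposure on the scale 23.7 (SD 3.5) kg/m^2, a protective causal
#' odds ratio of 0.81 per 1-SD exposure, and polygenic instrument strength
#' tuned so the genetic score explains roughly 1.5\% (males) and 3.1\%
#' (females) of exposure variance.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of biallelic variants.
#' @param maf vector of effect-allele frequencies in (0,1); recycled to
#'   \code{n_variants}. Default: an even spread over 0.05--0.45.
#' @param variant_effects_exposure per-allele additive effects on the latent
#'   exposure in exposure-SD units; a vector (shared by both sexes) or a
#'   two-column matrix \code{cbind(male, female)}. Default: equal effects
#'   scaled so the genetic variance explained is \code{r2_male} in males and
#'   \code{r2_female} in females.
#' @param r2_male,r2_female target genetic variance explained used to build
#'   the default \code{variant_effects_exposure}.
#' @param causal_effect_linear log-odds of the outcome per 1-SD exposure.
#' @param causal_effect_quadratic log-odds per squared SD (0 = linear model).
#' @param pleiotropy_effects per-variant direct variant-to-outcome log-odds
#'   (0 = valid instruments); recycled to \code{n_variants}.
#' @param confounder_effect_exposure,confounder_effect_outcome loadings of a
#'   shared standard-normal confounder U on exposure (SD units) and outcome
#'   (log-odds).
#' @param baseline_logit intercept of the outcome model.
#' @param n_regions,n_urban number of regions and how many of them are urban
#'   (regions \code{1..n_urban}).
#' @param region_intercepts per-region log-odds shifts; recycled.
#' @param sex_ratio proportion female.
#' @param exposure_mean,exposure_sd raw scale of the exposure (BMI-like).
#' @param n_pcs number of principal-component covariate columns to simulate.
#' @param age_mean,age_sd age distribution at baseline.
#' @param unrelated_fraction proportion flagged as the unrelated GRS
#'   weight-derivation subset.
#' @param trigger_probs marginal probabilities, among cases, of the four
#'   CIDI trigger items (sad/depressed, loss of interest, loss of appetite,
#'   feeling worthless).
#' @param cidi_prob_case,cidi_prob_control per-item probability of each of
#'   the seven CIDI-SF symptoms for cases and controls.
#' @param seed integer seed; the generator is deterministic given the config.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_individuals = 100377L,
                       n_variants = 100L,
                       maf = NULL,
                       variant_effects_exposure = NULL,
                       r2_male = 0.015,
                       r2_female = 0.031,
                       causal_effect_linear = log(0.81),
                       causal_effect_quadratic = 0,
                       pleiotropy_effects = 0,
                       confounder_effect_exposure = 0.25,
                       confounder_effect_outcome = 0.15,
                       baseline_logit = qlogis(3398 / 100377),
                       n_regions = 10L,
                       n_urban = 5L,
                       region_intercepts = 0,
                       sex_ratio = 0.569,
                       exposure_mean = 23.7,
                       exposure_sd = 3.5,
                       n_pcs = 12L,
                       age_mean = 53.8,
                       age_sd = 11,
                       unrelated_fraction = 72698 / 100377,
                       trigger_probs = c(0.951, 0.436, 0.253, 0.301),
                       cidi_prob_case = 0.30,
                       cidi_prob_control = 0.05,
                       seed = 1L) {
  n_individuals <- as.integer(n_individuals)
  n_variants <- as.integer(n_variants)
  stopifnot(n_individuals >= 2L, n_variants >= 1L, n_regions >= 1L,
            n_urban >= 0L, n_urban <= n_regions,
            sex_ratio >= 0, sex_ratio <= 1, exposure_sd > 0,
            length(trigger_probs) == 4L)
  if (is.null(maf)) {
    maf <- if (n_variants == 1L) 0.25 else
      seq(0.05, 0.45, length.out = n_variants)
  }
  maf <- rep_len(maf, n_variants)
  if (any(maf <= 0) || any(maf >= 1)) stop("all MAFs must lie in (0,1)")

  if (is.null(variant_effects_exposure)) {
    # equal per-variant effects hitting the target genetic r2 per sex
    vg_unit <- sum(2 * maf * (1 - maf))
    gm <- sqrt(r2_male / vg_unit)
    gf <- sqrt(r2_female / vg_unit)
    variant_effects_exposure <- cbind(male = rep(gm, n_variants),
                                      female = rep(gf, n_variants))
  }
  if (is.null(dim(variant_effects_exposure))) {
    variant_effects_exposure <-
      cbind(male = rep_len(variant_effects_exposure, n_variants),
            female = rep_len(variant_effects_exposure, n_variants))
  }
  stopifnot(nrow(variant_effects_exposure) == n_variants,
            ncol(variant_effects_exposure) == 2L)
  pleiotropy_effects <- rep_len(pleiotropy_effects, n_variants)
  region_intercepts <- rep_len(region_intercepts, n_regions)

  num_fields <- c(causal_effect_linear, causal_effect_quadratic,
                  pleiotropy_effects, confounder_effect_exposure,
                  confounder_effect_outcome, baseline_logit,
                  region_intercepts, variant_effects_exposure)
  if (any(!is.finite(num_fields))) stop("all model parameters must be finite")

  cfg <- list(n_individuals = n_individuals, n_variants = n_variants,
              maf = maf,
              variant_effects_exposure = variant_effects_exposure,
              causal_effect_linear = causal_effect_linear,
              causal_effect_quadratic = causal_effect_quadratic,
              pleiotropy_effects = pleiotropy_effects,
              confounder_effect_exposure = confounder_effect_exposure,
              confounder_effect_outcome = confounder_effect_outcome,
              baseline_logit = baseline_logit,
              n_regions = as.integer(n_regions),
              n_urban = as.integer(n_urban),
              region_intercepts = region_intercepts,
              sex_ratio = sex_ratio,
              exposure_mean = exposure_mean, exposure_sd = exposure_sd,
              n_pcs = as.integer(n_pcs),
              age_mean = age_mean, age_sd = age_sd,
              unrelated_fraction = unrelated_fraction,
              trigger_probs = trigger_probs,
              cidi_prob_case = cidi_prob_case,
              cidi_prob_control = cidi_prob_control,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d   variants: %d   regions: %d (%d urban)\n",
              x$n_individuals, x$n_variants, x$n_regions, x$n_urban))
  cat(sprintf("  causal effect: %.4f log-odds/SD (quadratic %.4f)\n",
              x$causal_effect_linear, x$causal_effect_quadratic))
  cat(sprintf("  confounding: a=%.3f (exposure), b=%.3f (outcome)\n",
              x$confounder_effect_exposure, x$confounder_effect_outcome))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
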