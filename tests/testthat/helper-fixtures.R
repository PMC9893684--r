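# shared fixture builders for the test suite; everything is generated in
# code so the repository ships no binary data

small_config <- function(...) {
  defaults <- list(n_individuals = 4000L, n_variants = 10L, n_pcs = 2L,
                   seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# summary-stat table with explicit alleles, for harmonisation tests
make_sumstats <- function(snp, ea, oa, beta, se = 0.02,
                          eaf = 0.3, n = 10000) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa,
             eaf = rep_len(eaf, length(snp)), beta = beta,
             se = rep_len(se, length(snp)),
             pval = 2 * stats::pnorm(-abs(beta / rep_len(se, length(snp)))),
             n = n)
}

# harmonised-style data.frame straight from betas (wald_ratios accepts it)
make_harmonised_df <- function(bx, sx, by, sy) {
  data.frame(snp = sprintf("s%02d", seq_along(bx)),
             effect_allele = "A", other_allele = "G",
             beta_exposure = bx, se_exposure = sx,
             eaf_exposure = 0.3,
             beta_outcome = by, se_outcome = sy, eaf_outcome = 0.3)
}

# GRS from the generative truth: the known per-allele, per-sex effects.
# Used where a test targets an estimator rather than GRS construction.
true_weight_grs <- function(cohort) {
  tr <- attr(cohort, "truth")
  G <- as.matrix(cohort[, attr(cohort, "variants")$snp, drop = FALSE])
  ifelse(cohort$sex == "female",
         as.vector(G %*% tr$gamma[, "female"]),
         as.vector(G %*% tr$gamma[, "male"]))
}

# evaluate a random draw under a local seed without touching the session RNG
with_seed_vec <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# 99% binomial band for an empirical proportion
binom_band99 <- function(p, n) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}
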