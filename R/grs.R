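#' Rank-based inverse normal transformation
#'
#' Maps values through their ranks to standard-normal quantiles using the
#' Blom offset: \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}. Ties share the
#' average rank; NAs are preserved.
#'
#' @param x numeric vector with at least 2 finite values, not all identical.
#' @return numeric vector of the same length.
#' @export
rank_inverse_normal <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("need at least 2 finite values")
  if (length(unique(x[ok])) == 1L) stop("all values identical")
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  n <- sum(ok)
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Code variants by their trait-raising allele, sex-aware
#'
#' Regresses the rank-inverse-normal transformed trait on all variant
#' dosages simultaneously (a joint multivariate model), separately in males
#' and females, and codes each variant by its trait-raising allele. When
#' the raising allele differs between sexes, the sex with the larger
#' absolute effect decides, and the same coded allele is applied to both
#' sexes.
#'
#' @param cohort cohort data.frame containing dosage columns and a
#'   \code{sex} column ("male"/"female").
#' @param variants variant metadata data.frame (snp, effect_allele,
#'   other_allele); dosages count the effect allele.
#' @param trait name of the trait column (default "exposure"). RINT is
#'   applied within sex.
#' @return data.frame of class \code{variant_coding}: snp, coded_allele,
#'   \code{flip} (TRUE when the coded allele is the original other allele,
#'   i.e. dosages must be recoded g -> 2-g), per-sex betas/SEs on the coded
#'   scale, and \code{coding_source_sex} ("concordant", "male", "female").
#' @export
code_trait_raising_alleles <- function(cohort, variants, trait = "exposure") {
  snps <- variants$snp
  if (!all(snps %in% names(cohort))) stop("variants missing from cohort")
  if (!all(c("male", "female") %in% cohort$sex))
    stop("both sexes must be represented")
  fit_sex <- function(s) {
    rows <- cohort$sex == s
    G <- as.matrix(cohort[rows, snps, drop = FALSE])
    y <- rank_inverse_normal(cohort[[trait]][rows])
    X <- cbind(`(Intercept)` = 1, G)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) stop("singular design: collinear variants")
    fit <- lm.fit(X, y)
    res <- fit$residuals
    sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
    XtXinv <- chol2inv(qr.R(qr_x))
    list(beta = fit$coefficients[-1L],
         se = sqrt(diag(XtXinv)[-1L] * sigma2))
  }
  fm <- fit_sex("male"); ff <- fit_sex("female")
  bm <- fm$beta; bf <- ff$beta
  raise_m <- ifelse(bm >= 0, variants$effect_allele, variants$other_allele)
  raise_f <- ifelse(bf >= 0, variants$effect_allele, variants$other_allele)
  concord <- raise_m == raise_f
  decider <- ifelse(concord, "concordant",
                    ifelse(abs(bm) >= abs(bf), "male", "female"))
  coded <- ifelse(concord | decider == "male", raise_m, raise_f)
  flip <- coded != variants$effect_allele
  sgn <- ifelse(flip, -1, 1)
  out <- data.frame(snp = snps, coded_allele = coded, flip = flip,
                    beta_male = sgn * bm, se_male = fm$se,
                    beta_female = sgn * bf, se_female = ff$se,
                    coding_source_sex = decider)
  class(out) <- c("variant_coding", "data.frame")
  out
}

coded_dosages <- function(cohort, coding) {
  G <- as.matrix(cohort[, coding$snp, drop = FALSE])
  if (any(coding$flip))
    G[, coding$flip] <- 2 - G[, coding$flip, drop = FALSE]
  G
}

#' Cross-fitted leave-block-out GRS weights
#'
#' Within the unrelated derivation subset, individuals are split into K
#' randomly assigned blocks (balanced to within one individual). For each
#' block and each sex, a joint linear regression of the rank-inverse-normal
#' transformed trait on all coded dosages plus principal-component
#' covariates is fitted with that block removed, and the dosage
#' coefficients become the weights applied to the excluded block's members.
#' Individuals outside the derivation subset receive weights from the full
#' derivation-subset regression (recorded as block 0). Variants with cohort
#' MAF below \code{maf_min} are excluded before weighting.
#'
#' @param cohort cohort data.frame; needs dosage columns, \code{sex},
#'   \code{unrelated} (logical derivation-subset flag), the trait column,
#'   and the PC columns.
#' @param coding a \code{variant_coding} from
#'   \code{\link{code_trait_raising_alleles}}.
#' @param K number of blocks (default 100).
#' @param seed RNG seed for block assignment.
#' @param trait trait column name.
#' @param pcs character vector of covariate column names included in the
#'   weight regressions (their coefficients are discarded).
#' @param maf_min variants below this cohort MAF are excluded.
#' @return object of class \code{grs_weights}: list with \code{weights}
#'   (array [snp x block x sex], block "0" = full-sample fallback),
#'   \code{block} (per-cohort-row block id; 0 outside the derivation
#'   subset), \code{coding} (restricted to retained variants),
#'   \code{excluded_snps}, \code{K}, \code{seed}.
#' @export
crossfit_weights <- function(cohort, coding, K = 100L, seed = 1L,
                             trait = "exposure",
                             pcs = grep("^pc[0-9]+$", names(cohort), value = TRUE),
                             maf_min = 0.01) {
  if (K < 2L) stop("K must be at least 2")
  if (is.null(cohort$unrelated)) stop("cohort lacks an 'unrelated' flag")

  freq <- colMeans(as.matrix(cohort[, coding$snp, drop = FALSE])) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= maf_min
  excluded <- coding$snp[!keep]
  coding <- coding[keep, , drop = FALSE]
  if (!nrow(coding)) stop("no variants left after MAF screen")
  m <- nrow(coding)

  der <- which(cohort$unrelated)
  if (length(der) < K) stop("derivation subset smaller than K")
  block <- integer(nrow(cohort))  # 0 = not in derivation subset
  block[der] <- with_seed(seed, sample(rep_len(seq_len(K), length(der))))

  Gc <- coded_dosages(cohort, coding)
  sexes <- c("male", "female")
  W <- array(NA_real_, dim = c(m, K + 1L, 2L),
             dimnames = list(coding$snp, as.character(0:K), sexes))
  for (si in seq_along(sexes)) {
    rows <- der[cohort$sex[der] == sexes[si]]
    if (!length(rows)) stop("no derivation individuals of sex ", sexes[si])
    y <- rank_inverse_normal(cohort[[trait]][rows])
    X <- cbind(1, Gc[rows, , drop = FALSE],
               as.matrix(cohort[rows, pcs, drop = FALSE]))
    bl <- block[rows]
    W[, 1L, si] <- lm.fit(X, y)$coefficients[1L + seq_len(m)]
    for (b in seq_len(K)) {
      inb <- bl == b
      if (!any(!inb)) stop("block ", b, " leaves no training individuals")
      W[, b + 1L, si] <-
        lm.fit(X[!inb, , drop = FALSE], y[!inb])$coefficients[1L + seq_len(m)]
    }
  }
  structure(list(weights = W, block = block, coding = coding,
                 excluded_snps = excluded, K = K, seed = seed,
                 trait = trait, pcs = pcs),
            class = "grs_weights")
}

#' @export
print.grs_weights <- function(x, ...) {
  cat(sprintf("Cross-fitted GRS weights: %d variants, %d blocks (+ full-sample fallback)\n",
              nrow(x$coding), x$K))
  if (length(x$excluded_snps))
    cat(sprintf("  excluded by MAF screen: %d\n", length(x$excluded_snps)))
  cat(sprintf("  derivation individuals: %d\n", sum(x$block > 0)))
  invisible(x)
}

#' Score individuals with cross-fitted GRS weights
#'
#' Each individual's score is the weighted sum of coded dosages using the
#' weight vector estimated without their own block (full-sample weights for
#' individuals outside the derivation subset). Individuals with missing
#' dosages are returned as NA with a log attribute.
#'
#' @param cohort cohort data.frame.
#' @param weights a \code{grs_weights} object.
#' @return numeric vector aligned with cohort rows;
#'   \code{attr(,"n_dropped")} counts complete-case exclusions.
#' @export
compute_grs <- function(cohort, weights) {
  stopifnot(inherits(weights, "grs_weights"))
  Gc <- coded_dosages(cohort, weights$coding)
  score <- rep(NA_real_, nrow(cohort))
  cc <- complete.cases(Gc)
  sex_i <- match(cohort$sex, c("male", "female"))
  blk_i <- weights$block + 1L
  for (si in 1:2) {
    for (b in unique(blk_i)) {
      rows <- which(cc & sex_i == si & blk_i == b)
      if (length(rows))
        score[rows] <- Gc[rows, , drop = FALSE] %*% weights$weights[, b, si]
    }
  }
  attr(score, "n_dropped") <- sum(!cc)
  score
}

#' Instrument strength of a genetic risk score
#'
#' Per-stratum univariate regression of the raw trait on the score:
#' variance explained R^2 and F = R^2 (n-2) / (1 - R^2).
#'
#' @param cohort cohort data.frame.
#' @param score per-individual GRS (aligned with cohort rows).
#' @param strata optional column name(s) to stratify by (e.g. "sex");
#'   NULL computes a single overall row.
#' @param trait trait column name.
#' @return data.frame with stratum labels, r2, F, n.
#' @export
instrument_strength <- function(cohort, score, strata = "sex",
                                trait = "exposure") {
  grp <- if (is.null(strata)) factor(rep("all", nrow(cohort)))
  else interaction(cohort[strata], drop = TRUE, sep = ":")
  out <- lapply(levels(grp), function(g) {
    rows <- grp == g & is.finite(score) & is.finite(cohort[[trait]])
    n <- sum(rows)
    if (n < 3L) stop("stratum '", g, "' has fewer than 3 usable individuals")
    r2 <- cor(score[rows], cohort[[trait]][rows])^2
    data.frame(stratum = g, r2 = r2, F = r2 * (n - 2) / (1 - r2), n = n)
  })
  do.call(rbind, out)
}
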