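#' Two-stage instrumental-variable estimate within a stratum
#'
#' Stage 1 regresses the exposure on the genetic risk score plus covariates
#' (linear model); stage 2 regresses the binary outcome on the stage-1
#' fitted exposure plus the same covariates (logistic model, predictor
#' substitution). The fitted-exposure coefficient is rescaled to log-odds
#' per 1 SD of the exposure, with the SD taken from the full analysis
#' sample (not the stratum) so estimates are comparable across strata.
#'
#' Model-based stage-2 SEs ignore stage-1 sampling uncertainty; a seeded
#' nonparametric bootstrap SE is available via \code{n_boot}.
#'
#' @param cohort cohort data.frame.
#' @param grs per-individual score aligned with cohort rows.
#' @param outcome binary outcome column name.
#' @param covariates covariate column names used in both stages.
#' @param stratum logical vector selecting the stratum (default all rows).
#' @param exposure exposure column name.
#' @param exposure_sd SD used for per-1-SD scaling; default
#'   \code{sd(cohort[[exposure]])} over the full sample.
#' @param n_boot if > 0, number of bootstrap resamples for the SE.
#' @param seed bootstrap seed.
#' @return one-row data.frame: beta (log-odds/SD), se, pval, n_cases,
#'   n_controls, converged (FALSE flags separation/non-convergence; such
#'   strata should be dropped from meta-analysis).
#' @export
two_stage_estimate <- function(cohort, grs, outcome = "depressive_symptoms",
                               covariates = c("age"),
                               stratum = NULL, exposure = "exposure",
                               exposure_sd = NULL, n_boot = 0L, seed = 1L) {
  if (is.null(stratum)) stratum <- rep(TRUE, nrow(cohort))
  exposure_sd <- exposure_sd %||% sd(cohort[[exposure]], na.rm = TRUE)
  d <- cohort[stratum, , drop = FALSE]
  g <- grs[stratum]
  ok <- is.finite(g) & complete.cases(d[, c(outcome, exposure, covariates)])
  d <- d[ok, , drop = FALSE]; g <- g[ok]
  y <- d[[outcome]]
  n_cases <- sum(y == 1); n_controls <- sum(y == 0)
  if (n_cases < 1L || n_controls < 1L)
    stop("stratum needs at least one case and one control")
  if (var(g) == 0) stop("zero stage-1 slope: GRS constant within stratum")

  est_fun <- function(d, g) {
    Z <- cbind(1, grs = g, as.matrix(d[, covariates, drop = FALSE]))
    s1 <- lm.fit(Z, d[[exposure]])
    if (abs(s1$coefficients[["grs"]]) < .Machine$double.eps)
      stop("zero stage-1 slope")
    xhat <- s1$fitted.values
    X2 <- cbind(1, xhat = xhat, as.matrix(d[, covariates, drop = FALSE]))
    s2 <- glm.fit(X2, d[[outcome]], family = binomial())
    list(fit = s2, X = X2)
  }
  s2 <- est_fun(d, g)
  conv <- s2$fit$converged && !s2$fit$boundary &&
    !any(s2$fit$fitted.values < 1e-10 | s2$fit$fitted.values > 1 - 1e-10)
  beta_unit <- s2$fit$coefficients[["xhat"]]
  w <- s2$fit$weights
  XtWX <- crossprod(s2$X * sqrt(w))
  se_unit <- sqrt(diag(solve(XtWX))[2L])

  if (n_boot > 0L) {
    se_unit <- with_seed(seed, {
      bs <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(nrow(d), replace = TRUE)
        tryCatch(est_fun(d[idx, , drop = FALSE], g[idx])$fit$coefficients[["xhat"]],
                 error = function(e) NA_real_)
      }, numeric(1))
      sd(bs, na.rm = TRUE)
    })
  }
  beta <- beta_unit * exposure_sd
  se <- se_unit * exposure_sd
  data.frame(beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)),
             n_cases = n_cases, n_controls = n_controls, converged = conv)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools estimates with weights 1/se^2 and reports Cochran's Q (df = k-1)
#' and I^2 = max(0, (Q - df)/Q) * 100.
#'
#' @param estimates data.frame with columns \code{beta} and \code{se}
#'   (extra columns, e.g. stratum labels, are carried in
#'   \code{attr(,"strata")}).
#' @return one-row data.frame: beta, se, pval, or, ci_low, ci_high, k, Q,
#'   Q_df, Q_p, I2.
#' @export
fixed_effects_meta <- function(estimates) {
  est <- as.data.frame(estimates)
  if (!nrow(est)) stop("no estimates to pool")
  if (any(!is.finite(est$se)) || any(est$se <= 0))
    stop("all SEs must be finite and positive")
  w <- 1 / est$se^2
  beta <- sum(w * est$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- nrow(est)
  Q <- sum(w * (est$beta - beta)^2)
  Q_df <- k - 1
  Q_p <- if (Q_df >= 1) pchisq(Q, Q_df, lower.tail = FALSE) else NA_real_
  I2 <- if (Q <= 0) 0 else max(0, (Q - Q_df) / Q) * 100
  out <- data.frame(beta = beta, se = se,
                    pval = 2 * pnorm(-abs(beta / se)),
                    or = exp(beta),
                    ci_low = exp(beta - qnorm(0.975) * se),
                    ci_high = exp(beta + qnorm(0.975) * se),
                    k = k, Q = Q, Q_df = Q_df, Q_p = Q_p, I2 = I2)
  attr(out, "strata") <- est
  out
}

#' Fisher z comparison of two independent estimates
#'
#' z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2) with a two-sided normal
#' p-value; used to contrast male vs female and urban vs rural one-sample
#' estimates.
#'
#' @param a,b one-row data.frames (or lists) with \code{beta} and \code{se}.
#' @return list with \code{z} and \code{p}.
#' @export
fisher_z_compare <- function(a, b) {
  if (!is.finite(a$beta) || !is.finite(b$beta)) stop("non-finite betas")
  if (a$se <= 0 || b$se <= 0) stop("non-positive SEs")
  z <- (a$beta - b$beta) / sqrt(a$se^2 + b$se^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Convert between odds-ratio confidence intervals and log-odds scale
#'
#' \code{or_ci_to_beta_se} reconstructs beta = ln(OR) and
#' se = (ln(hi) - ln(lo)) / (2 * 1.959964) from a printed 95\% CI;
#' \code{beta_se_to_or_ci} is its inverse.
#'
#' @param or,ci_low,ci_high odds ratio and 95\% CI bounds,
#'   0 < ci_low < or < ci_high.
#' @return \code{or_ci_to_beta_se}: list(beta, se).
#' @export
or_ci_to_beta_se <- function(or, ci_low, ci_high) {
  if (!(0 < ci_low && ci_low < or && or < ci_high))
    stop("require 0 < ci_low < or < ci_high")
  list(beta = log(or),
       se = (log(ci_high) - log(ci_low)) / (2 * qnorm(0.975)))
}

#' @rdname or_ci_to_beta_se
#' @param beta,se log odds ratio and its standard error.
#' @return \code{beta_se_to_or_ci}: list(or, ci_low, ci_high).
#' @export
beta_se_to_or_ci <- function(beta, se) {
  list(or = exp(beta),
       ci_low = exp(beta - qnorm(0.975) * se),
       ci_high = exp(beta + qnorm(0.975) * se))
}

#' Stratified one-sample MR with fixed-effects pooling and contrasts
#'
#' Runs \code{\link{two_stage_estimate}} in every sex-by-region stratum,
#' then pools by fixed-effects meta-analysis into the nine groups of the
#' study design (all/male/female crossed with both/urban/rural regions) and
#' computes Fisher z contrasts: P_sex (male vs female within each region
#' group) and P_region (urban vs rural within each sex group). Strata whose
#' logistic stage failed to converge, and optionally strata with case
#' prevalence below \code{min_prevalence}, are dropped and logged.
#'
#' @inheritParams two_stage_estimate
#' @param min_prevalence strata with case prevalence strictly below this are
#'   excluded (NULL disables; the study's sensitivity analysis uses 0.01).
#' @return list of class \code{one_sample_result}: \code{strata}
#'   (per-stratum estimates), \code{groups} (pooled table with or, ci,
#'   pval, Q, I2, P_sex, P_region), \code{dropped} (stratum labels and
#'   reasons).
#' @export
one_sample_mr <- function(cohort, grs, outcome = "depressive_symptoms",
                          covariates = c("age"),
                          exposure = "exposure", exposure_sd = NULL,
                          min_prevalence = NULL) {
  exposure_sd <- exposure_sd %||% sd(cohort[[exposure]], na.rm = TRUE)
  combos <- expand.grid(sex = c("male", "female"),
                        region = sort(unique(cohort$region)),
                        stringsAsFactors = FALSE)
  strata <- list(); dropped <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- cohort$sex == combos$sex[i] & cohort$region == combos$region[i]
    lab <- sprintf("%s:region%s", combos$sex[i], combos$region[i])
    urban <- unique(cohort$urban[sel])
    prev <- mean(cohort[[outcome]][sel], na.rm = TRUE)
    if (!is.null(min_prevalence) && prev < min_prevalence) {
      dropped[[lab]] <- "low_prevalence"; next
    }
    est <- tryCatch(
      two_stage_estimate(cohort, grs, outcome, covariates, stratum = sel,
                         exposure = exposure, exposure_sd = exposure_sd),
      error = function(e) conditionMessage(e))
    if (is.character(est)) { dropped[[lab]] <- est; next }
    if (!est$converged) { dropped[[lab]] <- "non_converged"; next }
    strata[[lab]] <- cbind(data.frame(sex = combos$sex[i],
                                      region = combos$region[i],
                                      urban = urban), est)
  }
  strata <- do.call(rbind, strata)
  if (is.null(strata) || !nrow(strata)) stop("no estimable strata")

  groups <- expand.grid(sex_group = c("all", "male", "female"),
                        region_group = c("both", "urban", "rural"),
                        stringsAsFactors = FALSE)
  pool <- function(sg, rg) {
    sel <- rep(TRUE, nrow(strata))
    if (sg != "all") sel <- sel & strata$sex == sg
    if (rg == "urban") sel <- sel & strata$urban
    if (rg == "rural") sel <- sel & !strata$urban
    if (!any(sel)) return(NULL)
    fixed_effects_meta(strata[sel, , drop = FALSE])
  }
  res <- lapply(seq_len(nrow(groups)),
                function(i) pool(groups$sex_group[i], groups$region_group[i]))
  keep <- !vapply(res, is.null, logical(1))
  groups <- cbind(groups[keep, , drop = FALSE], do.call(rbind, res[keep]))
  rownames(groups) <- NULL

  gget <- function(sg, rg) {
    row <- groups[groups$sex_group == sg & groups$region_group == rg, ]
    if (nrow(row)) row else NULL
  }
  groups$P_sex <- NA_real_
  groups$P_region <- NA_real_
  for (rg in c("both", "urban", "rural")) {
    m <- gget("male", rg); f <- gget("female", rg)
    if (!is.null(m) && !is.null(f)) {
      p <- fisher_z_compare(m, f)$p
      groups$P_sex[groups$sex_group == "all" & groups$region_group == rg] <- p
    }
  }
  for (sg in c("all", "male", "female")) {
    u <- gget(sg, "urban"); r <- gget(sg, "rural")
    if (!is.null(u) && !is.null(r)) {
      p <- fisher_z_compare(u, r)$p
      groups$P_region[groups$sex_group == sg & groups$region_group == "both"] <- p
    }
  }
  structure(list(strata = strata, groups = groups,
                 dropped = dropped, exposure_sd = exposure_sd),
            class = "one_sample_result")
}

#' @export
print.one_sample_result <- function(x, ...) {
  cat("One-sample MR (two-stage IV, fixed-effects pooled)\n")
  cat(sprintf("  strata estimated: %d, dropped: %d; exposure SD = %.3f\n",
              nrow(x$strata), length(x$dropped), x$exposure_sd))
  print(x$groups[, c("sex_group", "region_group", "or", "ci_low", "ci_high",
                     "pval", "I2", "P_sex", "P_region")], digits = 3)
  invisible(x)
}
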