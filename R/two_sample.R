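#' Per-variant Wald ratio estimates
#'
#' The per-variant causal estimate beta_outcome / beta_exposure with the
#' first-order delta-method standard error se_outcome / |beta_exposure|,
#' which makes the inverse-variance weighted mean of the ratios exactly
#' equal to the zero-intercept weighted regression of outcome betas on
#' exposure betas. A second-order SE additionally propagating the exposure
#' SE is available via \code{second_order = TRUE}.
#'
#' @param hset a \code{harmonised_set} or a data.frame with columns
#'   \code{beta_exposure, se_exposure, beta_outcome, se_outcome} (and
#'   \code{snp}).
#' @param second_order use the second-order delta-method SE.
#' @return data.frame with snp, ratio, se, weight and the input betas.
#'   Variants with a zero exposure beta are dropped with a warning.
#' @export
wald_ratios <- function(hset, second_order = FALSE) {
  d <- harmonised_data(hset)
  if (!nrow(d)) stop("empty harmonised set")
  zero <- d$beta_exposure == 0
  if (any(zero)) {
    warning(sprintf("dropping %d variant(s) with zero exposure beta: %s",
                    sum(zero), paste(d$snp[zero], collapse = ", ")))
    d <- d[!zero, , drop = FALSE]
    if (!nrow(d)) stop("no variants left after dropping zero exposure betas")
  }
  ratio <- d$beta_outcome / d$beta_exposure
  se <- if (second_order) {
    sqrt(d$se_outcome^2 / d$beta_exposure^2 +
           d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4)
  } else {
    d$se_outcome / abs(d$beta_exposure)
  }
  data.frame(snp = d$snp, ratio = ratio, se = se, weight = 1 / se^2,
             beta_exposure = d$beta_exposure, se_exposure = d$se_exposure,
             beta_outcome = d$beta_outcome, se_outcome = d$se_outcome)
}

harmonised_data <- function(x) {
  if (inherits(x, "harmonised_set")) x$data
  else if (is.data.frame(x)) x
  else stop("expected a harmonised_set or data.frame")
}

as_wald_ratios <- function(x) {
  if (is.data.frame(x) && all(c("ratio", "se") %in% names(x))) {
    if (is.null(x$weight)) x$weight <- 1 / x$se^2
    x
  } else wald_ratios(x)
}

mr_estimate_row <- function(method, beta, se, n_snps,
                            Q = NA_real_, Q_df = NA_real_,
                            intercept = NA_real_, intercept_se = NA_real_) {
  Q_p <- if (is.na(Q) || Q_df < 1) NA_real_ else
    pchisq(Q, df = Q_df, lower.tail = FALSE)
  I2 <- if (is.na(Q) || Q <= 0) 0 else max(0, (Q - Q_df) / Q) * 100
  data.frame(method = method, n_snps = n_snps, beta = beta, se = se,
             or = exp(beta), ci_low = exp(beta - qnorm(0.975) * se),
             ci_high = exp(beta + qnorm(0.975) * se),
             pval = 2 * pnorm(-abs(beta / se)),
             Q = Q, Q_df = Q_df, Q_p = Q_p, I2 = I2,
             intercept = intercept, intercept_se = intercept_se,
             intercept_p = if (is.na(intercept)) NA_real_ else
               2 * pnorm(-abs(intercept / intercept_se)))
}

#' Inverse-variance weighted estimator
#'
#' Weighted mean of per-variant Wald ratios with weights 1/se^2. Under
#' \code{effects = "fixed"} the SE is \eqn{1/\sqrt{\sum w_i}}; under
#' \code{"random"} it is scaled multiplicatively by
#' \eqn{\sqrt{\max(1, Q/(k-1))}}. The default \code{"auto"} reports the
#' fixed-effects model unless Cochran's Q is significant at p < 0.05, in
#' which case the multiplicative random-effects scaling is applied —
#' heterogeneity among the causal estimates signals possible pleiotropy.
#'
#' @param x a \code{harmonised_set}, harmonised data.frame, or the output of
#'   \code{\link{wald_ratios}}.
#' @param effects "auto", "fixed" or "random".
#' @return one-row data.frame (method, n_snps, beta, se, or, ci, pval, Q,
#'   Q_df, Q_p, I2, intercept fields NA).
#' @export
mr_ivw <- function(x, effects = c("auto", "fixed", "random")) {
  effects <- match.arg(effects)
  r <- as_wald_ratios(x)
  k <- nrow(r)
  if (!k) stop("no Wald ratios supplied")
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  Q <- sum(w * (r$ratio - beta)^2)
  Q_df <- k - 1
  se_fixed <- 1 / sqrt(sum(w))
  scale <- if (k > 1) sqrt(max(1, Q / (k - 1))) else 1
  Q_p <- if (k > 1) pchisq(Q, Q_df, lower.tail = FALSE) else NA_real_
  use_random <- switch(effects,
                       fixed = FALSE,
                       random = TRUE,
                       auto = isTRUE(Q_p < 0.05))
  se <- if (use_random) se_fixed * scale else se_fixed
  mr_estimate_row(if (use_random) "IVW_random" else "IVW_fixed",
                  beta, se, k, Q = Q, Q_df = Q_df)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome betas on exposure betas with
#' a free intercept, weights 1/se_outcome^2. Pairs are first oriented so all
#' exposure betas are positive (jointly flipping the signs of both betas),
#' which makes the intercept interpretable as the average directional
#' pleiotropic effect. The residual dispersion is floored at 1
#' (multiplicative overdispersion), matching the random-effects IVW scaling.
#'
#' @param x a \code{harmonised_set} or harmonised data.frame (needs exposure
#'   betas, so Wald ratios alone are insufficient).
#' @return one-row data.frame; \code{beta} is the slope (causal estimate),
#'   \code{intercept}/\code{intercept_se}/\code{intercept_p} describe
#'   directional pleiotropy; Q is Rucker's heterogeneity about the Egger fit.
#' @export
mr_egger <- function(x) {
  d <- harmonised_data(if (inherits(x, "harmonised_set")) x else x)
  if (nrow(d) < 3L) stop("MR-Egger requires at least 3 variants")
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  if (length(unique(bx)) == 1L)
    stop("all exposure betas identical: Egger slope unidentifiable")
  w <- 1 / d$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  adj <- 1 / min(1, sm$sigma)  # floor residual dispersion at 1
  slope <- coef(fit)[["bx"]]
  slope_se <- sm$coefficients["bx", "Std. Error"] * adj
  int <- coef(fit)[["(Intercept)"]]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] * adj
  Q <- sum(w * residuals(fit)^2)
  mr_estimate_row("Egger", slope, slope_se, nrow(d), Q = Q, Q_df = nrow(d) - 2,
                  intercept = int, intercept_se = int_se)
}

# cumulative-weight interpolated median (Bowden et al. weighted median core)
weighted_median_point <- function(b, w) {
  if (any(w <= 0)) stop("non-positive weights")
  o <- order(b)
  b <- b[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  approx(s, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Orders the Wald ratios and interpolates the ratio at standardised
#' cumulative weight 0.5; consistent when at least 50\% of the weight comes
#' from valid instruments. The SE is a parametric bootstrap SD: per-variant
#' exposure and outcome betas are resampled from normal(beta, se), ratios
#' and weights recomputed, and the point estimate recomputed \code{n_boot}
#' times.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap draws for the SE.
#' @param seed RNG seed for the bootstrap.
#' @return one-row data.frame (method "WM").
#' @export
mr_weighted_median <- function(x, n_boot = 1000L, seed = 1L) {
  r <- as_wald_ratios(x)
  if (nrow(r) < 3L) stop("weighted median requires at least 3 variants")
  est <- weighted_median_point(r$ratio, r$weight)
  se <- boot_median_se(r, n_boot, seed, penalty = NULL)
  mr_estimate_row("WM", est, se, nrow(r))
}

#' Penalised weighted median estimator
#'
#' Down-weights heterogeneous variants before the weighted median: each
#' variant's contribution to Cochran's Q about the weighted-median estimate,
#' Q_j = w_j (ratio_j - WM)^2, is converted to an upper-tail chi-square(1)
#' probability p_j and the weight multiplied by min(1, penalty * p_j).
#'
#' @inheritParams mr_weighted_median
#' @param penalty penalisation constant (default 20, the published value;
#'   a variant with p_j >= 1/penalty is not penalised).
#' @return one-row data.frame (method "PWM").
#' @export
mr_penalised_weighted_median <- function(x, n_boot = 1000L, seed = 1L,
                                         penalty = 20) {
  r <- as_wald_ratios(x)
  if (nrow(r) < 3L) stop("penalised weighted median requires at least 3 variants")
  est <- pwm_point(r$ratio, r$weight, penalty)
  se <- boot_median_se(r, n_boot, seed, penalty = penalty)
  mr_estimate_row("PWM", est, se, nrow(r))
}

pwm_point <- function(b, w, penalty) {
  wm <- weighted_median_point(b, w)
  Qj <- w * (b - wm)^2
  pj <- pchisq(Qj, df = 1, lower.tail = FALSE)
  wp <- w * pmin(1, penalty * pj)
  keep <- wp > 0  # extreme outliers can be penalised to exactly zero
  weighted_median_point(b[keep], wp[keep])
}

boot_median_se <- function(r, n_boot, seed, penalty = NULL) {
  k <- nrow(r)
  have_betas <- !is.null(r$beta_exposure) && !is.null(r$beta_outcome)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(i) {
      if (have_betas) {
        bx <- rnorm(k, r$beta_exposure, r$se_exposure)
        by <- rnorm(k, r$beta_outcome, r$se_outcome)
        ok <- bx != 0
        ratio <- by[ok] / bx[ok]
        w <- (bx[ok] / r$se_outcome[ok])^2
      } else {
        # pre-computed ratios only: resample each ratio from its normal
        ratio <- rnorm(k, r$ratio, r$se)
        w <- r$weight
      }
      if (is.null(penalty)) weighted_median_point(ratio, w)
      else pwm_point(ratio, w, penalty)
    }, numeric(1))
    sd(ests)
  })
}

#' Median F statistic of instrument strength
#'
#' Per-variant F = (beta/se)^2 from the exposure GWAS, summarised by the
#' median across instruments.
#'
#' @param exposure summary-statistic data.frame with \code{beta} and
#'   \code{se} (e.g. the exposure side of a harmonised set, using columns
#'   \code{beta_exposure}/\code{se_exposure} if present).
#' @return list with per-variant \code{F} and \code{median_F}.
#' @export
median_f_statistic <- function(exposure) {
  d <- if (inherits(exposure, "harmonised_set")) exposure$data else exposure
  beta <- d$beta_exposure %||% d$beta
  se <- d$se_exposure %||% d$se
  if (is.null(beta) || !length(beta)) stop("no exposure records")
  if (any(se <= 0)) stop("non-positive exposure SE")
  F <- (beta / se)^2
  list(F = F, median_F = median(F))
}

#' Run all four two-sample MR estimators
#'
#' Convenience wrapper returning IVW (fixed and random), MR-Egger, weighted
#' median and penalised weighted median as one table, with the median F
#' statistic attached as an attribute.
#'
#' @inheritParams mr_weighted_median
#' @param penalty penalisation constant for PWM.
#' @return data.frame of estimates; \code{attr(,"median_F")}.
#' @export
mr_all <- function(x, n_boot = 1000L, seed = 1L, penalty = 20) {
  d <- harmonised_data(if (inherits(x, "harmonised_set")) x else x)
  res <- rbind(mr_ivw(d, effects = "fixed"),
               mr_ivw(d, effects = "random"),
               mr_egger(d),
               mr_weighted_median(d, n_boot = n_boot, seed = seed),
               mr_penalised_weighted_median(d, n_boot = n_boot, seed = seed,
                                            penalty = penalty))
  rownames(res) <- NULL
  attr(res, "median_F") <- median_f_statistic(d)$median_F
  res
}
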