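#' Control-function non-linear MR fit within a stratum
#'
#' Stage 1 regresses the exposure on the genetic risk score plus covariates
#' and retains the residual; stage 2 is a logistic regression of the
#' outcome on the exposure, its square, the covariates and the stage-1
#' residual. The residual term absorbs unmeasured confounding, so the
#' exposure and exposure-squared coefficients are causal (control-function)
#' estimates, and the Wald p-value of the quadratic term is the
#' non-linearity test.
#'
#' The exposure is mean-centred within the stratum before squaring to
#' reduce collinearity; the linear coefficient is back-transformed to the
#' raw scale (the quadratic coefficient is unaffected by centring).
#'
#' @inheritParams two_stage_estimate
#' @param quadratic include the squared-exposure term (default TRUE).
#'   With \code{quadratic = FALSE} the fit is the linear control-function
#'   estimator, comparable to \code{\link{two_stage_estimate}}.
#' @return one-row data.frame of class \code{cf_result}: beta_linear /
#'   se_linear (raw scale), beta_quadratic / se_quadratic / p_quadratic,
#'   beta_residual / se_residual, n, converged, centre (the mean used);
#'   the centred-scale coefficient covariance, and the observed exposure
#'   range, are attached as attributes for \code{\link{fitted_curve}}.
#' @export
control_function_fit <- function(cohort, grs, outcome = "depressive_symptoms",
                                 covariates = c("age"), stratum = NULL,
                                 exposure = "exposure", quadratic = TRUE) {
  if (is.null(stratum)) stratum <- rep(TRUE, nrow(cohort))
  d <- cohort[stratum, , drop = FALSE]
  g <- grs[stratum]
  ok <- is.finite(g) & complete.cases(d[, c(outcome, exposure, covariates)])
  d <- d[ok, , drop = FALSE]; g <- g[ok]
  if (var(g) == 0) stop("zero stage-1 slope: GRS constant within stratum")

  Z <- cbind(1, grs = g, as.matrix(d[, covariates, drop = FALSE]))
  s1 <- lm.fit(Z, d[[exposure]])
  res1 <- s1$residuals

  m <- mean(d[[exposure]])
  xc <- d[[exposure]] - m
  if (max(abs(cor(xc, res1)), na.rm = TRUE) > 0.999)
    warning("exposure and stage-1 residual are near-collinear")
  X2 <- if (quadratic)
    cbind(`(Intercept)` = 1, xc = xc, xc2 = xc^2,
          as.matrix(d[, covariates, drop = FALSE]), resid = res1)
  else
    cbind(`(Intercept)` = 1, xc = xc,
          as.matrix(d[, covariates, drop = FALSE]), resid = res1)
  s2 <- glm.fit(X2, d[[outcome]], family = binomial())
  conv <- s2$converged &&
    !any(s2$fitted.values < 1e-10 | s2$fitted.values > 1 - 1e-10)
  w <- s2$weights
  V <- solve(crossprod(X2 * sqrt(w)))
  cf <- s2$coefficients
  b1 <- cf[["xc"]]
  b2 <- if (quadratic) cf[["xc2"]] else 0
  br <- cf[["resid"]]
  i1 <- which(colnames(X2) == "xc")
  i2 <- if (quadratic) which(colnames(X2) == "xc2") else NA_integer_
  ir <- which(colnames(X2) == "resid")
  # raw-scale linear coefficient: b1 - 2 m b2 (delta method for its SE)
  b1_raw <- b1 - 2 * m * b2
  if (quadratic) {
    v_raw <- V[i1, i1] + 4 * m^2 * V[i2, i2] - 4 * m * V[i1, i2]
    se_q <- sqrt(V[i2, i2])
    p_q <- 2 * pnorm(-abs(b2 / se_q))
    vc <- V[c(i1, i2), c(i1, i2)]
  } else {
    v_raw <- V[i1, i1]
    se_q <- NA_real_; p_q <- NA_real_
    vc <- matrix(c(V[i1, i1], 0, 0, 0), 2, 2)
  }
  out <- data.frame(beta_linear = b1_raw, se_linear = sqrt(v_raw),
                    beta_quadratic = if (quadratic) b2 else NA_real_,
                    se_quadratic = se_q, p_quadratic = p_q,
                    beta_residual = br, se_residual = sqrt(V[ir, ir]),
                    n = nrow(d), converged = conv, centre = m)
  class(out) <- c("cf_result", "data.frame")
  attr(out, "vcov_centred") <- vc
  attr(out, "beta_centred") <- c(linear = b1, quadratic = b2)
  attr(out, "exposure_range") <- range(d[[exposure]])
  out
}

#' Construct a control-function result from known coefficients
#'
#' Utility for building a \code{cf_result} directly from centred-scale
#' coefficients, e.g. to plot analytic curves.
#'
#' @param beta_linear,beta_quadratic centred-scale coefficients.
#' @param vcov 2x2 covariance of (linear, quadratic); default zero.
#' @param centre centring constant (default 0).
#' @param exposure_range observed exposure range (default unbounded).
#' @return a \code{cf_result}.
#' @export
cf_result <- function(beta_linear, beta_quadratic,
                      vcov = matrix(0, 2, 2), centre = 0,
                      exposure_range = c(-Inf, Inf)) {
  out <- data.frame(beta_linear = beta_linear - 2 * centre * beta_quadratic,
                    se_linear = sqrt(vcov[1, 1]),
                    beta_quadratic = beta_quadratic,
                    se_quadratic = sqrt(vcov[2, 2]),
                    p_quadratic = NA_real_, beta_residual = 0,
                    se_residual = NA_real_, n = NA_integer_,
                    converged = TRUE, centre = centre)
  class(out) <- c("cf_result", "data.frame")
  attr(out, "vcov_centred") <- vcov
  attr(out, "beta_centred") <- c(linear = beta_linear,
                                 quadratic = beta_quadratic)
  attr(out, "exposure_range") <- exposure_range
  out
}

#' Fitted non-linear exposure-outcome curve
#'
#' Evaluates the quadratic control-function log-odds curve
#' \eqn{\beta_1 (x - m) + \beta_2 (x - m)^2} on a grid, with pointwise
#' standard errors from the coefficient covariance (the residual term is
#' set to its mean, zero).
#'
#' @param result a \code{cf_result}.
#' @param grid numeric vector of exposure values; values outside the
#'   observed exposure range trigger a warning and are flagged.
#' @return data.frame: x, eta (log-odds relative to the centre), se,
#'   \code{extrapolated}.
#' @export
fitted_curve <- function(result, grid) {
  stopifnot(inherits(result, "cf_result"))
  b <- attr(result, "beta_centred")
  V <- attr(result, "vcov_centred")
  rng <- attr(result, "exposure_range")
  xc <- grid - result$centre
  eta <- b[["linear"]] * xc + b[["quadratic"]] * xc^2
  se <- sqrt(pmax(0, xc^2 * V[1, 1] + xc^4 * V[2, 2] + 2 * xc^3 * V[1, 2]))
  extra <- grid < rng[1] | grid > rng[2]
  if (any(extra))
    warning(sprintf("%d grid point(s) outside the observed exposure range",
                    sum(extra)))
  data.frame(x = grid, eta = eta, se = se, extrapolated = extra)
}
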