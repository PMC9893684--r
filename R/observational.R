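#' Observational odds ratio per 1-SD exposure
#'
#' Conventional logistic regression of the outcome on the standardised
#' exposure plus adjustment covariates — the estimate against which the MR
#' results are contrasted. Standardisation uses the full-sample SD so
#' per-SD estimates are comparable across strata and invariant to affine
#' rescaling of the exposure.
#'
#' @param cohort cohort data.frame.
#' @param outcome binary outcome column.
#' @param covariates adjustment columns (default age, sex, region; region
#'   entered as a factor). Extend via config for SES/smoking-style
#'   sensitivity adjustments.
#' @param stratum logical row selector (default all).
#' @param exposure exposure column.
#' @param exposure_sd SD for scaling; default full-sample SD.
#' @return one-row data.frame: beta, se, or, ci_low, ci_high, pval,
#'   n_cases, n_controls.
#' @export
logistic_or_per_sd <- function(cohort, outcome = "depressive_symptoms",
                               covariates = c("age", "sex", "region"),
                               stratum = NULL, exposure = "exposure",
                               exposure_sd = NULL) {
  if (is.null(stratum)) stratum <- rep(TRUE, nrow(cohort))
  exposure_sd <- exposure_sd %||% sd(cohort[[exposure]], na.rm = TRUE)
  d <- cohort[stratum, , drop = FALSE]
  d <- d[complete.cases(d[, c(outcome, exposure, covariates)]), , drop = FALSE]
  d$.xstd <- (d[[exposure]] - mean(d[[exposure]])) / exposure_sd
  covs <- covariates[vapply(covariates, function(v)
    length(unique(d[[v]])) > 1L, logical(1))]  # drop constants within stratum
  if ("region" %in% covs) d$region <- factor(d$region)
  fml <- stats::reformulate(c(".xstd", covs), response = outcome)
  fit <- glm(fml, data = d, family = binomial())
  if (!fit$converged) warning("logistic model did not converge")
  cf <- summary(fit)$coefficients
  beta <- cf[".xstd", "Estimate"]; se <- cf[".xstd", "Std. Error"]
  data.frame(beta = beta, se = se, or = exp(beta),
             ci_low = exp(beta - qnorm(0.975) * se),
             ci_high = exp(beta + qnorm(0.975) * se),
             pval = 2 * pnorm(-abs(beta / se)),
             n_cases = sum(d[[outcome]] == 1),
             n_controls = sum(d[[outcome]] == 0))
}

#' BMI category assignment (Chinese working-group definitions)
#'
#' Half-open intervals: underweight [-Inf, 18.5), normal [18.5, 24),
#' overweight [24, 28), obese [28, Inf). The printed clinical definitions
#' leave rounding gaps (23.9--24, 27.9--28); the half-open intervals close
#' them so every value is classified while retaining the printed labels.
#'
#' @param bmi numeric vector.
#' @param breaks interval boundaries (ascending).
#' @param labels category labels, one fewer than breaks has entries + 1.
#' @return factor of categories.
#' @export
bmi_category <- function(bmi, breaks = c(-Inf, 18.5, 24, 28, Inf),
                         labels = c("underweight", "normal",
                                    "overweight", "obese")) {
  cut(bmi, breaks = breaks, labels = labels, right = FALSE)
}

#' Per-category odds ratios versus a reference category
#'
#' One logistic fit per non-reference category: a binary contrast of that
#' category versus the reference, with other categories dropped from the
#' fit. Underweight individuals are always excluded from the binary
#' measures.
#'
#' @inheritParams logistic_or_per_sd
#' @param reference reference category name (default "normal").
#' @param exclude categories excluded entirely (default "underweight").
#' @return data.frame, one row per contrasted category, with or, ci, pval
#'   and per-group counts.
#' @export
category_or <- function(cohort, outcome = "depressive_symptoms",
                        covariates = c("age", "sex", "region"),
                        exposure = "exposure", reference = "normal",
                        exclude = "underweight") {
  cat_ <- bmi_category(cohort[[exposure]])
  if (!any(cat_ == reference, na.rm = TRUE)) stop("empty reference category")
  targets <- setdiff(levels(cat_), c(reference, exclude))
  out <- lapply(targets, function(tc) {
    sel <- !is.na(cat_) & cat_ %in% c(reference, tc)
    d <- cohort[sel, , drop = FALSE]
    d$.incat <- as.integer(cat_[sel] == tc)
    d <- d[complete.cases(d[, c(outcome, covariates)]), , drop = FALSE]
    if (!any(d$.incat == 1L)) stop("empty category: ", tc)
    if ("region" %in% covariates) d$region <- factor(d$region)
    covs <- covariates[vapply(covariates, function(v)
      length(unique(d[[v]])) > 1L, logical(1))]
    fml <- stats::reformulate(c(".incat", covs), response = outcome)
    fit <- glm(fml, data = d, family = binomial())
    cf <- summary(fit)$coefficients
    beta <- cf[".incat", "Estimate"]; se <- cf[".incat", "Std. Error"]
    data.frame(category = tc, reference = reference, beta = beta, se = se,
               or = exp(beta),
               ci_low = exp(beta - qnorm(0.975) * se),
               ci_high = exp(beta + qnorm(0.975) * se),
               pval = 2 * pnorm(-abs(beta / se)),
               n_category = sum(d$.incat == 1), n_reference = sum(d$.incat == 0))
  })
  do.call(rbind, out)
}
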