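#' Significance tier of a p-value
#'
#' Applies the study's reporting convention: p below the
#' multiple-testing-corrected threshold is "corrected" evidence, p below
#' the tentative threshold is "tentative", otherwise "none". The corrected
#' threshold is 0.025 for the two-sample analyses (two trait groups) and
#' 0.013 for the one-sample analyses (four trait-by-setting groups).
#'
#' @param p p-value(s).
#' @param tentative tentative-evidence threshold (default 0.05).
#' @param corrected corrected threshold (0.025 two-sample, 0.013 one-sample).
#' @return character vector in \{"none", "tentative", "corrected"\}.
#' @export
significance_tier <- function(p, tentative = 0.05, corrected = 0.025) {
  stopifnot(tentative > 0, tentative < 1, corrected > 0, corrected < 1)
  ifelse(p < corrected, "corrected",
         ifelse(p < tentative, "tentative", "none"))
}

#' Baseline-characteristics summary by case status
#'
#' Table-1-style summary: continuous variables as mean (SD) per group with
#' a linear-regression comparison p-value; binary and categorical variables
#' as N (column \%) per level with a logistic-regression p-value (the case
#' indicator regressed on the variable).
#'
#' @param cohort cohort data.frame.
#' @param case name of the binary case-indicator column.
#' @param continuous,categorical character vectors of column names.
#' @return data.frame: variable, level (NA for continuous), case / control
#'   summaries (n, pct or mean, sd), p.
#' @export
summarize_demographics <- function(cohort, case = "depressive_symptoms",
                                   continuous = c("age", "exposure"),
                                   categorical = c("sex", "urban")) {
  y <- cohort[[case]]
  if (!all(y %in% c(0, 1))) stop("case indicator must be binary")
  if (!any(y == 1) || !any(y == 0)) stop("empty case or control group")
  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    p <- summary(lm(x ~ y))$coefficients["y", "Pr(>|t|)"]
    rows[[v]] <- data.frame(
      variable = v, level = NA_character_,
      case_n = sum(y == 1), case_mean = mean(x[y == 1]),
      case_sd = sd(x[y == 1]), case_pct = NA_real_,
      control_n = sum(y == 0), control_mean = mean(x[y == 0]),
      control_sd = sd(x[y == 0]), control_pct = NA_real_, p = p)
  }
  for (v in categorical) {
    x <- factor(cohort[[v]])
    p <- if (nlevels(x) < 2L) 1 else {
      fit0 <- glm(y ~ 1, family = binomial())
      fit1 <- glm(y ~ x, family = binomial())
      stats::anova(fit0, fit1, test = "Chisq")$`Pr(>Chi)`[2]
    }
    for (lev in levels(x)) {
      nc <- sum(x == lev & y == 1); nn <- sum(x == lev & y == 0)
      rows[[paste(v, lev)]] <- data.frame(
        variable = v, level = lev,
        case_n = nc, case_mean = NA_real_, case_sd = NA_real_,
        case_pct = round(100 * nc / sum(y == 1), 1),
        control_n = nn, control_mean = NA_real_, control_sd = NA_real_,
        control_pct = round(100 * nn / sum(y == 0), 1), p = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default analysis configuration
#'
#' All pipeline defaults in one list: simulation parameters (see
#' \code{\link{sim_config}}), harmonisation filters (allele-frequency
#' window 0.45--0.55), estimator options (K = 100 cross-fitting blocks,
#' 1000 bootstrap draws, penalty constant 20), and significance thresholds
#' (tentative 0.05; corrected 0.025 two-sample, 0.013 one-sample).
#'
#' @param ... overrides merged into the defaults (nested lists merged
#'   shallowly).
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulation = list(n_individuals = 20000L, n_variants = 50L),
    filters = list(maf_window = c(0.45, 0.55)),
    estimators = list(n_boot = 1000L, penalty = 20, K = 100L),
    thresholds = list(tentative = 0.05, two_sample = 0.025,
                      one_sample = 0.013),
    outcome = "depressive_symptoms",
    covariates = c("age"),
    min_prevalence = NULL)
  modifyList(cfg, list(...))
}

#' Read a YAML analysis configuration
#'
#' Loads a YAML file and merges it over \code{\link{default_config}},
#' validating thresholds and seed.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), user)
  th <- unlist(cfg$thresholds)
  if (any(th <= 0 | th >= 1)) stop("thresholds must lie in (0,1)")
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage in dependency order: cohort and two-sample
#' summary-statistic simulation, harmonisation and exclusion filters, the
#' four two-sample MR estimators with instrument diagnostics, cross-fitted
#' GRS construction and strength, stratified one-sample two-stage IV
#' estimation with fixed-effects pooling and Fisher z contrasts,
#' control-function non-linear MR, observational per-SD and category
#' models, and a baseline-characteristics table. Every result table gains
#' a \code{tier} column from \code{\link{significance_tier}}. Identical
#' config and seed give identical outputs.
#'
#' @param config list from \code{\link{default_config}} or
#'   \code{\link{read_config}}.
#' @param out_dir optional directory; when given, all tables are written as
#'   headered TSVs plus a JSON run manifest recording the seed and all
#'   settings.
#' @return list of class \code{pipeline_result} with elements
#'   \code{two_sample}, \code{one_sample}, \code{nonlinear},
#'   \code{observational}, \code{categories}, \code{grs_strength},
#'   \code{demographics}, \code{harmonisation}, \code{manifest}.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  sim_args <- c(config$simulation, list(seed = config$seed))
  scfg <- stage("simulate", do.call(sim_config, sim_args))
  cohort <- stage("simulate", simulate_cohort(scfg))
  variants <- attr(cohort, "variants")

  pair <- stage("simulate_sumstats", simulate_sumstats_pair(scfg))
  hs <- stage("harmonise",
              align_effect_alleles(pair$exposure_stats, pair$outcome_stats))
  hs <- stage("harmonise", apply_exclusion_filters(hs, config$filters))

  ts <- stage("two_sample",
              mr_all(hs, n_boot = config$estimators$n_boot,
                     seed = config$seed, penalty = config$estimators$penalty))
  ts$tier <- significance_tier(ts$pval, config$thresholds$tentative,
                               config$thresholds$two_sample)

  coding <- stage("grs", code_trait_raising_alleles(cohort, variants))
  K_eff <- min(config$estimators$K,
               max(2L, floor(sum(cohort$unrelated) / 50)))
  wts <- stage("grs", crossfit_weights(cohort, coding, K = K_eff,
                                       seed = config$seed))
  grs <- stage("grs", compute_grs(cohort, wts))
  strength <- stage("grs", instrument_strength(cohort, grs, strata = "sex"))

  os <- stage("one_sample",
              one_sample_mr(cohort, grs, outcome = config$outcome,
                            covariates = config$covariates,
                            min_prevalence = config$min_prevalence))
  os$groups$tier <- significance_tier(os$groups$pval,
                                      config$thresholds$tentative,
                                      config$thresholds$one_sample)

  nl <- stage("nonlinear", {
    res <- lapply(c(urban = TRUE, rural = FALSE), function(u) {
      control_function_fit(cohort, grs, outcome = config$outcome,
                           covariates = config$covariates,
                           stratum = cohort$urban == u)
    })
    data.frame(region_group = names(res), do.call(rbind, res),
               row.names = NULL)
  })
  nl$tier <- significance_tier(nl$p_quadratic, config$thresholds$tentative,
                               config$thresholds$one_sample)

  obs <- stage("observational", {
    rows <- list(
      all = logistic_or_per_sd(cohort, outcome = config$outcome),
      male = logistic_or_per_sd(cohort, outcome = config$outcome,
                                stratum = cohort$sex == "male"),
      female = logistic_or_per_sd(cohort, outcome = config$outcome,
                                  stratum = cohort$sex == "female"))
    data.frame(stratum = names(rows), do.call(rbind, rows),
               row.names = NULL)
  })
  obs$tier <- significance_tier(obs$pval, config$thresholds$tentative,
                                config$thresholds$one_sample)
  cats <- stage("observational", category_or(cohort, outcome = config$outcome))
  demo <- stage("report", summarize_demographics(cohort, case = config$outcome))

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("adimr")),
                   config = config[setdiff(names(config), "simulation")],
                   simulation = config$simulation,
                   n_individuals = nrow(cohort),
                   n_variants = nrow(variants),
                   K_blocks = K_eff,
                   grs_fallback = "non-derivation individuals scored with full-derivation-subset weights",
                   harmonisation_exclusions = as.list(table(hs$exclusions$reason)))

  out <- structure(list(two_sample = ts, one_sample = os, nonlinear = nl,
                        observational = obs, categories = cats,
                        grs_strength = strength, demographics = demo,
                        harmonisation = hs, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  invisible(out)
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(result$two_sample, "two_sample_mr.tsv")
  wt(result$one_sample$strata, "one_sample_strata.tsv")
  wt(result$one_sample$groups, "one_sample_groups.tsv")
  wt(result$nonlinear, "nonlinear_mr.tsv")
  wt(result$observational, "observational.tsv")
  wt(result$categories, "observational_categories.tsv")
  wt(result$grs_strength, "grs_strength.tsv")
  wt(result$demographics, "demographics.tsv")
  wt(result$harmonisation$exclusions, "harmonisation_exclusions.tsv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("adimr pipeline result\n")
  cat(sprintf("  cohort: %d individuals, %d variants (seed %d)\n",
              x$manifest$n_individuals, x$manifest$n_variants,
              x$manifest$seed))
  cat("\nTwo-sample MR:\n")
  print(x$two_sample[, c("method", "n_snps", "or", "ci_low", "ci_high",
                         "pval", "tier")], digits = 3)
  cat("\nOne-sample MR (pooled groups):\n")
  print(x$one_sample$groups[, c("sex_group", "region_group", "or",
                                "ci_low", "ci_high", "pval", "I2", "tier")],
        digits = 3)
  invisible(x)
}

#' Write / read a cohort as headered TSVs
#'
#' The cohort table is written as \code{cohort.tsv} (one row per
#' individual, dosage columns named by variant id) and its variant
#' metadata as \code{variants.tsv} (snp, effect_allele, other_allele,
#' maf).
#'
#' @param cohort cohort data.frame from \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{read_cohort}: the cohort with the variants table
#'   re-attached as \code{attr(,"variants")}.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(cohort, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(attr(cohort, "variants"), file.path(dir, "variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cohort <- read.delim(file.path(dir, "cohort.tsv"),
                       stringsAsFactors = FALSE, check.names = FALSE)
  attr(cohort, "variants") <- read.delim(file.path(dir, "variants.tsv"),
                                         stringsAsFactors = FALSE)
  cohort
}
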