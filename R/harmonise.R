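#' Align exposure and outcome summary statistics to a common effect allele
#'
#' For every variant present in the exposure dataset, looks up the outcome
#' dataset: if the outcome's effect allele matches the exposure's, the pair
#' is kept as-is; if effect and other alleles are swapped, the outcome beta
#' is negated and its effect-allele frequency replaced by 1 - eaf; variants
#' absent from the outcome are logged as \code{missing_in_outcome} and
#' irreconcilable allele pairs as \code{allele_mismatch}. Strand
#' (complement) flips are deliberately not attempted; palindromic-variant
#' risk is handled downstream by the allele-frequency window filter
#' (\code{\link{apply_exclusion_filters}}).
#'
#' @param exposure,outcome summary-statistic data.frames with columns
#'   \code{snp, effect_allele, other_allele, eaf, beta, se} (and optionally
#'   \code{pval, n}).
#' @return an object of class \code{harmonised_set}: list with \code{data}
#'   (snp, effect_allele, other_allele, beta_exposure, se_exposure,
#'   eaf_exposure, beta_outcome, se_outcome, eaf_outcome) and
#'   \code{exclusions} (snp, reason).
#' @export
align_effect_alleles <- function(exposure, outcome) {
  check_sumstats(exposure, "exposure")
  check_sumstats(outcome, "outcome")
  om <- outcome[match(exposure$snp, outcome$snp), ]
  ea_x <- toupper(exposure$effect_allele); oa_x <- toupper(exposure$other_allele)
  ea_y <- toupper(om$effect_allele);       oa_y <- toupper(om$other_allele)

  missing <- is.na(om$snp)
  same <- !missing & ea_x == ea_y & oa_x == oa_y
  swapped <- !missing & ea_x == oa_y & oa_x == ea_y
  mismatch <- !missing & !same & !swapped

  beta_out <- ifelse(swapped, -om$beta, om$beta)
  eaf_out <- ifelse(swapped, 1 - om$eaf, om$eaf)

  keep <- same | swapped
  data <- data.frame(snp = exposure$snp[keep],
                     effect_allele = exposure$effect_allele[keep],
                     other_allele = exposure$other_allele[keep],
                     beta_exposure = exposure$beta[keep],
                     se_exposure = exposure$se[keep],
                     eaf_exposure = exposure$eaf[keep],
                     beta_outcome = beta_out[keep],
                     se_outcome = om$se[keep],
                     eaf_outcome = eaf_out[keep])
  exclusions <- data.frame(
    snp = exposure$snp[!keep],
    reason = ifelse(missing[!keep], "missing_in_outcome", "allele_mismatch"))
  new_harmonised_set(data, exclusions)
}

new_harmonised_set <- function(data, exclusions) {
  structure(list(data = data, exclusions = exclusions),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("Harmonised summary statistics: %d variants retained, %d excluded\n",
              nrow(x$data), nrow(x$exclusions)))
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}

check_sumstats <- function(df, what) {
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s dataset lacks columns: %s", what,
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$snp))
    stop(sprintf("duplicate variant ids in %s dataset", what))
  if (any(df$se <= 0)) stop(sprintf("non-positive SE in %s dataset", what))
  if (any(toupper(df$effect_allele) == toupper(df$other_allele)))
    stop(sprintf("identical effect and other allele in %s dataset", what))
  invisible(TRUE)
}

#' Apply variant exclusion filters to a harmonised set
#'
#' Implements the sensitivity-analysis filters applied before two-sample MR:
#' \describe{
#'   \item{\code{maf_window = c(lo, hi)}}{removes variants whose
#'     outcome-dataset minor allele frequency, \code{min(eaf, 1-eaf)}, lies
#'     strictly inside \code{(lo, hi)} — guards against harmonisation error
#'     for near-palindromic variants with MAF close to 0.50. Boundary values
#'     are retained (strict inequalities).}
#'   \item{\code{discordant_raising_allele = data.frame(snp, raising_allele)}}{
#'     removes variants whose trait-raising allele in the supplied reference
#'     ancestry differs from the exposure dataset's trait-raising allele
#'     (the effect allele when beta > 0, else the other allele).}
#'   \item{\code{named_snps = c(...)}}{removes explicitly listed variant ids,
#'     e.g. the MC4R variant rs2229616.}
#' }
#' Filters are applied in the order above; each removed variant receives the
#' first applicable reason.
#'
#' @param hset a \code{harmonised_set} from \code{\link{align_effect_alleles}}.
#' @param filters named list with any of \code{maf_window},
#'   \code{discordant_raising_allele}, \code{named_snps}.
#' @return a \code{harmonised_set} with filtered \code{data}, an extended
#'   exclusion log, and \code{attr(,"filter_counts")} giving the number
#'   removed by each filter.
#' @export
apply_exclusion_filters <- function(hset, filters = list()) {
  stopifnot(inherits(hset, "harmonised_set"))
  known <- c("maf_window", "discordant_raising_allele", "named_snps")
  unknown <- setdiff(names(filters), known)
  if (length(unknown))
    stop("unknown filter name(s): ", paste(unknown, collapse = ", "))

  d <- hset$data
  reason <- rep(NA_character_, nrow(d))

  if (!is.null(filters$maf_window)) {
    w <- filters$maf_window
    if (length(w) != 2L || w[1] >= w[2])
      stop("maf_window must be c(lo, hi) with lo < hi")
    maf <- pmin(d$eaf_outcome, 1 - d$eaf_outcome)
    hit <- maf > w[1] & maf < w[2]
    reason[is.na(reason) & hit] <- "maf_window"
  }
  if (!is.null(filters$discordant_raising_allele)) {
    ref <- filters$discordant_raising_allele
    stopifnot(all(c("snp", "raising_allele") %in% names(ref)))
    raising_here <- ifelse(d$beta_exposure > 0,
                           toupper(d$effect_allele), toupper(d$other_allele))
    ref_ra <- toupper(ref$raising_allele[match(d$snp, ref$snp)])
    hit <- !is.na(ref_ra) & ref_ra != raising_here
    reason[is.na(reason) & hit] <- "discordant_raising_allele"
  }
  if (!is.null(filters$named_snps)) {
    hit <- d$snp %in% filters$named_snps
    reason[is.na(reason) & hit] <- "named_snp"
  }

  removed <- !is.na(reason)
  out <- new_harmonised_set(
    d[!removed, , drop = FALSE],
    rbind(hset$exclusions,
          data.frame(snp = d$snp[removed], reason = reason[removed])))
  counts <- table(factor(reason[removed],
                         levels = c("maf_window", "discordant_raising_allele",
                                    "named_snp")))
  attr(out, "filter_counts") <- as.list(counts)
  out
}

#' Read / write the summary-statistic TSV dialect
#'
#' Headered tab-separated files with columns
#' \code{snp, effect_allele, other_allele, eaf, beta, se, pval, n}.
#'
#' @param path file path.
#' @param df summary-statistic data.frame.
#' @return \code{read_sumstats}: a validated data.frame.
#' @export
read_sumstats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_sumstats(df, path)
  df
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
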