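#' Calibration settings for the naive substitution rate
#'
#' Divergence to the outgroup accrues along both lineages, so counts are
#' divided by twice the assumed root age and by the number of callable
#' sites.
#'
#' @param n_callable_sites number of positions amenable to variant calling.
#' @param root_age_years assumed TMRCA at the tree root; default 1.5 million
#'   years (dog/wolf-coyote divergence).
#' @param two_lineage_factor fixed at 2.
#' @return list of class `calibration_config`.
#' @export
calibration_config <- function(n_callable_sites, root_age_years = 1.5e6,
                               two_lineage_factor = 2) {
  if (n_callable_sites <= 0) stop("n_callable_sites must be positive")
  if (root_age_years <= 0) stop("root_age_years must be positive")
  structure(list(n_callable_sites = n_callable_sites,
                 root_age_years = root_age_years,
                 two_lineage_factor = two_lineage_factor),
            class = "calibration_config")
}

#' Count substitutions between a sample and the outgroup
#'
#' Counts callable sites where both calls are present (non-missing,
#' non-heterozygous) and the alleles differ. Sites with a missing call in
#' either member contribute nothing.
#'
#' @param gm a [genotype_matrix()].
#' @param sample,outgroup sample IDs.
#' @param callable_sites optional 0-based positions to restrict to; default
#'   all sites in the matrix.
#' @return integer substitution count.
#' @export
pairwise_substitutions <- function(gm, sample, outgroup,
                                   callable_sites = NULL) {
  for (s in c(sample, outgroup))
    if (!s %in% gm_samples(gm)) stop("unknown sample: ", s)
  keep <- if (is.null(callable_sites)) rep(TRUE, ncol(gm$geno)) else
    gm$pos %in% callable_sites
  a <- gm$geno[sample, keep]
  b <- gm$geno[outgroup, keep]
  ok <- !is.na(a) & !is.na(b) & a %in% c(0L, 1L) & b %in% c(0L, 1L)
  sum(a[ok] != b[ok])
}

#' Mean and s.d. of ingroup-to-outgroup substitution counts
#'
#' @param gm a [genotype_matrix()].
#' @param ingroup ingroup sample IDs (non-empty).
#' @param outgroup outgroup sample ID.
#' @param callable_sites optional positions to restrict to.
#' @return list with `mean`, `sd` (sample s.d., n-1 denominator; `NA` for a
#'   single sample) and the per-sample `counts`.
#' @export
cohort_substitution_summary <- function(gm, ingroup, outgroup,
                                        callable_sites = NULL) {
  if (length(ingroup) == 0) stop("ingroup must be non-empty")
  counts <- vapply(ingroup, function(s)
    pairwise_substitutions(gm, s, outgroup, callable_sites), numeric(1))
  list(mean = mean(counts),
       sd = if (length(counts) >= 2) sd(counts) else NA_real_,
       counts = counts)
}

#' Naive calibrated substitution rate
#'
#' `rate = mean_substitutions / (n_callable_sites * 2 * root_age_years)`,
#' in substitutions per site per year. Summaries print 3 significant
#' figures; full precision is retained in the object.
#'
#' @param mean_substitutions mean ingroup-outgroup substitution count.
#' @param calib a [calibration_config()].
#' @param sd_substitutions optional s.d. of the counts, echoed in the result.
#' @return list of class `rate_estimate` with `rate`, `mean_substitutions`,
#'   `sd_substitutions` and the calibration inputs.
#' @export
naive_rate <- function(mean_substitutions, calib,
                       sd_substitutions = NA_real_) {
  if (!inherits(calib, "calibration_config"))
    stop("calib must be a calibration_config")
  if (mean_substitutions < 0) stop("mean_substitutions must be >= 0")
  rate <- mean_substitutions /
    (calib$n_callable_sites * calib$two_lineage_factor *
       calib$root_age_years)
  structure(list(rate = rate, mean_substitutions = mean_substitutions,
                 sd_substitutions = sd_substitutions,
                 n_callable_sites = calib$n_callable_sites,
                 root_age_years = calib$root_age_years,
                 two_lineage_factor = calib$two_lineage_factor),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %.3g substitutions/site/year\n  mean %.2f (s.d. %s) substitutions over %d sites, root age %.3g yr\n",
    signif(x$rate, 3), x$mean_substitutions,
    ifelse(is.na(x$sd_substitutions), "NA",
           sprintf("%.2f", x$sd_substitutions)),
    as.integer(x$n_callable_sites), x$root_age_years))
  invisible(x)
}
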