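#' Sex inference from autosome/X depth ratio
#'
#' Male samples are identified by an autosome-to-X sequencing depth ratio
#' above `ratio_min` together with adequate autosomal coverage (both strict
#' inequalities).
#'
#' @param autosomal_mean_depth,x_mean_depth mean sequencing depths (reads).
#' @param ratio_min minimum A/X depth ratio; default 1.85.
#' @param autosomal_min minimum autosomal coverage; default 10.
#' @return list with `include` (logical) and `ratio`.
#' @export
infer_male <- function(autosomal_mean_depth, x_mean_depth,
                       ratio_min = 1.85, autosomal_min = 10) {
  if (x_mean_depth <= 0) stop("X-chromosome depth must be positive")
  if (autosomal_mean_depth < 0) stop("depths must be non-negative")
  ratio <- autosomal_mean_depth / x_mean_depth
  list(include = ratio > ratio_min && autosomal_mean_depth > autosomal_min,
       ratio = ratio)
}

#' Method-of-moments IBD-sharing estimate (pi-hat) for two runs
#'
#' Estimates the proportion of sites identical by descent between two
#' haploid genotype vectors from identity-by-state counts. Per site, the
#' match probability is `pihat + (1-pihat)*(p^2+q^2)`; averaging over sites
#' and solving gives `pihat = (m - e)/(1 - e)` where `m` is the observed IBS
#' match rate and `e` the expected match rate for unrelated chromosomes
#' under the supplied allele frequencies. The estimate is clamped to
#' \[0, 1\]; identical inputs yield exactly 1.
#'
#' @param g_a,g_b haploid allele codes (0/1, `NA` missing) at the same sites.
#' @param freq optional per-site alternate-allele frequencies from the pooled
#'   run set; when `NULL` they are estimated from the pair itself (small
#'   samples bias the estimate toward 0 — supply pooled frequencies where
#'   available).
#' @param min_sites minimum overlapping non-missing sites; default 100.
#' @return pi-hat estimate in \[0, 1\].
#' @export
estimate_pihat <- function(g_a, g_b, freq = NULL, min_sites = 100) {
  if (length(g_a) != length(g_b)) stop("runs must cover the same sites")
  ok <- !is.na(g_a) & !is.na(g_b)
  if (!is.null(freq)) ok <- ok & !is.na(freq)
  if (sum(ok) < min_sites)
    stop("insufficient data: ", sum(ok), " overlapping sites < ", min_sites)
  a <- g_a[ok]; b <- g_b[ok]
  if (all(a == b)) return(1)
  p <- if (is.null(freq)) (a + b) / 2 else freq[ok]
  e <- mean(p^2 + (1 - p)^2)
  if (e >= 1) stop("insufficient data: no polymorphic sites")
  m <- mean(a == b)
  min(1, max(0, (m - e) / (1 - e)))
}

#' Pairwise pi-hat table for sequencing runs within samples
#'
#' Computes [estimate_pihat()] for every pair of runs belonging to the same
#' sample, with pooled allele frequencies estimated across all runs.
#'
#' @param run_geno runs x sites matrix of haploid codes (rownames = run IDs).
#' @param run_info data.frame with columns `run`, `sample`, `reads`.
#' @param freq optional per-site frequencies; default pooled across runs.
#' @param min_sites passed to [estimate_pihat()].
#' @return data.frame with `sample`, `run_a`, `run_b`, `reads_a`, `reads_b`,
#'   `pihat`.
#' @export
run_pihat_table <- function(run_geno, run_info, freq = NULL,
                            min_sites = 100) {
  if (is.null(freq)) freq <- colMeans(run_geno, na.rm = TRUE)
  out <- list()
  for (s in unique(run_info$sample)) {
    runs <- run_info$run[run_info$sample == s]
    if (length(runs) < 2) next
    prs <- utils::combn(runs, 2)
    for (k in seq_len(ncol(prs))) {
      ra <- prs[1, k]; rb <- prs[2, k]
      out[[length(out) + 1L]] <- data.frame(
        sample = s, run_a = ra, run_b = rb,
        reads_a = run_info$reads[run_info$run == ra],
        reads_b = run_info$reads[run_info$run == rb],
        pihat = estimate_pihat(run_geno[ra, ], run_geno[rb, ], freq,
                               min_sites),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), run_a = character(),
                      run_b = character(), reads_a = numeric(),
                      reads_b = numeric(), pihat = numeric()))
  do.call(rbind, out)
}

#' Screen samples for run-identity failures
#'
#' A sample is dropped when any pair of its sequencing runs (both with more
#' than `min_reads` reads) shows pi-hat below `threshold`, indicating that
#' runs from different biological samples may have been merged.
#'
#' @param pihat_table output of [run_pihat_table()].
#' @param threshold minimum within-sample pi-hat; default 0.90.
#' @param min_reads read-count guard (strict); default 100000.
#' @return character vector of sample IDs to drop.
#' @export
screen_runs <- function(pihat_table, threshold = 0.90, min_reads = 100000) {
  bad <- pihat_table$pihat < threshold &
    pihat_table$reads_a > min_reads & pihat_table$reads_b > min_reads
  sort(unique(pihat_table$sample[bad]))
}
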