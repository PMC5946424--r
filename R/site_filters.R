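#' Site-level filter for one candidate variant site
#'
#' Within callable regions a site is dropped if any sample call is a
#' maximum-likelihood heterozygote, if any sample call is missing, or if the
#' site's MQ0/raw-depth ratio exceeds `mq0_ratio_max` (strict inequality, so
#' a ratio of exactly 0.10 passes). The reason reports the first violated
#' rule in the fixed order het, missing, mq0.
#'
#' @param calls integer vector of per-sample codes (0 ref, 1 alt, 2 het,
#'   `NA` missing).
#' @param raw_depth,mq0 site-level raw depth and MQ0 read counts.
#' @param mq0_ratio_max maximum MQ0/raw-depth ratio; default 0.10.
#' @return list with `pass` (logical) and `reason` (`"het"`, `"missing"`,
#'   `"mq0"`, or `NA` when passing).
#' @export
filter_site <- function(calls, raw_depth, mq0, mq0_ratio_max = 0.10) {
  if (any(calls == 2L, na.rm = TRUE))
    return(list(pass = FALSE, reason = "het"))
  if (anyNA(calls))
    return(list(pass = FALSE, reason = "missing"))
  ratio <- if (raw_depth == 0) 0 else mq0 / raw_depth
  if (ratio > mq0_ratio_max)
    return(list(pass = FALSE, reason = "mq0"))
  list(pass = TRUE, reason = NA_character_)
}

#' Depth-outlier filter (median +/- k MAD)
#'
#' Removes sites with extreme sequencing depth. MAD is the unscaled median
#' absolute deviation `median(|x - median(x)|)` (no 1.4826 consistency
#' factor). Bounds are inclusive; when all depths are equal the bounds
#' collapse to the median and only sites at exactly the median pass.
#'
#' @param depths per-site depth summaries (e.g. the median across samples).
#' @param multiplier MAD multiplier, default 3.
#' @return list with `lower`, `upper` and logical `pass` per site.
#' @export
depth_mad_filter <- function(depths, multiplier = 3) {
  if (length(depths) == 0) stop("depths must be non-empty")
  med <- median(depths)
  mad0 <- median(abs(depths - med))
  lower <- med - multiplier * mad0
  upper <- med + multiplier * mad0
  list(lower = lower, upper = upper,
       pass = depths >= lower & depths <= upper)
}

#' Indel-proximity filter
#'
#' A site fails if it lies within `window` bp (inclusive) of the nearest
#' indel: distance 5 fails, distance 6 passes, with the default window.
#'
#' @param site_pos coordinates of candidate sites.
#' @param indel_positions sorted coordinates of called indels (may be empty).
#' @param window proximity window in bp, default 5.
#' @return logical vector, `TRUE` where the site passes.
#' @export
indel_proximity_filter <- function(site_pos, indel_positions, window = 5) {
  if (length(indel_positions) == 0) return(rep(TRUE, length(site_pos)))
  indel_positions <- sort(indel_positions)
  i <- findInterval(site_pos, indel_positions)
  d_left <- ifelse(i >= 1, site_pos - indel_positions[pmax(i, 1L)], Inf)
  d_right <- ifelse(i < length(indel_positions),
                    indel_positions[pmin(i + 1L, length(indel_positions))] -
                      site_pos, Inf)
  pmin(d_left, d_right) > window
}

#' Per-genotype quality filter for ancient samples
#'
#' Degraded ancient samples are restricted to calls with read depth >= 4,
#' genotype quality >= 30, mapping quality >= 15 and base quality >= 15
#' (all thresholds inclusive and configurable).
#'
#' @param depth,genotype_quality,map_quality,base_quality numeric vectors of
#'   per-call statistics.
#' @param min_depth,min_gq,min_mq,min_bq thresholds.
#' @return logical vector, `TRUE` where the call is callable.
#' @export
filter_ancient_call <- function(depth, genotype_quality, map_quality,
                                base_quality, min_depth = 4, min_gq = 30,
                                min_mq = 15, min_bq = 15) {
  depth >= min_depth & genotype_quality >= min_gq &
    map_quality >= min_mq & base_quality >= min_bq
}

#' Apply all site-level filters to a genotype matrix
#'
#' Combines the heterozygote/missingness screen, the MQ0/raw-depth ratio
#' filter (when site-level INFO statistics are available), the median +/- k
#' MAD depth-outlier filter (on per-site depth summaries across samples) and
#' the indel-proximity filter. Reasons are reported in the fixed order
#' het, missing, mq0, depth, indel; the surviving set is independent of
#' filter order.
#'
#' @param gm a [genotype_matrix()].
#' @param mq0_ratio_max maximum site MQ0/raw-depth ratio (strict).
#' @param mad_multiplier MAD multiplier for the depth-outlier filter.
#' @param indel_positions 0-based coordinates of called indels.
#' @param indel_window proximity window in bp.
#' @param depth_summary how to summarize per-call depths per site.
#' @return list with `matrix` (filtered [genotype_matrix()]), logical `pass`,
#'   character `reason` per input site, and the MAD `bounds`.
#' @export
apply_site_filters <- function(gm, mq0_ratio_max = 0.10, mad_multiplier = 3,
                               indel_positions = integer(),
                               indel_window = 5,
                               depth_summary = c("median", "mean")) {
  depth_summary <- match.arg(depth_summary)
  n_sites <- ncol(gm$geno)
  fail_het <- colSums(gm$geno == 2L, na.rm = TRUE) > 0
  fail_missing <- colSums(is.na(gm$geno)) > 0
  if (!is.null(gm$site_dp) && !is.null(gm$site_mq0)) {
    ratio <- ifelse(gm$site_dp == 0, 0, gm$site_mq0 / gm$site_dp)
    fail_mq0 <- ratio > mq0_ratio_max
  } else fail_mq0 <- rep(FALSE, n_sites)
  bounds <- NULL
  if (!is.null(gm$dp)) {
    f <- if (depth_summary == "median") median else mean
    site_depth <- apply(gm$dp, 2, f, na.rm = TRUE)
    mad_res <- depth_mad_filter(site_depth, mad_multiplier)
    fail_depth <- !mad_res$pass
    bounds <- c(lower = mad_res$lower, upper = mad_res$upper)
  } else fail_depth <- rep(FALSE, n_sites)
  fail_indel <- !indel_proximity_filter(gm$pos, indel_positions, indel_window)
  reason <- rep(NA_character_, n_sites)
  reason[fail_indel] <- "indel"
  reason[fail_depth] <- "depth"
  reason[fail_mq0] <- "mq0"
  reason[fail_missing] <- "missing"
  reason[fail_het] <- "het"
  pass <- is.na(reason)
  list(matrix = gm_subset_sites(gm, pass), pass = pass, reason = reason,
       bounds = bounds)
}

#' Mark sub-threshold ancient calls as missing
#'
#' Applies [filter_ancient_call()] to the per-call annotations of selected
#' samples and sets uncallable genotypes to `NA`.
#'
#' @param gm a [genotype_matrix()] carrying `dp`, `gq` (and optionally `mq`,
#'   `bq`) matrices.
#' @param samples sample IDs to screen.
#' @param min_depth,min_gq,min_mq,min_bq thresholds as in
#'   [filter_ancient_call()].
#' @return the genotype matrix with uncallable calls set to missing.
#' @export
mark_uncallable <- function(gm, samples, min_depth = 4, min_gq = 30,
                            min_mq = 15, min_bq = 15) {
  if (is.null(gm$dp) || is.null(gm$gq))
    stop("per-call dp and gq annotations are required")
  n_sites <- ncol(gm$geno)
  for (s in samples) {
    if (!s %in% rownames(gm$geno)) stop("unknown sample: ", s)
    ok <- filter_ancient_call(
      gm$dp[s, ], gm$gq[s, ],
      if (is.null(gm$mq)) rep(Inf, n_sites) else gm$mq[s, ],
      if (is.null(gm$bq)) rep(Inf, n_sites) else gm$bq[s, ],
      min_depth, min_gq, min_mq, min_bq)
    gm$geno[s, !ok] <- NA_integer_
  }
  gm
}
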