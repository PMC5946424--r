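#' Per-position depth/MQ0 track
#'
#' Holds raw read depth, filter-passing read depth and the count of mapping
#' quality zero (MQ0) reads for a contiguous stretch of reference positions.
#' High MQ0/depth ratios flag repetitive or amplicon sequence where short
#' reads cannot be uniquely placed.
#'
#' @param pos 0-based positions, contiguous and strictly increasing.
#' @param raw_depth,mq0 integer vectors; `mq0[i] <= raw_depth[i]`.
#' @param filtered_depth depth of filter-passing reads; defaults to
#'   `raw_depth - mq0`.
#' @return An object of class `position_track` (a data.frame).
#' @export
position_track <- function(pos, raw_depth, mq0,
                           filtered_depth = raw_depth - mq0) {
  pos <- as.integer(pos)
  n <- length(pos)
  if (n == 0) stop("track must be non-empty")
  if (length(raw_depth) != n || length(mq0) != n || length(filtered_depth) != n)
    stop("all track columns must have equal length")
  if (n > 1 && any(diff(pos) != 1L))
    stop("positions must be contiguous (strictly increasing by 1)")
  if (any(mq0 > raw_depth)) stop("mq0 cannot exceed raw_depth")
  if (any(raw_depth < 0) || any(mq0 < 0)) stop("depths must be non-negative")
  x <- data.frame(pos = pos, raw_depth = as.numeric(raw_depth),
                  filtered_depth = as.numeric(filtered_depth),
                  mq0 = as.numeric(mq0))
  class(x) <- c("position_track", "data.frame")
  x
}

#' Exponentially weighted moving average
#'
#' `s[1] = x[1]`, `s[t] = alpha*x[t] + (1-alpha)*s[t-1]`. Used to smooth
#' per-position depth and MQ0-ratio series along the chromosome before
#' thresholding.
#'
#' @param x numeric series, non-empty.
#' @param alpha smoothing weight in (0, 1]; `alpha = 1` returns `x` unchanged.
#'   The default smoothing window used downstream corresponds to
#'   `alpha = 2/(w + 1)` for an effective window of `w` positions.
#' @return numeric vector of the same length as `x`.
#' @export
compute_ewma <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("alpha must be a single number in (0, 1]")
  if (length(x) == 0) stop("series must be non-empty")
  if (alpha == 1) return(as.numeric(x))
  as.numeric(stats::filter(alpha * x, 1 - alpha,
                           method = "recursive", init = x[1]))
}

#' MQ0/raw-depth ratio
#'
#' Proportion of reads with mapping quality zero per position, defined as 0
#' where raw depth is 0 (such positions fail the depth filter regardless).
#'
#' @param track a [position_track()].
#' @return numeric vector in \[0, 1\].
#' @export
mq0_ratio <- function(track) {
  r <- ifelse(track$raw_depth == 0, 0, track$mq0 / track$raw_depth)
  as.numeric(r)
}

#' Thresholds for the regional callability mask
#'
#' @param depth_min,depth_max bounds on EWMA-smoothed filtered depth (reads).
#'   When `NULL` they default, at mask-building time, to 0.33x and 2.0x the
#'   median filtered depth of the track.
#' @param mq0_ratio_max maximum smoothed MQ0/raw-depth ratio; default 0.10,
#'   matching the site-level MQ0 ratio filter.
#' @param ewma_alpha smoothing weight; default `2/(1000+1)`, an effective
#'   window of about 1 kb.
#' @param min_region_len minimum length (bp) for a pass region; shorter pass
#'   runs are demoted to fail. Default 1 (no demotion).
#' @return a list of class `mask_thresholds`.
#' @export
mask_thresholds <- function(depth_min = NULL, depth_max = NULL,
                            mq0_ratio_max = 0.10,
                            ewma_alpha = 2 / 1001, min_region_len = 1L) {
  if (!is.null(depth_min) && !is.null(depth_max) && depth_min >= depth_max)
    stop("depth_min must be < depth_max")
  if (mq0_ratio_max <= 0 || mq0_ratio_max >= 1)
    stop("mq0_ratio_max must be in (0, 1)")
  if (ewma_alpha <= 0 || ewma_alpha > 1) stop("ewma_alpha must be in (0, 1]")
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 mq0_ratio_max = mq0_ratio_max, ewma_alpha = ewma_alpha,
                 min_region_len = as.integer(min_region_len)),
            class = "mask_thresholds")
}

merge_runs <- function(df) {
  if (nrow(df) <= 1) return(df)
  keep <- c(TRUE, df$status[-1] != df$status[-nrow(df)] |
              df$reason[-1] != df$reason[-nrow(df)])
  grp <- cumsum(keep)
  out <- df[keep, , drop = FALSE]
  out$end <- as.vector(tapply(df$end, grp, max))
  rownames(out) <- NULL
  out
}

#' Build the regional callability mask
#'
#' A position passes iff the EWMA-smoothed filtered depth lies within
#' `[depth_min, depth_max]`, the EWMA-smoothed MQ0/raw-depth ratio is at most
#' `mq0_ratio_max`, and the position is not in an excluded interval. Runs of
#' equal status/reason are merged into 0-based half-open intervals that
#' exactly tile the analyzed range. Pass runs shorter than `min_region_len`
#' are demoted to fail with the nearest violated filter as reason.
#'
#' @param track a [position_track()].
#' @param thr a [mask_thresholds()].
#' @param excluded optional data.frame with `start`, `end` columns (0-based,
#'   half-open) of intervals excluded from analysis a priori.
#' @return A `region_mask`: data.frame with columns `start`, `end`, `status`
#'   (`pass`/`fail`) and `reason` (`none`, `depth`, `mq0_ratio`, `excluded`),
#'   with an attribute `range = c(first, last+1)`.
#' @export
build_region_mask <- function(track, thr = mask_thresholds(),
                              excluded = NULL) {
  if (!inherits(track, "position_track")) track <- as_position_track(track)
  n <- nrow(track)
  depth_min <- thr$depth_min %||% (0.33 * median(track$filtered_depth))
  depth_max <- thr$depth_max %||% (2.0 * median(track$filtered_depth))
  if (depth_min >= depth_max) stop("depth_min must be < depth_max")
  fd <- compute_ewma(track$filtered_depth, thr$ewma_alpha)
  rr <- compute_ewma(mq0_ratio(track), thr$ewma_alpha)
  ok_depth <- fd >= depth_min & fd <= depth_max
  ok_mq0 <- rr <= thr$mq0_ratio_max
  excl <- rep(FALSE, n)
  if (!is.null(excluded) && nrow(excluded) > 0) {
    for (i in seq_len(nrow(excluded)))
      excl <- excl | (track$pos >= excluded$start[i] &
                        track$pos < excluded$end[i])
  }
  pass <- ok_depth & ok_mq0 & !excl
  reason <- ifelse(pass, "none",
                   ifelse(excl, "excluded",
                          ifelse(!ok_depth, "depth", "mq0_ratio")))
  key <- paste(pass, reason)
  r <- rle(key)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  df <- data.frame(start = track$pos[idx_start],
                   end = track$pos[idx_end] + 1L,
                   status = ifelse(pass[idx_start], "pass", "fail"),
                   reason = reason[idx_start], stringsAsFactors = FALSE)
  if (thr$min_region_len > 1L) {
    for (i in seq_len(nrow(df))) {
      if (df$status[i] == "pass" &&
          (df$end[i] - df$start[i]) < thr$min_region_len) {
        nb <- character(0)
        if (i > 1) nb <- c(nb, df$reason[i - 1])
        if (i < nrow(df)) nb <- c(nb, df$reason[i + 1])
        df$status[i] <- "fail"
        df$reason[i] <- if ("depth" %in% nb) "depth" else "mq0_ratio"
      }
    }
    df <- merge_runs(df)
  }
  attr(df, "range") <- c(track$pos[1], track$pos[n] + 1L)
  class(df) <- c("region_mask", "data.frame")
  df
}

as_position_track <- function(x) {
  position_track(x$pos, x$raw_depth, x$mq0,
                 x$filtered_depth %||% (x$raw_depth - x$mq0))
}

#' Per-position status of a region mask
#'
#' @param mask a `region_mask` from [build_region_mask()].
#' @return logical vector over the analyzed range, `TRUE` where status is
#'   `pass`.
#' @export
mask_status_by_position <- function(mask) {
  rep(mask$status == "pass", times = mask$end - mask$start)
}

#' Position-level concordance of two region masks
#'
#' Proportion of positions at which two masks over the same range agree on
#' pass/fail status (1 means identical masks).
#'
#' @param mask_a,mask_b `region_mask` objects covering the same range.
#' @return proportion in \[0, 1\].
#' @export
mask_concordance <- function(mask_a, mask_b) {
  if (!identical(attr(mask_a, "range"), attr(mask_b, "range")))
    stop("masks must cover the same range")
  mean(mask_status_by_position(mask_a) == mask_status_by_position(mask_b))
}

#' Jaccard overlap of two interval sets
#'
#' Positions covered by both interval sets divided by positions covered by
#' either; intervals are 0-based half-open `start`/`end` data.frames.
#'
#' @param a,b data.frames with `start` and `end` columns.
#' @return Jaccard index in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  lo <- min(c(a$start, b$start))
  hi <- max(c(a$end, b$end))
  cov <- function(df) {
    v <- logical(hi - lo)
    for (i in seq_len(nrow(df)))
      v[seq(df$start[i] - lo + 1L, df$end[i] - lo)] <- TRUE
    v
  }
  va <- cov(a); vb <- cov(b)
  sum(va & vb) / sum(va | vb)
}
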