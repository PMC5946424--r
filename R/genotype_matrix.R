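#' Haploid genotype matrix
#'
#' Container for a samples x sites matrix of haploid allele codes with
#' optional per-call and per-site annotations. Codes: `0` ancestral/reference,
#' `1` alternate, `2` heterozygous (from a diploid-emitting caller), `NA`
#' missing.
#'
#' @param geno integer matrix, samples in rows (rownames = sample IDs),
#'   sites in columns.
#' @param pos integer vector of 0-based site coordinates, strictly increasing.
#' @param ref,alt character vectors of reference/alternate alleles per site.
#' @param id optional character site identifiers.
#' @param chrom contig name used when writing VCF.
#' @param dp,gq,mq,bq optional numeric matrices (same shape as `geno`) of
#'   per-call read depth, genotype quality, mapping quality and base quality.
#' @param site_dp,site_mq0 optional per-site raw depth and MQ0 read counts
#'   (VCF INFO-level statistics).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, pos, ref, alt, id = NULL, chrom = "Y",
                            dp = NULL, gq = NULL, mq = NULL, bq = NULL,
                            site_dp = NULL, site_mq0 = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) stop("geno must have sample IDs as rownames")
  pos <- as.integer(pos)
  n_sites <- ncol(geno)
  if (length(pos) != n_sites) stop("pos length must equal ncol(geno)")
  if (n_sites > 1 && any(diff(pos) <= 0)) stop("pos must be strictly increasing")
  if (length(ref) != n_sites || length(alt) != n_sites)
    stop("ref/alt must have one allele per site")
  if (is.null(id)) id <- sprintf("v%06d", pos + 1L)
  colnames(geno) <- id
  for (m in list(dp, gq, mq, bq))
    if (!is.null(m) && !identical(dim(m), dim(geno)))
      stop("per-call annotation matrices must match dim(geno)")
  x <- list(geno = geno, pos = pos, id = as.character(id),
            ref = as.character(ref), alt = as.character(alt), chrom = chrom,
            dp = dp, gq = gq, mq = mq, bq = bq,
            site_dp = site_dp, site_mq0 = site_mq0)
  class(x) <- "genotype_matrix"
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites (%s)\n",
              nrow(x$geno), ncol(x$geno), x$chrom))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.1f%%; annotations: %s\n", 100 * miss,
              paste(c("dp", "gq", "mq", "bq")[!vapply(
                list(x$dp, x$gq, x$mq, x$bq), is.null, logical(1))],
                collapse = ",")))
  invisible(x)
}

#' Sample identifiers of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return character vector of sample IDs.
#' @export
gm_samples <- function(gm) rownames(gm$geno)

#' Subset a genotype matrix by sample
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample IDs to keep.
#' @return a `genotype_matrix` restricted to the selected samples.
#' @export
gm_subset_samples <- function(gm, samples) {
  miss <- setdiff(samples, rownames(gm$geno))
  if (length(miss) > 0)
    stop("unknown sample: ", paste(miss, collapse = ","))
  sub <- function(m) if (is.null(m)) NULL else m[samples, , drop = FALSE]
  genotype_matrix(gm$geno[samples, , drop = FALSE], gm$pos, gm$ref, gm$alt,
                  id = gm$id, chrom = gm$chrom, dp = sub(gm$dp),
                  gq = sub(gm$gq), mq = sub(gm$mq), bq = sub(gm$bq),
                  site_dp = gm$site_dp, site_mq0 = gm$site_mq0)
}

#' Subset a genotype matrix by site
#'
#' @param gm a [genotype_matrix()].
#' @param keep logical or integer index over sites.
#' @return a `genotype_matrix` restricted to the selected sites.
#' @export
gm_subset_sites <- function(gm, keep) {
  sub <- function(m) if (is.null(m)) NULL else m[, keep, drop = FALSE]
  genotype_matrix(gm$geno[, keep, drop = FALSE], gm$pos[keep],
                  gm$ref[keep], gm$alt[keep], id = gm$id[keep],
                  chrom = gm$chrom, dp = sub(gm$dp), gq = sub(gm$gq),
                  mq = sub(gm$mq), bq = sub(gm$bq),
                  site_dp = gm$site_dp[keep], site_mq0 = gm$site_mq0[keep])
}
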