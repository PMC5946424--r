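#' Read a haploid genotype matrix from VCF
#'
#' Parses biallelic SNV records with vcfR. Genotypes are recoded to haploid
#' integers: hom-ref (`0`, `0/0`) to 0, hom-alt to 1, diploid hets to the
#' het flag 2, `.`/`./.` to missing. Multi-allelic records are skipped with
#' a warning. Positions are converted to 0-based coordinates; per-call DP
#' and GQ and site-level INFO `DP`/`MQ0` are carried along when present.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1] %||% character(0)
    geno <- matrix(integer(0), nrow = length(samples), ncol = 0,
                   dimnames = list(samples, NULL))
    return(genotype_matrix(geno, integer(0), character(0), character(0),
                           chrom = "Y"))
  }
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  code[gt %in% c("0", "0/0", "0|0")] <- 0L
  code[gt %in% c("1", "1/1", "1|1")] <- 1L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 2L
  grab_fmt <- function(el) {
    m <- tryCatch(
      suppressWarnings(vcfR::extract.gt(v, element = el,
                                        as.numeric = TRUE)),
      error = function(e) NULL)
    if (is.null(m) || all(is.na(m))) NULL else t(m)
  }
  grab_info <- function(el) {
    x <- tryCatch(
      suppressWarnings(vcfR::extract.info(v, element = el,
                                          as.numeric = TRUE)),
      error = function(e) NULL)
    if (is.null(x) || all(is.na(x))) NULL else x
  }
  genotype_matrix(t(code), as.integer(fix$POS) - 1L, fix$REF, fix$ALT,
                  id = ifelse(is.na(fix$ID) | fix$ID == ".",
                              sprintf("v%06d", as.integer(fix$POS)),
                              fix$ID),
                  chrom = fix$CHROM[1],
                  dp = grab_fmt("DP"), gq = grab_fmt("GQ"),
                  site_dp = grab_info("DP"), site_mq0 = grab_info("MQ0"))
}

#' Write a haploid genotype matrix as plain-text VCF 4.2
#'
#' Haploid calls are written as `0`/`1`, the het flag as `0/1`, missing as
#' `.`; per-call DP/GQ and site-level INFO `DP`/`MQ0` are emitted when
#' present.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  samples <- gm_samples(gm)
  has_fmt <- !is.null(gm$dp) && !is.null(gm$gq)
  has_info <- !is.null(gm$site_dp) && !is.null(gm$site_mq0)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", gm$chrom),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
           "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Reads with mapping quality zero\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix(".", nrow = length(samples), ncol = ncol(gm$geno))
  gt_str[gm$geno == 0L] <- "0"
  gt_str[gm$geno == 1L] <- "1"
  gt_str[gm$geno == 2L] <- "0/1"
  lines <- vapply(seq_len(ncol(gm$geno)), function(j) {
    info <- if (has_info)
      sprintf("DP=%d;MQ0=%d", gm$site_dp[j], gm$site_mq0[j]) else "."
    cells <- if (has_fmt)
      sprintf("%s:%d:%d", gt_str[, j], gm$dp[, j], gm$gq[, j])
    else gt_str[, j]
    paste(c(gm$chrom, gm$pos[j] + 1L, gm$id[j], gm$ref[j], gm$alt[j],
            ".", ".", info, if (has_fmt) "GT:DP:GQ" else "GT", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a rooted tree from a newick file
#'
#' @param path newick file; leaf labels must be unique.
#' @return an `ape::phylo` tree.
#' @export
read_tree_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ","))
  tree
}

#' Write a tree as newick
#' @param tree an `ape::phylo` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a per-position track from 3-column TSV
#'
#' Columns `pos` (0-based), `depth` (raw), `mq0`; filtered depth is taken
#' as `depth - mq0`.
#'
#' @param path TSV file with a header line.
#' @return a [position_track()].
#' @export
read_track_tsv <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  d <- read.table(path, header = TRUE, sep = "\t")
  position_track(d$pos, d$depth, d$mq0)
}

#' Write a per-position track as 3-column TSV
#' @param track a [position_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  write.table(data.frame(pos = track$pos, depth = track$raw_depth,
                         mq0 = track$mq0),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of 0-based half-open intervals
#'
#' @param path BED file (3 or more tab-separated columns, no header).
#' @return data.frame with `chrom`, `start`, `end` and `name` when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  d <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  d
}

#' Write intervals as BED
#'
#' @param df data.frame with `start`, `end` and optionally `name` columns.
#' @param path output file.
#' @param chrom contig name for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, chrom = "Y") {
  out <- data.frame(chrom = chrom, start = df$start, end = df$end)
  if (!is.null(df$name)) out$name <- df$name
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a region mask as BED with the fail reason as name
#'
#' @param mask a `region_mask` from [build_region_mask()].
#' @param path output file.
#' @param chrom contig name.
#' @return `path`, invisibly.
#' @export
write_region_mask_bed <- function(mask, path, chrom = "Y") {
  df <- data.frame(start = mask$start, end = mask$end,
                   name = ifelse(mask$status == "pass", "pass",
                                 mask$reason))
  write_bed(df, path, chrom = chrom)
}

#' Write the files for a simulated cohort
#'
#' Emits `genotypes.vcf`, `tree.nwk`, `track.tsv`, `amplicons.bed`,
#' `truth_sites.tsv`, `truth_samples.tsv` and `haplogroups.yaml` under
#' `dir`.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_vcf(sim$matrix, file.path(dir, "genotypes.vcf"))
  write_tree_newick(sim$tree, file.path(dir, "tree.nwk"))
  write_track_tsv(sim$track, file.path(dir, "track.tsv"))
  amp <- do.call(rbind, lapply(sim$truth$amplicon_regions, function(a)
    data.frame(start = a[1], end = a[2], name = paste0("cn", a[3]))))
  if (is.null(amp)) amp <- data.frame(start = integer(), end = integer())
  write_bed(amp, file.path(dir, "amplicons.bed"), chrom = sim$matrix$chrom)
  write.table(sim$truth$variant_branch_map,
              file.path(dir, "truth_sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hg <- sim$truth$haplogroup_of_sample
  write.table(data.frame(sample = names(hg), haplogroup = unname(hg)),
              file.path(dir, "truth_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(lapply(sim$truth$haplogroup_nodes, as.list),
                   file.path(dir, "haplogroups.yaml"))
  invisible(dir)
}
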