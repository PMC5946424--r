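#' Run the full haplogroup-analysis pipeline
#'
#' Executes the stages in order — callability mask, site filtering, branch
#' assignment, panel extraction, haplogroup calling, naive rate — on files
#' referenced by a configuration list (or YAML file), writing `mask.bed`,
#' `filtered.vcf`, `assignments.tsv`, `branch_counts.tsv`, `panel.tsv`,
#' `calls.tsv`, `frequency.tsv`, `rate.json` and `run.log` to the output
#' directory. Identical configuration and inputs produce byte-identical
#' outputs.
#'
#' Recognized configuration fields: `vcf`, `tree`, `outgroup` (required);
#' `qc_depths` (TSV with `sample`, `autosomal_depth`, `x_depth` columns for
#' the male-inclusion screen), `track`, `excluded_bed`, `indels_bed`,
#' `haplogroups` (named list of
#' clade leaf vectors; default: child clades of the ingroup ancestor),
#' `ancient_samples`, `mask` / `site` / `ancient` / `call` threshold blocks,
#' `root_age_years` (default 1.5e6), `n_callable_sites` (default: mask pass
#' positions, else the filtered site count), `out_dir`.
#'
#' @param config a named list or path to a YAML file.
#' @return invisibly, a list with the stage objects (`mask`, `matrix`,
#'   `assignments`, `counts`, `panel`, `cohort`, `rate`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (f in c("vcf", "tree", "outgroup"))
    if (is.null(config[[f]])) stop("configuration error: missing field ", f)
  for (f in c("vcf", "tree", "track", "excluded_bed", "indels_bed"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("configuration error: ", f, " file not found: ", config[[f]])
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    log_lines <<- c(log_lines, line)
    line
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  for (f in c("vcf", "tree", "track"))
    if (!is.null(config[[f]]))
      note("input", f, " ", config[[f]], " md5=",
           unname(tools::md5sum(config[[f]])))

  mask <- NULL
  n_callable <- config$n_callable_sites
  if (!is.null(config$track)) {
    mask <- stage("mask", {
      track <- read_track_tsv(config$track)
      thr <- do.call(mask_thresholds, config$mask %||% list())
      excl <- if (!is.null(config$excluded_bed))
        read_bed(config$excluded_bed) else NULL
      build_region_mask(track, thr, excluded = excl)
    })
    write_region_mask_bed(mask, file.path(out_dir, "mask.bed"))
    n_pass <- sum((mask$end - mask$start)[mask$status == "pass"])
    if (is.null(n_callable)) n_callable <- n_pass
    note("mask", "pass_positions=", n_pass, " intervals=", nrow(mask))
  }

  gm <- stage("read", read_genotype_vcf(config$vcf))
  tree <- stage("read", read_tree_newick(config$tree))
  outgroup <- config$outgroup

  if (!is.null(config$qc_depths)) {
    gm <- stage("qc", {
      qd <- read.table(config$qc_depths, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      keep <- vapply(seq_len(nrow(qd)), function(i)
        infer_male(qd$autosomal_depth[i], qd$x_depth[i])$include,
        logical(1))
      included <- union(qd$sample[keep], outgroup)
      note("qc", "included=", sum(keep), "/", nrow(qd))
      gm_subset_samples(gm, intersect(gm_samples(gm), included))
    })
  }
  if (!outgroup %in% gm_samples(gm))
    stop("[stage read] outgroup not in VCF: ", outgroup)
  if (!outgroup %in% tree$tip.label)
    stop("[stage read] outgroup not in tree: ", outgroup)

  if (!is.null(mask)) {
    pass_pos <- logical(attr(mask, "range")[2])
    for (i in which(mask$status == "pass"))
      pass_pos[seq(mask$start[i] + 1L, mask$end[i])] <- TRUE
    keep <- gm$pos < length(pass_pos) & pass_pos[gm$pos + 1L]
    gm <- gm_subset_sites(gm, keep)
    note("mask", "sites_in_pass_regions=", ncol(gm$geno))
  }

  if (!is.null(config$ancient_samples) && !is.null(gm$dp)) {
    anc <- do.call(mark_uncallable, c(
      list(gm = gm, samples = config$ancient_samples),
      config$ancient %||% list()))
    gm <- anc
    note("ancient", "screened=",
         paste(config$ancient_samples, collapse = ","))
  }

  filt <- stage("filter", {
    indels <- if (!is.null(config$indels_bed))
      read_bed(config$indels_bed)$start else integer()
    # ancient samples are screened per-genotype above, not at site level:
    # their dropout must not remove sites from the modern cohort
    modern <- setdiff(gm_samples(gm), config$ancient_samples)
    do.call(apply_site_filters, c(
      list(gm = gm_subset_samples(gm, modern), indel_positions = indels),
      config$site %||% list()))
  })
  gm <- gm_subset_sites(gm, filt$pass)
  write_genotype_vcf(gm, file.path(out_dir, "filtered.vcf"))
  note("filter", "pass=", sum(filt$pass), " fail=", sum(!filt$pass))
  if (is.null(n_callable)) n_callable <- ncol(gm$geno)

  asn <- stage("assign", {
    variants <- polarize(gm, outgroup)
    assign_branches(variants, tree, outgroup,
                    absent = setdiff(tree$tip.label, gm_samples(gm)))
  })
  write.table(asn, file.path(out_dir, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- count_diagnostics(asn)
  ctab <- rbind(counts$branch_counts,
                data.frame(node = "Incompatible",
                           count = counts$n_incompatible))
  write.table(ctab, file.path(out_dir, "branch_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("assign", "diagnostic=", sum(asn$status == "diagnostic"),
       " incompatible=", counts$n_incompatible,
       " uninformative=", counts$n_uninformative)

  hg_nodes <- stage("panel", {
    h <- config$haplogroups
    if (is.null(h)) h <- default_haplogroup_nodes(tree, outgroup)
    lapply(h, unlist)
  })
  panel <- extract_panel(asn, hg_nodes)
  write.table(panel, file.path(out_dir, "panel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("panel", "labels=", length(unique(panel$haplogroup)),
       " sites=", nrow(panel))

  cohort <- stage("call", do.call(assign_cohort, c(
    list(gm = gm, panel = panel, exclude = outgroup),
    config$call %||% list())))
  write.table(cohort$calls, file.path(out_dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(cohort$frequency),
              file.path(out_dir, "frequency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("call", "assigned=", sum(!is.na(cohort$calls$label)), "/",
       nrow(cohort$calls))

  rate <- stage("rate", {
    ingroup <- setdiff(gm_samples(gm), outgroup)
    subs <- cohort_substitution_summary(gm, ingroup, outgroup)
    naive_rate(subs$mean,
               calibration_config(n_callable,
                                  config$root_age_years %||% 1.5e6),
               sd_substitutions = subs$sd)
  })
  jsonlite::write_json(unclass(rate), file.path(out_dir, "rate.json"),
                       auto_unbox = TRUE, digits = NA)
  note("rate", "rate=", signif(rate$rate, 3),
       " mean_substitutions=", rate$mean_substitutions)

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(mask = mask, matrix = gm, assignments = asn,
                 counts = counts, panel = panel, cohort = cohort,
                 rate = rate, out_dir = out_dir))
}

#' Default haplogroup labels from the ingroup ancestor's child clades
#'
#' Labels the child clades of the ingroup most recent common ancestor
#' `HG1..HGk` in decreasing size order — a fallback when no haplogroup
#' definition is supplied.
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup outgroup tip label.
#' @return named list of tip-label vectors.
#' @export
default_haplogroup_nodes <- function(tree, outgroup) {
  ingroup <- setdiff(tree$tip.label, outgroup)
  mrca <- if (length(ingroup) == 1) match(ingroup, tree$tip.label) else
    ape::getMRCA(tree, ingroup)
  sets <- node_leafsets(tree)
  kids <- tree$edge[tree$edge[, 1] == mrca, 2]
  clades <- lapply(kids, function(k) setdiff(sets[[k]], outgroup))
  clades <- clades[lengths(clades) > 0]
  clades <- clades[order(-lengths(clades))]
  setNames(clades, paste0("HG", seq_along(clades)))
}
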