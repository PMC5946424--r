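#' Descendant leaf sets for every node of a rooted tree
#'
#' @param tree an `ape::phylo` object.
#' @return list indexed by node number (tips first, then internal nodes),
#'   each element the sorted tip labels descending from that node.
#' @export
node_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  sets[seq_len(ntip)] <- as.list(tree$tip.label)
  edge <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(edge)))
    sets[[edge[i, 1]]] <- c(sets[[edge[i, 1]]], sets[[edge[i, 2]]])
  lapply(sets, sort)
}

clade_label <- function(leaves) paste(sort(leaves), collapse = ",")

#' Polarize variants against an outgroup
#'
#' At each site with a non-missing outgroup call, the derived allele is the
#' allele differing from the outgroup state; carriers are the non-outgroup
#' samples holding it. Sites where the outgroup is missing are skipped
#' (uninformative) by default, or polarized by the minor allele with
#' `missing_fallback = "minor"` (ties resolve to uninformative).
#' Heterozygous calls are treated as missing.
#'
#' @param gm a [genotype_matrix()].
#' @param outgroup sample ID of the outgroup.
#' @param missing_fallback `"skip"` or `"minor"`.
#' @return list of class `polarized_variants`; each element has `site`,
#'   `pos`, `ancestral`, `derived`, `carriers`, `missing`, `uninformative`.
#' @export
polarize <- function(gm, outgroup, missing_fallback = c("skip", "minor")) {
  missing_fallback <- match.arg(missing_fallback)
  samples <- gm_samples(gm)
  if (!outgroup %in% samples) stop("outgroup not in matrix: ", outgroup)
  ingroup <- setdiff(samples, outgroup)
  out <- vector("list", ncol(gm$geno))
  for (j in seq_len(ncol(gm$geno))) {
    g <- gm$geno[ingroup, j]
    names(g) <- ingroup
    og <- gm$geno[outgroup, j]
    miss <- ingroup[is.na(g) | g == 2L]
    rec <- list(site = gm$id[j], pos = gm$pos[j],
                ancestral = NA_character_, derived = NA_character_,
                carriers = character(0), missing = miss,
                uninformative = TRUE)
    derived_code <- NA_integer_
    if (!is.na(og) && og %in% c(0L, 1L)) {
      derived_code <- 1L - og
    } else if (missing_fallback == "minor") {
      cnt <- c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE))
      if (cnt[1] != cnt[2] && sum(cnt) > 0)
        derived_code <- if (cnt[2] < cnt[1]) 1L else 0L
    }
    if (!is.na(derived_code)) {
      carriers <- ingroup[!is.na(g) & g == derived_code]
      rec$ancestral <- if (derived_code == 1L) gm$ref[j] else gm$alt[j]
      rec$derived <- if (derived_code == 1L) gm$alt[j] else gm$ref[j]
      rec$carriers <- carriers
      rec$uninformative <- length(carriers) == 0
    }
    out[[j]] <- rec
  }
  class(out) <- "polarized_variants"
  out
}

#' Assign one variant to the deepest node of genotype universality
#'
#' Starting from each carrier leaf, ancestry is followed rootward while every
#' non-missing, non-outgroup leaf under the candidate node is itself a
#' carrier, yielding the maximal carrier-pure ("top") nodes. A single top
#' node makes the variant diagnostic for that branch; two or more top nodes
#' mark it potentially recurrent and incompatible with the tree; an empty
#' carrier set is uninformative. Outgroup leaves are excluded from the
#' universality test, so a variant carried by every ingroup sample is
#' diagnostic for the ingroup stem.
#'
#' @param carriers tip labels carrying the derived allele.
#' @param tree an `ape::phylo` rooted tree.
#' @param outgroup tip label(s) excluded from the universality test.
#' @param missing tip labels with no call at this site; excluded from the
#'   test so low-coverage samples cannot break otherwise clean diagnostics.
#' @return list with `status` (`diagnostic`/`incompatible`/`uninformative`),
#'   `node` (sorted-leaf label of the assigned branch, or `NA`) and
#'   `top_nodes` (labels of the maximal carrier-pure nodes).
#' @export
assign_branch <- function(carriers, tree, outgroup = NULL,
                          missing = character()) {
  tips <- tree$tip.label
  if (length(setdiff(carriers, tips)) > 0)
    stop("carrier not in tree: ",
         paste(setdiff(carriers, tips), collapse = ","))
  eligible <- setdiff(tips, outgroup)
  informative <- setdiff(eligible, missing)
  car <- intersect(carriers, informative)
  if (length(car) == 0)
    return(list(status = "uninformative", node = NA_character_,
                top_nodes = character(0)))
  sets <- node_leafsets(tree)
  pure <- vapply(sets, function(s) {
    inf <- s[s %in% informative]
    length(inf) > 0 && all(inf %in% car)
  }, logical(1))
  ntip <- length(tips)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tops <- integer(0)
  for (tip in match(car, tips)) {
    cur <- tip
    while (parent[cur] != 0L && pure[parent[cur]]) cur <- parent[cur]
    tops <- c(tops, cur)
  }
  tops <- sort(unique(tops))
  labels <- vapply(tops, function(i)
    clade_label(intersect(sets[[i]], eligible)), character(1))
  if (length(tops) == 1L)
    list(status = "diagnostic", node = labels, top_nodes = labels)
  else
    list(status = "incompatible", node = NA_character_,
         top_nodes = sort(labels))
}

#' Assign every polarized variant to a branch
#'
#' @param variants a `polarized_variants` object from [polarize()].
#' @param tree an `ape::phylo` rooted tree whose tips are the sample IDs.
#' @param outgroup outgroup tip label(s).
#' @param absent tip labels with no genotype data at all (e.g. samples
#'   dropped by QC); treated as missing at every site.
#' @return data.frame with `site`, `pos`, `status`, `node`, `ancestral`,
#'   `derived`; attribute `top_nodes` holds the per-site label lists.
#' @export
assign_branches <- function(variants, tree, outgroup = NULL,
                            absent = character()) {
  res <- lapply(variants, function(v) {
    if (v$uninformative)
      list(status = "uninformative", node = NA_character_,
           top_nodes = character(0))
    else assign_branch(v$carriers, tree, outgroup,
                       union(v$missing, absent))
  })
  df <- data.frame(
    site = vapply(variants, `[[`, character(1), "site"),
    pos = vapply(variants, `[[`, integer(1), "pos"),
    status = vapply(res, `[[`, character(1), "status"),
    node = vapply(res, `[[`, character(1), "node"),
    ancestral = vapply(variants, `[[`, character(1), "ancestral"),
    derived = vapply(variants, `[[`, character(1), "derived"),
    stringsAsFactors = FALSE)
  attr(df, "top_nodes") <- lapply(res, `[[`, "top_nodes")
  df
}

#' Tabulate diagnostic mutations per branch
#'
#' @param assignments output of [assign_branches()].
#' @return list with `branch_counts` (data.frame `node`, `count`, sorted by
#'   decreasing count), `n_incompatible`, `n_uninformative`, `n_total`.
#'   Branch counts plus incompatible sites partition all informative
#'   variants.
#' @export
count_diagnostics <- function(assignments) {
  diag <- assignments[assignments$status == "diagnostic", , drop = FALSE]
  if (nrow(diag) > 0) {
    tab <- table(diag$node)
    bc <- data.frame(node = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    bc <- bc[order(-bc$count, bc$node), , drop = FALSE]
    rownames(bc) <- NULL
  } else {
    bc <- data.frame(node = character(), count = integer())
  }
  list(branch_counts = bc,
       n_incompatible = sum(assignments$status == "incompatible"),
       n_uninformative = sum(assignments$status == "uninformative"),
       n_total = nrow(assignments))
}

#' Extract a haplogroup diagnostic-site panel
#'
#' Collects, for each labeled haplogroup node, the sites diagnostic to
#' exactly that branch together with their ancestral/derived alleles. Sites
#' diagnostic for an ancestral label are never listed under a nested child
#' label. The label hierarchy (child -> parent by leaf-set nesting) is
#' attached as attribute `hierarchy`.
#'
#' @param assignments output of [assign_branches()].
#' @param haplogroup_nodes named list mapping haplogroup labels to the tip
#'   labels of their clades.
#' @return data.frame of class `diagnostic_panel` with columns `haplogroup`,
#'   `pos`, `ancestral`, `derived`.
#' @export
extract_panel <- function(assignments, haplogroup_nodes) {
  if (length(haplogroup_nodes) == 0) stop("haplogroup_nodes must be named")
  node_of <- vapply(haplogroup_nodes, clade_label, character(1))
  if (anyDuplicated(node_of)) stop("haplogroup labels map to duplicate clades")
  rows <- list()
  for (lab in names(haplogroup_nodes)) {
    hit <- assignments$status == "diagnostic" &
      assignments$node == node_of[[lab]]
    if (any(hit))
      rows[[lab]] <- data.frame(
        haplogroup = lab, pos = assignments$pos[hit],
        ancestral = assignments$ancestral[hit],
        derived = assignments$derived[hit], stringsAsFactors = FALSE)
  }
  panel <- if (length(rows)) do.call(rbind, rows) else
    data.frame(haplogroup = character(), pos = integer(),
               ancestral = character(), derived = character())
  rownames(panel) <- NULL
  hier <- setNames(rep(NA_character_, length(haplogroup_nodes)),
                   names(haplogroup_nodes))
  for (a in names(haplogroup_nodes)) {
    supers <- names(haplogroup_nodes)[vapply(haplogroup_nodes, function(s)
      all(haplogroup_nodes[[a]] %in% s) &&
        length(s) > length(haplogroup_nodes[[a]]), logical(1))]
    if (length(supers) > 0)
      hier[a] <- supers[which.min(lengths(haplogroup_nodes[supers]))]
  }
  attr(panel, "hierarchy") <- hier
  class(panel) <- c("diagnostic_panel", "data.frame")
  panel
}
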