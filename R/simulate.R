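#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a male canid
#' resequencing panel: a rooted tree with deep haplogroup splits and a
#' designated outgroup, infinite-sites mutations placed on branches (with
#' optional recurrent mutations on disjoint clades), per-position depth/MQ0
#' tracks with amplicon-like copy-number regions, and degraded "ancient"
#' samples with random site dropout and sub-threshold call quality.
#'
#' @param n_samples total samples including one outgroup leaf (`>= 2`).
#' @param n_sites_region length (bp) of the simulated reference.
#' @param n_haplogroups number of deep ingroup clades to plant.
#' @param tree_spec optional newick string to use instead of a random tree.
#' @param mutations_per_branch Poisson mean of mutations per branch, or a
#'   named vector of exact counts keyed by branch label (sorted clade
#'   leaves, comma-joined).
#' @param n_mutations optional exact total mutation count, distributed
#'   uniformly across branches (overrides `mutations_per_branch`).
#' @param recurrent_fraction proportion of all sites that are recurrent
#'   (placed on two disjoint, non-sibling branches), in \[0, 1\].
#' @param amplicon_regions list of `c(start, end, copy_number)` vectors
#'   (0-based half-open, `copy_number >= 2`).
#' @param variant_margin bp of buffer around amplicons where no variants are
#'   placed (diagnostic SNVs are modeled in uniquely mappable sequence;
#'   mapping reliability degrades near repeat boundaries).
#' @param mean_depth mean per-position read depth at copy number 1.
#' @param site_depth_cv coefficient of variation of the per-site depth
#'   factor shared across samples (gamma-distributed; models mappability
#'   and GC effects). 0 disables overdispersion.
#' @param mq0_baseline MQ0 read proportion outside amplicons.
#' @param mq0_amplicon MQ0 read proportion inside amplicons (`>= 0.5` so the
#'   downstream mask can recover the intervals).
#' @param ancient_samples list of `list(sample, callable_fraction,
#'   mean_depth)` entries describing samples to degrade.
#' @param seed integer seed fixing all outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20, n_sites_region = 100000,
                       n_haplogroups = 3, tree_spec = NULL,
                       mutations_per_branch = 5, n_mutations = NULL,
                       recurrent_fraction = 0,
                       amplicon_regions = list(c(40000, 60000, 2)),
                       variant_margin = 2000, mean_depth = 15,
                       site_depth_cv = 0.2, mq0_baseline = 0.02,
                       mq0_amplicon = 0.5, ancient_samples = NULL,
                       seed = 1L) {
  if (n_samples < 2) stop("invalid config: n_samples must be >= 2")
  if (recurrent_fraction < 0 || recurrent_fraction >= 1)
    stop("invalid config: recurrent_fraction must be in [0, 1)")
  if (mean_depth <= 0) stop("invalid config: mean_depth must be positive")
  for (a in amplicon_regions) {
    if (length(a) != 3) stop("invalid config: amplicon must be (start, end, copy_number)")
    if (a[1] < 0 || a[2] > n_sites_region || a[1] >= a[2])
      stop("invalid config: amplicon interval outside [0, n_sites_region)")
    if (a[3] < 2) stop("invalid config: amplicon copy_number must be >= 2")
  }
  for (an in ancient_samples %||% list())
    if (an$callable_fraction < 0 || an$callable_fraction > 1)
      stop("invalid config: callable_fraction must be in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 n_sites_region = as.integer(n_sites_region),
                 n_haplogroups = as.integer(n_haplogroups),
                 tree_spec = tree_spec,
                 mutations_per_branch = mutations_per_branch,
                 n_mutations = n_mutations,
                 recurrent_fraction = recurrent_fraction,
                 amplicon_regions = amplicon_regions,
                 variant_margin = as.integer(variant_margin),
                 mean_depth = mean_depth, site_depth_cv = site_depth_cv,
                 mq0_baseline = mq0_baseline,
                 mq0_amplicon = mq0_amplicon,
                 ancient_samples = ancient_samples,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a rooted binary tree with haplogroup clades and an outgroup
#'
#' Ingroup leaves are partitioned near-evenly into `n_haplogroups` clades;
#' each clade is a random coalescent subtree and the clades are joined by a
#' ladder backbone, with a single outgroup leaf `OUT` attached at the root.
#' The clade membership is recorded in the `haplogroups` attribute.
#'
#' @param config a [sim_config()].
#' @return an `ape::phylo` rooted binary tree with `n_samples` leaves;
#'   attributes `outgroup` and `haplogroups`.
#' @export
simulate_tree <- function(config) {
  if (config$n_samples < 2) stop("invalid config: n_samples must be >= 2")
  set.seed(config$seed)
  if (!is.null(config$tree_spec)) {
    tree <- ape::read.tree(text = config$tree_spec)
    attr(tree, "outgroup") <- attr(tree, "outgroup") %||% "OUT"
    return(tree)
  }
  n_in <- config$n_samples - 1L
  w <- max(2L, nchar(as.character(n_in)))
  labels <- sprintf(paste0("S%0", w, "d"), seq_len(n_in))
  k <- min(config$n_haplogroups, n_in)
  sizes <- rep(n_in %/% k, k) + c(rep(1L, n_in %% k), rep(0L, k - n_in %% k))
  groups <- split(labels, rep(seq_len(k), times = sizes))
  sub_nwk <- vapply(groups, function(g) {
    if (length(g) == 1) return(g)
    t <- ape::rcoal(length(g), tip.label = g)
    t$edge.length <- NULL
    sub(";$", "", ape::write.tree(t))
  }, character(1))
  backbone <- sub_nwk[1]
  if (k > 1)
    for (i in 2:k) backbone <- paste0("(", backbone, ",", sub_nwk[i], ")")
  tree <- ape::read.tree(text = paste0("(", backbone, ",OUT);"))
  attr(tree, "outgroup") <- "OUT"
  attr(tree, "haplogroups") <-
    setNames(lapply(groups, sort), paste0("HG", seq_len(k)))
  tree
}

#' Simulate haploid genotypes by placing mutations on branches
#'
#' Infinite-sites model: each non-recurrent mutation is placed on one branch
#' of the ingroup subtree (including the ingroup stem) and its derived
#' allele (coded 1) is carried by exactly the leaves below that branch; the
#' outgroup is ancestral (0) at every site. Recurrent sites are placed on
#' two disjoint non-sibling branches so their carrier set is the union of
#' two clades and never itself a clade. Variant positions avoid amplicons
#' plus `variant_margin` bp. Per-call depth is Poisson around `mean_depth`
#' with high genotype/mapping/base qualities; site-level INFO depth and MQ0
#' counts are drawn at the baseline MQ0 rate.
#'
#' @param tree a tree from [simulate_tree()].
#' @param config a [sim_config()].
#' @return list with `matrix` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`: `tree`, `variant_branch_map`, `recurrent_sites`,
#'   `amplicon_regions`, `haplogroup_of_sample`, `haplogroup_nodes`).
#' @export
simulate_genotypes <- function(tree, config) {
  set.seed(config$seed + 1L)
  outgroup <- attr(tree, "outgroup") %||% "OUT"
  tips <- tree$tip.label
  sets <- node_leafsets(tree)
  keys <- vapply(sets, clade_label, character(1))
  cand <- which(vapply(sets, function(s) !outgroup %in% s, logical(1)))
  cand <- cand[cand %in% tree$edge[, 2]]  # nodes with a parent edge
  edge_labels <- keys[cand]
  n_edges <- length(cand)

  mpb <- config$mutations_per_branch
  if (!is.null(config$n_mutations)) {
    counts <- tabulate(sample.int(n_edges, config$n_mutations,
                                  replace = TRUE), nbins = n_edges)
  } else if (!is.null(names(mpb))) {
    counts <- integer(n_edges)
    hit <- match(names(mpb), edge_labels)
    if (anyNA(hit)) stop("unknown branch label in mutations_per_branch")
    counts[hit] <- as.integer(mpb)
  } else {
    counts <- rpois(n_edges, mpb)
  }
  m <- sum(counts)
  n_rec <- round(config$recurrent_fraction /
                   (1 - config$recurrent_fraction) * m)

  allowed <- rep(TRUE, config$n_sites_region)
  for (a in config$amplicon_regions) {
    lo <- max(0L, a[1] - config$variant_margin)
    hi <- min(config$n_sites_region, a[2] + config$variant_margin)
    allowed[seq(lo + 1L, hi)] <- FALSE
  }
  allowed_pos <- which(allowed) - 1L
  if (m + n_rec > length(allowed_pos))
    stop("too many mutations for the mappable region")
  pos <- sort(sample(allowed_pos, m + n_rec))

  site_edge <- rep(cand, times = counts)
  if (length(site_edge) > 1)  # shuffle branch order across positions
    site_edge <- sample(site_edge)
  rec_flag <- c(rep(FALSE, m), rep(TRUE, n_rec))
  if (length(rec_flag) > 1) rec_flag <- sample(rec_flag)
  geno <- matrix(0L, nrow = length(tips), ncol = m + n_rec,
                 dimnames = list(tips, NULL))
  branch1 <- character(m + n_rec)
  branch2 <- rep(NA_character_, m + n_rec)
  i_base <- 0L
  disjoint_pairs <- NULL
  if (n_rec > 0) {
    prs <- utils::combn(n_edges, 2)
    ok <- vapply(seq_len(ncol(prs)), function(j) {
      s1 <- sets[[cand[prs[1, j]]]]; s2 <- sets[[cand[prs[2, j]]]]
      length(intersect(s1, s2)) == 0 &&
        !clade_label(union(s1, s2)) %in% keys
    }, logical(1))
    disjoint_pairs <- prs[, ok, drop = FALSE]
    if (ncol(disjoint_pairs) == 0)
      stop("tree has no disjoint non-sibling branch pair for recurrence")
  }
  for (j in seq_len(m + n_rec)) {
    if (!rec_flag[j]) {
      i_base <- i_base + 1L
      e <- site_edge[i_base]
      geno[sets[[e]], j] <- 1L
      branch1[j] <- keys[e]
    } else {
      pick <- disjoint_pairs[, sample.int(ncol(disjoint_pairs), 1L)]
      e1 <- cand[pick[1]]; e2 <- cand[pick[2]]
      geno[union(sets[[e1]], sets[[e2]]), j] <- 1L
      branch1[j] <- keys[e1]
      branch2[j] <- keys[e2]
    }
  }
  nsite <- m + n_rec
  ref <- sample(c("A", "C", "G", "T"), nsite, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  # per-site depth factor shared across samples (mappability/GC variation);
  # without it the cross-site depth distribution is unrealistically tight
  # and the downstream MAD outlier filter clips ordinary sites
  cv <- config$site_depth_cv %||% 0.2
  site_factor <- if (cv > 0)
    stats::rgamma(nsite, shape = cv^-2, rate = cv^-2) else rep(1, nsite)
  dp <- matrix(rpois(length(tips) * nsite,
                     rep(config$mean_depth * site_factor,
                         each = length(tips))),
               nrow = length(tips), dimnames = list(tips, NULL))
  gq <- matrix(99L, nrow = length(tips), ncol = nsite,
               dimnames = list(tips, NULL))
  mq <- matrix(60L, nrow = length(tips), ncol = nsite,
               dimnames = list(tips, NULL))
  bq <- matrix(37L, nrow = length(tips), ncol = nsite,
               dimnames = list(tips, NULL))
  site_dp <- as.integer(colSums(dp))
  site_mq0 <- rbinom(nsite, site_dp, config$mq0_baseline)
  gm <- genotype_matrix(geno, pos, ref, alt, chrom = "Ysim", dp = dp,
                        gq = gq, mq = mq, bq = bq, site_dp = site_dp,
                        site_mq0 = site_mq0)
  hgs <- attr(tree, "haplogroups") %||% list()
  hg_of <- setNames(rep(NA_character_, length(tips)), tips)
  for (h in names(hgs)) hg_of[hgs[[h]]] <- h
  truth <- structure(list(
    tree = tree,
    variant_branch_map = data.frame(site = gm$id, pos = pos,
                                    branch = branch1, branch2 = branch2,
                                    recurrent = !is.na(branch2),
                                    stringsAsFactors = FALSE),
    recurrent_sites = pos[!is.na(branch2)],
    amplicon_regions = config$amplicon_regions,
    haplogroup_of_sample = hg_of,
    haplogroup_nodes = hgs), class = "sim_truth")
  list(matrix = gm, truth = truth)
}

#' Simulate a per-position depth/MQ0 track
#'
#' Depth is Poisson with mean `mean_depth * copy_number(pos)`; MQ0 counts
#' are binomial at rate `mq0_amplicon` inside amplicons and `mq0_baseline`
#' outside. Filtered depth is the raw depth minus MQ0 reads.
#'
#' @param config a [sim_config()].
#' @return a [position_track()] spanning `[0, n_sites_region)`.
#' @export
simulate_tracks <- function(config) {
  if (config$mean_depth <= 0) stop("mean_depth must be positive")
  set.seed(config$seed + 2L)
  L <- config$n_sites_region
  cn <- rep(1, L)
  p <- rep(config$mq0_baseline, L)
  for (a in config$amplicon_regions) {
    idx <- seq(a[1] + 1L, a[2])
    cn[idx] <- a[3]
    p[idx] <- config$mq0_amplicon
  }
  raw <- rpois(L, config$mean_depth * cn)
  mq0 <- rbinom(L, raw, p)
  position_track(0:(L - 1L), raw, mq0)
}

#' Degrade one sample to ancient-DNA-like callability
#'
#' Sets approximately `1 - callable_fraction` of the sample's sites to
#' missing (i.i.d. dropout) with sub-threshold depth and genotype quality
#' annotations; all other samples are untouched.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_id sample to degrade.
#' @param callable_fraction proportion of sites kept callable, in \[0, 1\].
#' @param seed integer seed.
#' @return the modified genotype matrix.
#' @export
degrade_to_ancient <- function(gm, sample_id, callable_fraction, seed = 1L) {
  if (!sample_id %in% gm_samples(gm)) stop("unknown sample: ", sample_id)
  if (callable_fraction < 0 || callable_fraction > 1)
    stop("callable_fraction must be in [0, 1]")
  set.seed(seed)
  drop <- runif(ncol(gm$geno)) > callable_fraction
  if (any(drop)) {
    gm$geno[sample_id, drop] <- NA_integer_
    if (!is.null(gm$dp))
      gm$dp[sample_id, drop] <- sample(0:3, sum(drop), replace = TRUE)
    if (!is.null(gm$gq))
      gm$gq[sample_id, drop] <- sample(0:29, sum(drop), replace = TRUE)
  }
  gm
}

#' Simulate a full cohort: tree, genotypes, track and ancient samples
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `matrix`, `truth`, `track`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  tree <- simulate_tree(config)
  sg <- simulate_genotypes(tree, config)
  track <- simulate_tracks(config)
  gm <- sg$matrix
  for (i in seq_along(config$ancient_samples %||% list())) {
    an <- config$ancient_samples[[i]]
    gm <- degrade_to_ancient(gm, an$sample, an$callable_fraction,
                             seed = config$seed + 10L + i)
  }
  list(tree = tree, matrix = gm, truth = sg$truth, track = track,
       config = config)
}

#' Simulate a diverged sample/outgroup pair at a known substitution rate
#'
#' Places `Poisson(2 * rate * age_years * n_sites)` substitutions between
#' two lineages that split `age_years` ago, for validating the naive rate
#' estimator.
#'
#' @param rate substitutions per site per year.
#' @param age_years divergence time.
#' @param n_sites callable sites.
#' @param seed integer seed.
#' @return a two-sample [genotype_matrix()] (`IN`, `OUT`) containing only
#'   the substituted sites.
#' @export
simulate_pair_divergence <- function(rate, age_years, n_sites, seed = 1L) {
  set.seed(seed)
  n_sub <- rpois(1, 2 * rate * age_years * n_sites)
  pos <- sort(sample.int(n_sites, min(n_sub, n_sites))) - 1L
  geno <- matrix(c(rep(1L, length(pos)), rep(0L, length(pos))),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("IN", "OUT"), NULL))
  genotype_matrix(geno, pos, ref = rep("A", length(pos)),
                  alt = rep("G", length(pos)), chrom = "Ysim")
}
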