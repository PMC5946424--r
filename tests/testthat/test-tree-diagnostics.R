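five_leaf_tree <- function() ape::read.tree(text = "((A,B),(C,D),O);")

make_gm <- function(geno) {
  genotype_matrix(geno, pos = seq_len(ncol(geno)) - 1L,
                  ref = rep("A", ncol(geno)), alt = rep("G", ncol(geno)))
}

test_that("polarization against the outgroup identifies derived carriers", {
  geno <- matrix(c(1L, 1L, 0L, 0L,
                   0L, 0L, 0L, 0L,
                   1L, 0L, 0L, NA), nrow = 4,
                 dimnames = list(c("A", "B", "C", "O"), NULL))
  v <- polarize(make_gm(geno), "O")
  expect_setequal(v[[1]]$carriers, c("A", "B"))
  expect_equal(v[[1]]$derived, "G")
  expect_equal(v[[1]]$ancestral, "A")
  # all samples equal the outgroup allele: uninformative
  expect_true(v[[2]]$uninformative)
  expect_length(v[[2]]$carriers, 0)
  # outgroup missing: skipped by default ...
  expect_true(v[[3]]$uninformative)
  # ... or polarized by minor allele on request (1 carrier of 3)
  v2 <- polarize(make_gm(geno), "O", missing_fallback = "minor")
  expect_equal(v2[[3]]$carriers, "A")
  expect_error(polarize(make_gm(geno), "X"), "outgroup")
})

test_that("outgroup carrying the alternate allele flips polarization", {
  geno <- matrix(c(0L, 0L, 1L, 1L), nrow = 4,
                 dimnames = list(c("A", "B", "C", "O"), NULL))
  v <- polarize(make_gm(geno), "O")
  expect_setequal(v[[1]]$carriers, c("A", "B"))
  expect_equal(v[[1]]$derived, "A")  # derived allele is the reference base
})

test_that("branch assignment matches the worked examples", {
  tr <- five_leaf_tree()
  r <- assign_branch(c("A", "B"), tr, outgroup = "O")
  expect_equal(r$status, "diagnostic")
  expect_equal(r$node, "A,B")

  r2 <- assign_branch(c("A", "C"), tr, outgroup = "O")
  expect_equal(r2$status, "incompatible")
  expect_equal(r2$top_nodes, c("A", "C"))

  r3 <- assign_branch("A", tr, outgroup = "O")
  expect_equal(r3$status, "diagnostic")
  expect_equal(r3$node, "A")

  # carried by the whole ingroup: diagnostic for the ingroup stem
  r4 <- assign_branch(c("A", "B", "C", "D"), tr, outgroup = "O")
  expect_equal(r4$status, "diagnostic")
  expect_equal(r4$node, "A,B,C,D")

  expect_equal(assign_branch(character(0), tr, "O")$status, "uninformative")
  expect_error(assign_branch("Z", tr, "O"), "not in tree")
})

test_that("missing leaves are excluded from the universality test", {
  tr <- five_leaf_tree()
  # B missing: {A} alone is now universal at node (A,B)
  r <- assign_branch("A", tr, outgroup = "O", missing = "B")
  expect_equal(r$status, "diagnostic")
  expect_equal(r$node, "A,B")
  # but a non-carrier with a call still blocks deeper nodes
  r2 <- assign_branch(c("A", "C"), tr, outgroup = "O", missing = "B")
  expect_equal(r2$status, "incompatible")
  expect_equal(r2$top_nodes, c("A,B", "C"))
})

test_that("assignment agrees with the brute-force clade oracle", {
  set.seed(73)
  for (i in 1:200) {
    n <- sample(4:16, 1)
    tree <- ape::rtree(n)
    tips <- tree$tip.label
    outgroup <- if (runif(1) < 0.5) sample(tips, 1) else NULL
    rest <- setdiff(tips, outgroup)
    missing <- if (runif(1) < 0.3)
      sample(rest, sample.int(max(1, length(rest) %/% 4), 1)) else character()
    pool <- setdiff(rest, missing)
    if (length(pool) == 0) next
    carriers <- sample(pool, sample.int(length(pool), 1))
    got <- assign_branch(carriers, tree, outgroup, missing)
    want <- oracle_assign_branch(carriers, tree, outgroup, missing)
    expect_identical(got$status, want$status)
    expect_identical(got$node, want$node)
    expect_identical(got$top_nodes, want$top_nodes)
  }
})

test_that("statuses partition the polarized variants", {
  cfg <- sim_config(n_samples = 10, n_mutations = 80,
                    recurrent_fraction = 0.1, seed = 79)
  sg <- simulate_genotypes(simulate_tree(cfg), cfg)
  asn <- assign_branches(polarize(sg$matrix, "OUT"), sg$truth$tree, "OUT")
  cd <- count_diagnostics(asn)
  expect_equal(sum(cd$branch_counts$count) + cd$n_incompatible +
                 cd$n_uninformative, cd$n_total)
  expect_equal(cd$n_total, ncol(sg$matrix$geno))
})

test_that("per-branch diagnostic counts equal the planted counts", {
  cfg <- sim_config(n_samples = 14, n_mutations = 200, seed = 83)
  sg <- simulate_genotypes(simulate_tree(cfg), cfg)
  asn <- assign_branches(polarize(sg$matrix, "OUT"), sg$truth$tree, "OUT")
  expect_true(all(asn$status == "diagnostic"))
  expect_equal(asn$node, sg$truth$variant_branch_map$branch)
  cd <- count_diagnostics(asn)
  want <- table(sg$truth$variant_branch_map$branch)
  got <- setNames(cd$branch_counts$count, cd$branch_counts$node)
  expect_equal(got[order(names(got))],
               c(want)[order(names(want))], ignore_attr = TRUE)
  expect_equal(cd$n_incompatible, 0L)
})

test_that("injected recurrent variants get exactly two top nodes", {
  cfg <- sim_config(n_samples = 12, n_mutations = 100,
                    recurrent_fraction = 0.1, seed = 89)
  sg <- simulate_genotypes(simulate_tree(cfg), cfg)
  asn <- assign_branches(polarize(sg$matrix, "OUT"), sg$truth$tree, "OUT")
  rec <- sg$truth$variant_branch_map$recurrent
  expect_true(all(asn$status[rec] == "incompatible"))
  tops <- attr(asn, "top_nodes")
  expect_true(all(lengths(tops[rec]) == 2L))
})

test_that("private variants are diagnostic for their leaf on any tree", {
  set.seed(97)
  for (i in 1:20) {
    tree <- ape::rtree(sample(3:12, 1))
    tip <- sample(tree$tip.label, 1)
    r <- assign_branch(tip, tree)
    expect_equal(r$status, "diagnostic")
    expect_equal(r$node, tip)
  }
})

test_that("panels keep nested haplogroup labels disjoint", {
  cfg <- sim_config(n_samples = 10, n_mutations = 120, seed = 101)
  sg <- simulate_genotypes(simulate_tree(cfg), cfg)
  tree <- sg$truth$tree
  asn <- assign_branches(polarize(sg$matrix, "OUT"), tree, "OUT")
  hgs <- sg$truth$haplogroup_nodes
  # add the ancestor of HG1+HG2 as a parent label, mirroring HG8-HG23
  nodes <- c(hgs, list(HGa = sort(c(hgs$HG1, hgs$HG2))))
  panel <- extract_panel(asn, nodes)
  expect_gt(nrow(panel), 0)
  expect_false(any(duplicated(panel$pos)))
  hier <- attr(panel, "hierarchy")
  expect_equal(unname(hier[c("HG1", "HG2")]), c("HGa", "HGa"))
  expect_true(is.na(hier["HGa"]))
  # panel sites for a label are exactly the truth mutations on its branch
  tr <- sg$truth$variant_branch_map
  for (lab in names(hgs)) {
    want <- sort(tr$pos[tr$branch == paste(hgs[[lab]], collapse = ",")])
    expect_equal(sort(panel$pos[panel$haplogroup == lab]), want)
  }
  empty <- extract_panel(asn[0, , drop = FALSE], nodes)
  expect_equal(nrow(empty), 0L)
})
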