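toy_panel <- function() {
  p <- data.frame(
    haplogroup = c(rep("HGp", 3), rep("HG1", 7), rep("HG2", 5)),
    pos = 0:14,
    ancestral = rep("A", 15),
    derived = rep("G", 15), stringsAsFactors = FALSE)
  attr(p, "hierarchy") <- c(HGp = NA_character_, HG1 = "HGp", HG2 = "HGp")
  class(p) <- c("diagnostic_panel", "data.frame")
  p
}

toy_gm <- function(calls) {
  # one sample "X" over the 15 panel sites
  geno <- matrix(as.integer(calls), nrow = 1,
                 dimnames = list("X", NULL))
  genotype_matrix(geno, pos = 0:14, ref = rep("A", 15), alt = rep("G", 15))
}

test_that("scores count derived and callable panel sites per label", {
  # derived at all HGp+HG1 sites, ancestral at HG2 sites
  gm <- toy_gm(c(rep(1, 10), rep(0, 5)))
  s <- score_sample(gm, "X", toy_panel())
  expect_equal(s$n_derived[s$haplogroup == "HG1"], 7L)
  expect_equal(s$n_callable[s$haplogroup == "HG1"], 7L)
  expect_equal(s$n_derived[s$haplogroup == "HG2"], 0L)

  # no callable sites anywhere
  s0 <- score_sample(toy_gm(rep(NA, 15)), "X", toy_panel())
  expect_true(all(s0$n_callable == 0L))
  expect_true(all(s0$n_derived == 0L))

  # 2 of 4 callable derived alleles at a leaf label
  calls <- rep(NA, 15)
  calls[4:7] <- c(1, 1, 0, 0)  # four HG1 sites callable, two derived
  s2 <- score_sample(toy_gm(calls), "X", toy_panel())
  expect_equal(s2$n_derived[s2$haplogroup == "HG1"], 2L)
  expect_equal(s2$n_callable[s2$haplogroup == "HG1"], 4L)
})

test_that("calling picks the most specific fully supported label", {
  panel <- toy_panel()
  hier <- attr(panel, "hierarchy")
  # full support at parent and one child: the child wins
  sc <- data.frame(haplogroup = c("HGp", "HG1", "HG2"),
                   n_derived = c(3L, 7L, 0L), n_callable = c(3L, 7L, 5L))
  call <- call_haplogroup(sc, hier, sample = "X")
  expect_equal(call$label, "HG1")
  expect_equal(call$n_derived, 7L)
  expect_equal(call$support, 1.0)

  # children uncallable: the ancestral label is retained
  sc2 <- data.frame(haplogroup = c("HGp", "HG1", "HG2"),
                    n_derived = c(3L, 0L, 0L), n_callable = c(3L, 0L, 0L))
  expect_equal(call_haplogroup(sc2, hier)$label, "HGp")

  # nothing callable: no-call
  sc3 <- data.frame(haplogroup = c("HGp", "HG1", "HG2"),
                    n_derived = c(0L, 0L, 0L), n_callable = c(0L, 0L, 0L))
  expect_true(is.na(call_haplogroup(sc3, hier)$label))
})

test_that("partial support annotates but never assigns", {
  panel <- toy_panel()
  hier <- attr(panel, "hierarchy")
  sc <- data.frame(haplogroup = c("HGp", "HG1", "HG2"),
                   n_derived = c(0L, 2L, 0L), n_callable = c(0L, 4L, 3L))
  call <- call_haplogroup(sc, hier)
  expect_true(is.na(call$label))
  expect_match(call$annotations, "consistent-with HG1 \\(2/4\\)", all = FALSE)
})

test_that("ties between fully supported sibling labels give no-call", {
  hier <- c(HG1 = NA_character_, HG2 = NA_character_)
  sc <- data.frame(haplogroup = c("HG1", "HG2"),
                   n_derived = c(3L, 4L), n_callable = c(3L, 4L))
  call <- call_haplogroup(sc, hier)
  expect_true(is.na(call$label))
  expect_match(call$annotations, "tie:HG1\\|HG2", all = FALSE)
})

test_that("a cohort of three planted haplogroups is recovered exactly", {
  cfg <- sim_config(n_samples = 31, n_haplogroups = 3, n_mutations = 400,
                    seed = 103)
  sim <- simulate_cohort(cfg)
  asn <- assign_branches(polarize(sim$matrix, "OUT"), sim$tree, "OUT")
  panel <- extract_panel(asn, sim$truth$haplogroup_nodes)
  co <- assign_cohort(sim$matrix, panel, exclude = "OUT")
  expect_equal(as.vector(co$frequency[c("HG1", "HG2", "HG3")]),
               c(10L, 10L, 10L))
  truth <- sim$truth$haplogroup_of_sample[co$calls$sample]
  expect_equal(co$calls$label, unname(truth))
  expect_true(all(co$calls$support == 1.0))
})

test_that("a cohort of one yields a single call row", {
  cfg <- sim_config(n_samples = 2, n_haplogroups = 1, n_mutations = 10,
                    seed = 107)
  sim <- simulate_cohort(cfg)
  asn <- assign_branches(polarize(sim$matrix, "OUT"), sim$tree, "OUT")
  panel <- extract_panel(asn, sim$truth$haplogroup_nodes)
  co <- assign_cohort(sim$matrix, panel, exclude = "OUT")
  expect_equal(nrow(co$calls), 1L)
  expect_equal(sum(co$frequency), 1L)
})

test_that("site dropout reduces callable counts monotonically", {
  cfg <- sim_config(n_samples = 10, n_mutations = 200, seed = 109)
  sim <- simulate_cohort(cfg)
  asn <- assign_branches(polarize(sim$matrix, "OUT"), sim$tree, "OUT")
  panel <- extract_panel(asn, sim$truth$haplogroup_nodes)
  s <- gm_samples(sim$matrix)[1]
  full <- score_sample(sim$matrix, s, panel)
  half <- score_sample(degrade_to_ancient(sim$matrix, s, 0.5, seed = 7),
                       s, panel)
  expect_true(all(half$n_callable <= full$n_callable))
  expect_lt(sum(half$n_callable), sum(full$n_callable))
  # degraded sample still called, with reduced support counts
  co <- assign_cohort(degrade_to_ancient(sim$matrix, s, 0.5, seed = 7),
                      panel, exclude = "OUT")
  truth <- sim$truth$haplogroup_of_sample
  got <- co$calls$label[co$calls$sample == s]
  expect_true(is.na(got) || got == truth[[s]])
})

test_that("samples below the support threshold are never assigned", {
  hier <- c(HG1 = NA_character_, HG2 = NA_character_)
  sc <- data.frame(haplogroup = c("HG1", "HG2"),
                   n_derived = c(3L, 1L), n_callable = c(5L, 4L))
  expect_true(is.na(call_haplogroup(sc, hier)$label))
})
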