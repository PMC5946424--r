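Package: patriline
Title: Y-Chromosome Callability Masking, Branch-Diagnostic Variant Mapping,
    and Haplogroup Assignment for Canid Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for paternal-lineage analysis from short-read resequencing
    of male canids. Builds a regional callability mask from per-position read
    depth and MQ0 statistics smoothed by exponentially weighted moving
    averages; applies site-level filters (heterozygote and missingness
    screens, MQ0/depth ratio, median +/- 3 MAD depth outliers, indel
    proximity) and per-genotype quality thresholds for degraded ancient
    samples; maps polarized SNVs onto a rooted phylogeny to find the deepest
    node of genotype universality and classify variants as branch-diagnostic
    or potentially recurrent; calls Y haplogroups for modern and
    partially-callable ancient samples with n-derived-of-n-callable support;
    and converts outgroup divergence counts into a naive calibrated
    substitution rate. A synthetic-data generator with known ground truth
    (random rooted trees, infinite-sites mutations, amplicon-like
    copy-number tracks, ancient-style site dropout) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
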