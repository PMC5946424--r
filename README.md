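# patriline

Paternal-lineage analysis of male short-read resequencing data. Because
the Y chromosome is haploid and largely non-recombining, every stable SNV
marks the branch of the paternal genealogy on which it arose, and
haplogroups — clades of that genealogy — can be recognized from small
panels of branch-diagnostic alleles. `patriline` is aimed at population
geneticists working with canid (or comparable) Y data who need to go from
per-position mapping statistics and a multi-sample VCF to haplogroup calls
and a calibrated substitution rate, including for partially callable
ancient specimens.

The package implements:

* **Regional callability mask** — exponentially weighted moving averages
  (s₁ = x₁, sₜ = αxₜ + (1−α)sₜ₋₁) of filtered read depth and of the
  MQ0/raw-depth ratio, thresholded (depth within bounds, ratio ≤ 0.10) to
  classify the chromosome into pass/fail intervals; multi-copy amplicon
  tracts fail on the MQ0 ratio.
* **Site and genotype filters** — heterozygote/missingness screens, strict
  MQ0/depth > 0.10, depth outliers outside median ± 3·MAD (unscaled),
  sites within 5 bp of indels; ancient genotypes require DP ≥ 4, GQ ≥ 30,
  MQ ≥ 15, BQ ≥ 15.
* **Sample QC** — A/X depth-ratio sex inference (> 1.85 and autosomal
  coverage > 10×) and a method-of-moments IBS→IBD (pi-hat) screen for
  run-identity failures (drop when π̂ < 0.90 between runs of > 100,000
  reads).
* **Branch-diagnostic variant mapping** — polarize each SNV against the
  outgroup, then find the deepest node of genotype universality: the
  maximal nodes whose non-missing leaves are all carriers. One top node ⇒
  diagnostic for that branch; several ⇒ potentially recurrent and
  incompatible with the tree.
* **Haplogroup calling** — n-derived-of-n-callable scoring against a
  diagnostic panel, hierarchy-aware (most specific fully supported label
  wins; ancestral label retained when child sites are uncallable; partial
  support annotated, never assigned).
* **Naive calibrated rate** — μ̂ = k̄ / (2·T·L) substitutions/site/year
  from the mean outgroup divergence count k̄, callable sites L and root
  age T (default 1.5 Myr).
* **Synthetic-data generator** — trees with planted haplogroup clades,
  infinite-sites mutations (plus injectable recurrent sites on disjoint
  clades), amplicon-bearing depth/MQ0 tracks and ancient-style dropout,
  all with recorded ground truth.

## Worked example

Simulate a 20-sample cohort (19 ingroup + outgroup `OUT`, three haplogroup
clades, 500 mutations, one copy-number-2 amplicon on a 100 kb reference),
write it to files, and run the full pipeline:

```r
library(patriline)
sim <- simulate_cohort(sim_config(n_samples = 20, n_mutations = 500,
                                  seed = 42))
d <- tempfile(); write_simulation(sim, d)
res <- run_pipeline(list(vcf = file.path(d, "genotypes.vcf"),
                         tree = file.path(d, "tree.nwk"),
                         track = file.path(d, "track.tsv"), outgroup = "OUT",
                         haplogroups = sim$truth$haplogroup_nodes,
                         out_dir = file.path(d, "out")))
res$cohort$frequency
#> HG1 HG2 HG3
#>   7   6   6
print(res$rate)
#> <rate_estimate> 3.35e-10 substitutions/site/year
#>   mean 79.68 (s.d. 14.91) substitutions over 79196 sites, root age 1.5e+06 yr
```

The run log shows what each stage did: the mask recovers the amplicon
(79,196 of 100,000 positions pass; all 500 variants lie in pass regions),
site filters trim the 19-site depth tail, all 481 analyzed variants map to
a single branch each (0 incompatible), and every one of the 19 ingroup
samples is called to its generating haplogroup (7 + 6 + 6). The rate is
the mean ingroup–outgroup divergence (79.7 substitutions) divided by
2 × 1.5 Myr × 79,196 callable sites. On the published study's own inputs —
362.81 mean substitutions over 484,924 callable sites — the same formula
gives 2.49 × 10⁻¹⁰ substitutions/site/year:

```r
naive_rate(362.81, calibration_config(484924, 1.5e6))
#> <rate_estimate> 2.49e-10 substitutions/site/year
```

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/patriline.R simulate --out sim_out --seed 1
Rscript inst/scripts/patriline.R mask --track sim_out/track.tsv --out mask.bed
Rscript inst/scripts/patriline.R run --config pipeline.yaml
```

See `vignettes/patriline-methods.Rmd` for the model, parameter defaults
and their rationale, and known limitations.

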