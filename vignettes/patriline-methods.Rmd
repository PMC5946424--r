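---
title: "Methods: callability masking, diagnostic-variant mapping and haplogroup assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: callability masking, diagnostic-variant mapping and haplogroup assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patriline)
```

# The problem

Y chromosomes are haploid and escape recombination over most of their
length, so paternal lineages form a clean genealogy: every stable SNV marks
the branch on which it arose, and clades of that genealogy — haplogroups —
can be recognized in any male sample from a handful of branch-diagnostic
alleles. In canids this is complicated by the Y's repetitive architecture:
roughly megabase-scale amplicon tracts (multi-copy, near-identical repeats
including the SRY region) defeat unique short-read mapping, and ancient
specimens add low depth and site dropout on top. `patriline` implements the
full chain from per-position mapping statistics to calibrated substitution
rates, with a synthetic-data generator that provides ground truth for every
stage.

# Regional callability mask

Per-position series — filter-passing read depth and the MQ0/raw-depth
ratio (the fraction of reads with mapping quality zero) — are smoothed with
an exponentially weighted moving average,
$s_t = \alpha x_t + (1-\alpha) s_{t-1}$, $s_1 = x_1$, and thresholded:
a position is callable iff smoothed filtered depth lies in
$[d_{\min}, d_{\max}]$ and the smoothed MQ0 ratio is at most $r_{\max}$,
outside any a-priori excluded interval. Runs of equal status are merged
into half-open intervals that exactly tile the analyzed range.

Tunable parameters, defaults, and why:

* `ewma_alpha = 2/(1000+1)` — an effective window of ~1 kb. The mask is
  meant to find multi-kb structural features (amplicons), not single-site
  noise; a kb-scale window suppresses Poisson depth fluctuation while
  keeping boundary blur an order of magnitude smaller than the features of
  interest. Configurable; `alpha = 1` disables smoothing entirely and the
  mask then equals a positionwise threshold check (a tested identity).
* `mq0_ratio_max = 0.10` — matches the site-level MQ0/raw-depth threshold
  used downstream, so regional and site-level screens are consistent.
* `depth_min`/`depth_max` default to 0.33x and 2.0x the median filtered
  depth of the track. Half-depth regions and duplicated (2x) regions are
  the natural failure modes; the published figure shows dashed bounds of
  this character without printing values, so these are package defaults,
  not literature values.
* `min_region_len = 1` — no demotion of short pass runs by default; when
  raised, a demoted run takes the reason of the nearest failing neighbor
  (depth preferred when both flank it).

The MQ0 ratio at zero-depth positions is defined as 0; such positions
cannot pass the depth bounds, so the convention never affects the mask,
only avoids 0/0.

Because both filters are applied to smoothed series, mask edges blur by
roughly $1/\alpha$ positions: entering an amplicon the smoothed ratio
crosses the threshold ~0.1 kb late, and leaving it decays back over
~0.9 kb. On default synthetic tracks (20 kb amplicon in 100 kb) this bounds
the achievable Jaccard overlap with truth at ~0.95, which is what the
acceptance checks observe. A real ~1 Mb amplicon makes the relative blur
ten times smaller.

# Site-level and ancient-sample filters

Within callable regions, candidate SNV sites are dropped when any sample
call is a maximum-likelihood heterozygote (impossible on a haploid
chromosome — a mapping artifact), when any sample call is missing, or when
the site MQ0/raw-depth ratio exceeds 0.10 (strictly — a ratio of exactly
0.10 passes). A depth-outlier filter then removes sites whose per-site
median depth across samples falls outside median ± 3 MAD, with MAD the
*unscaled* median absolute deviation (no 1.4826 normal-consistency factor
— the source methods state plain M.A.D.). Sites within 5 bp of a called
indel are removed; we read "within 5 bp" inclusively (distance 5 fails,
6 passes) as the conservative interpretation, and the window is
configurable. When all depths are equal the MAD bounds collapse to the
median — only sites at exactly the median pass; this degenerate case is
documented and tested rather than special-cased.

Two choices the literature leaves open, decided here: the depth summary
fed to the MAD filter is the per-site *median* across samples
(configurable to the mean), and filter reasons are reported in the fixed
order het, missing, mq0, depth, indel so logs are reproducible; the
surviving site set is independent of application order.

Ancient samples are screened per genotype, not per site: a call is usable
iff depth >= 4, genotype quality >= 30, mapping quality >= 15 and base
quality >= 15 (all inclusive, all configurable). In the pipeline, ancient
samples are excluded from the site-level missingness screen — their
dropout is information about the sample, not the site — and their
uncallable genotypes are simply set to missing before haplogroup scoring.

# Sample QC

Males are retained when the autosome-to-X depth ratio exceeds 1.85 and
autosomal coverage exceeds 10x (both strict). Run identity within a sample
is screened with a method-of-moments IBS-to-IBD estimator: with per-site
alternate-allele frequencies $p_j$ from the pooled run set, the expected
IBS match rate for unrelated haploid chromosomes is
$e = \overline{p_j^2 + q_j^2}$, and
$\hat\pi = (\bar m - e)/(1 - e)$ clamped to $[0,1]$, where $\bar m$ is the
observed match rate. Identical runs give exactly 1; a sample is dropped
when any pair of its runs with more than 100,000 reads each shows
$\hat\pi < 0.90$. The original analysis used an external tool's `--genome`
method whose exact formula is not published; this estimator preserves the
threshold semantics (tested to recover sharing levels 0, 0.5 and 1 within
0.05) without claiming numeric parity with that tool.

# Branch assignment and diagnostic panels

Variants are polarized against the outgroup: the derived allele is
whichever allele differs from the outgroup call, and carriers are the
ingroup samples holding it. When the outgroup call is missing the site is
uninformative by default; an optional minor-allele fallback polarizes by
frequency, with ties resolved to uninformative.

For each variant, assignment walks rootward from every carrier leaf while
the candidate node remains *carrier-pure*: every non-missing, non-outgroup
leaf below it is a carrier. The maximal such nodes are the variant's top
nodes. Exactly one top node makes the variant diagnostic for that branch
(the deepest node of genotype universality); two or more make it
potentially recurrent and incompatible with the tree; no carriers make it
uninformative. Three design points:

* Missing leaves are excluded from the purity test, so a low-coverage
  sample cannot break an otherwise clean diagnostic site. A strict mode
  (treat missing as non-carrier) is available by passing the missing set
  as empty.
* Outgroup leaves are likewise excluded, which makes a variant carried by
  the whole ingroup diagnostic for the ingroup stem rather than
  incompatible at a basal trifurcation.
* Branches are identified by the sorted tuple of their descendant leaf
  names — stable across tree serializations and polytomies.

The walk-up procedure is verified against a brute-force oracle (enumerate
every node's leaf set, test purity by set algebra, take maximal nodes by
containment) on 1000 random trees per run; a variant is diagnostic iff its
carrier set equals some clade's non-missing leaf set.

Diagnostic panels list, per labeled haplogroup node, the sites diagnostic
to exactly that branch with ancestral/derived alleles; nested labels stay
disjoint (a stem site is never listed under a child), and the label
hierarchy is recovered from leaf-set nesting.

# Haplogroup calling

A sample is scored per label as `n_derived` of `n_callable` panel sites.
With default `min_support = 1`, only labels with every callable diagnostic
site derived qualify, and the most specific (deepest) qualifying label is
called — so a sample callable only at stem sites is assigned the ancestral
label with children unresolved, mirroring how partially callable ancient
samples behave. Partial support (e.g. 2 of 4 callable derived alleles at a
leaf label) is reported as a consistent-with annotation, never as an
assignment; ties between equally specific fully supported labels yield a
no-call with the full score table retained. These conventions follow the
narrative treatment of ancient samples in the source study, which states
no formal partial-support rule.

# Naive substitution rate

With mean ingroup-outgroup substitution count $\bar k$ over $L$ callable
sites and an assumed root age $T$, the naive rate is
$\hat\mu = \bar k / (2TL)$ — the factor 2 because divergence accumulates
on both lineages. Defaults: $T = 1.5$ Myr (dog/wolf-coyote split). Sites
missing in either member of a pair are excluded from the count but *not*
from $L$: the published computation divides by the fixed callable-site
total, and a per-pair denominator is available as an option. The s.d. over
ingroup samples uses the $n-1$ denominator (unspecified in the source).
The worked example — 362.81 substitutions, 484,924 sites, 1.5 Myr — gives
$2.49\times10^{-10}$ substitutions/site/year to three significant figures:

```{r}
naive_rate(362.81, calibration_config(484924, 1.5e6))
```

# The synthetic-data generator

The generator provides every input with known truth. What it emulates, and
what it deliberately does not:

* **Tree**: ingroup leaves are split near-evenly into `n_haplogroups`
  random coalescent clades joined by a ladder backbone, with one outgroup
  leaf at the root — deep splits like the real haplogroup structure, but
  no attempt at realistic canid demography.
* **Mutations**: infinite-sites placement on ingroup branches (the stem
  included); each non-recurrent variant's carriers are exactly one clade.
  Recurrence is injected explicitly: a recurrent site is placed on two
  disjoint, non-sibling branches, so its carrier set is a union of clades
  and provably not a clade. Counts are Poisson per branch, an exact total,
  or a per-branch map.
* **Tracks**: depth is Poisson with mean `mean_depth * copy_number`;
  amplicons ([40, 60) kb of 100 kb, copy number 2 by default) raise the
  MQ0 rate from 0.02 to 0.5 so the in-amplicon smoothed ratio sits far
  above the 0.10 threshold — the regime the mask is designed for.
  Positions are independent given the copy-number profile; read-level
  simulation, alignment and PCR/damage chemistry are out of scope.
* **Per-call depths** carry a gamma-distributed per-site factor
  (CV 0.2) shared across samples, modeling mappability/GC variation.
  Without it, the cross-site distribution of median depth is unrealistically
  tight (MAD ~0.5 reads) and the median ± 3 MAD filter clips ~12% of
  perfectly ordinary sites; with it, the filter trims only the few-percent
  depth tail, as it does on real data.
* **Variant placement** avoids amplicons plus a 2 kb margin: real
  diagnostic SNVs are ascertained in uniquely mappable sequence, and
  mapping reliability degrades near repeat boundaries (the same blur the
  EWMA mask shows).
* **Ancient samples**: i.i.d. site dropout at `1 - callable_fraction`,
  with sub-threshold depth/quality annotations on dropped calls. Damage
  patterns (deamination) are not simulated — only the downstream quality
  thresholds matter to this package.

A fixed seed makes every output bit-identical. Because dropout is i.i.d.
and mutations are infinite-sites, passing tests demonstrate algorithmic
correctness under the assumed statistical structure; they do not
demonstrate robustness to correlated dropout, reference bias, or
genotyping error beyond the modeled het/missing/depth artifacts.

# Problem sizes and numerical choices

Test and acceptance runs use 20-sample cohorts with 500 planted mutations
on 100 kb regions, 1000 random trees of at most 16 leaves for oracle
comparison, and 100 replicate pairs at 5e5 sites for rate recovery —
sizes at which expected behavior is sharp (binomial/Poisson standard
errors well below the asserted tolerances) while a full run stays in
seconds. The end-to-end recovery comparison is made over the sites
retained by filtering: the MAD depth filter legitimately removes the
extreme few percent of the depth distribution even on clean data, and
branch counts and haplogroup labels are required to match truth exactly on
the analyzed set (with retention itself asserted at >= 95%).

Degenerate inputs are defined, not errored, wherever a convention is
defensible: MQ0 ratio 0 at zero depth, collapsed MAD bounds for constant
depths, `sd = NA` for single-sample cohorts, empty carrier sets as
uninformative. Genuine contract violations (empty tracks, unknown samples,
alpha outside (0,1], missing files) raise named errors.

# Known limitations

* The pass-position total of a real mask depends on the unpublished EWMA
  parameterization and depth bounds; the defaults here are reasoned
  choices, so absolute pass counts are not comparable to published totals
  (rate calibration accepts the callable-site count as an input for
  exactly this reason).
* The pi-hat estimator is a stand-in with preserved semantics, not a
  reimplementation of the original tool.
* Coordinates are handled as given (0-based half-open internally, 1-based
  in VCF, 0-based in BED); reference-orientation flips are the caller's
  responsibility via explicit coordinate transformation.
* Tree inference, Bayesian TMRCA estimation, array-probe remapping and
  ancestry analyses are out of scope; the package consumes a rooted tree,
  it does not infer one.
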