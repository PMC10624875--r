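---
title: "Paired differential methylation analysis of cryopreserved sperm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired differential methylation analysis of cryopreserved sperm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryomethyl)
library(data.table)
```

## The problem

Fish spermatozoa carry a DNA-methylation profile that is partly inherited
by the embryo, so any methylation damage inflicted by cryopreservation is
a potential risk for the offspring. The design this package analyses is a
paired one: sperm from each of 12 males is assayed fresh and after
freezing with each of three cryoprotectants (DMSO, methanol, glycerol),
giving 48 RRBS libraries. RRBS (reduced representation bisulfite
sequencing) digests the genome with MspI (CCGG), size-selects fragments,
bisulfite-converts them and sequences the survivors, so each library
reports methylated/unmethylated read counts for a few percent of the
genome's CpG cytosines.

The pipeline starts downstream of alignment, at per-cytosine count
reports (Bismark coverage or CX dialect). Everything upstream — trimming,
alignment, methylation extraction — is out of scope.

## Coordinate and counting conventions

* Internal coordinates are 1-based and strand-resolved, matching CX
  reports; BED/bedGraph export converts to 0-based half-open at the
  boundary.
* Both cytosines of a CpG dinucleotide are kept as distinct sites (one
  per strand). The genomic denominator for representation statistics is
  therefore twice the CG-dinucleotide count. We do not collapse strands
  anywhere, because symmetry of cryopreservation damage across strands is
  exactly the kind of assumption the analysis should not make.
* Methylation ratios are always recomputed from counts; the percent
  column of coverage files is ignored.
* Coverage-dialect files carry no strand; when a reference FASTA is
  available the strand is resolved from the base at the position, else it
  is stored as "." and the records stay in every analysis (they are
  excluded only from strand-specific invariant checks).

## The paired test

A differentially methylated cytosine (DMC) is called per cryoprotectant
from the males in which the site was read (depth ≥ 1) in *both* the fresh
and the treated sample — "paired cytosines". Only sites paired in at
least 6 of the 12 males are tested; this keeps every call reproducible
across half the cohort. No information is borrowed from neighbouring
cytosines: the sperm methylome is so strongly bimodal that per-site
counts are already near-binary, and smoothing would import exactly the
bias the paired design avoids.

For male $m$ with counts $(n^{meth}, n^{unmeth})$ and depth
$N = n^{meth}+n^{unmeth}$, the stabilised proportion is
$\hat p = (n^{meth}+0.5)/(N+1)$ and the arcsine link
$y = \arcsin\sqrt{\hat p}$. The paired difference
$d_m = y^{treated}_m - y^{fresh}_m$ has delta-method variance
$v_m = \tfrac{1}{4(N^{treated}_m+1)} + \tfrac{1}{4(N^{fresh}_m+1)}$,
which is proportion-free — the variance-stabilising property of the
arcsine link. The site statistic is the inverse-variance-weighted Wald
statistic

$$ z = \frac{\sum_m d_m / v_m}{\sum_m 1/v_m} \cdot
       \sqrt{\sum_m 1/v_m}, $$

with a two-sided normal p-value. The pseudocounts ($+0.5$ on the count,
$+1$ on the depth) keep $y$ away from the degenerate 0/1 boundary in the
depth-1 regime that the pairing rule admits.

DMCs are sites with $p < 0.001$, with no multiple-testing correction by
default: the threshold is the one printed inside the region rule, and an
optional Benjamini–Hochberg mode is a flag. A sign-flip permutation test
is kept in the test suite as the independent oracle: over simulated sites
spanning the study's depth range the two tests' p-value rankings agree
(rank correlation > 0.9), and the Wald test's type-I error at
$\alpha = 0.001$ is nominal at depth 30 and across depths 10–40.

### Trend classification

Each called DMC is classified from the raw per-male ratio deltas
(treated − fresh): hypermethylated if strictly more than half of the
*informative* males (those possessing the paired site) have a positive
delta, hypomethylated if more than half are negative, otherwise
unclassified. Zero deltas dilute the denominator but vote for neither
side. Using informative males, not all 12, as the denominator is a
design decision: a male without the site has no trend to contribute.
The three classes always partition the DMC set.

## Regions

Two rules aggregate DMCs spatially:

* **DMR rule** (stringent): a window of 50 bases anchored at a CpG
  qualifies when it holds ≥ 5 CpGs of which ≥ 75% are DMCs
  ($p < 0.001$); overlapping qualifying windows are merged and the
  counts recomputed over the merged span. Merging is our reporting
  choice — per-anchor windows overlap heavily and merged spans are how
  DMR tools report.
* **Potentially sensitive regions** (empirical): at least two DMCs with
  consecutive spacing ≤ 100 b (the read length). The chaining is
  transitive (single linkage): DMCs at 100, 190 and 280 form one region
  although the outer pair is 180 b apart. The pairwise reading was the
  other defensible interpretation; transitive closure is the natural
  maximal extension and is what the tests' brute-force oracle encodes
  too. A region is "sensitive to" a cryoprotectant when it holds ≥ 2 of
  that comparison's DMCs, and regions are built over the pooled DMCs of
  all cryoprotectants so that shared regions are visible.

Feature annotation is strand-aware and multi-labelling: promoter
(5 kb upstream of the TSS), exon 1, other exons, intron 1, other introns
(ranks in transcription order), downstream (1 kb past the TES). A region
is labelled with *every* feature it overlaps across all genes — no
precedence — and is intergenic only when nothing overlaps. Promoter and
downstream windows are clipped at chromosome edges; no exclusion is
applied when a promoter overlaps another gene's body. Gene models come
from GFF3 via the longest-span transcript of each gene; genes without
exon children fall back to the gene body as a single exon.

## Quality correlation

The per-male DMC burden is the number of called DMCs at which the male is
informative *and* shows a nonzero delta — a cohort-level DMC does not
credit a male that never expressed it. The study never defines "DMC
number" per male precisely; this counting rule is one reconstruction and
the screen takes any burden table, so alternatives (informative-only, or
direction-concordant counts) drop in trivially.

Burden is correlated with each quality metric (membrane-intact %,
high-mitochondria %, motile %, normalised fertilisation %) by Spearman's
rank correlation with midrank ties. The p-value is a permutation one:
complete enumeration of all $n!$ permutations up to $n = 7$, and a
seeded Monte-Carlo sample of 20 000 permutations above that (12!
≈ 4.8×10⁸ makes complete enumeration at the cohort size pointless; the
Monte-Carlo standard error at p ≈ 0.05 is ~0.0015, far below any
decision boundary). Constant vectors — glycerol's all-zero fertilisation
and motility — are flagged degenerate and not tested.

## The synthetic study

The generator emulates the statistical structure the analysis assumes,
with known truth, and its defaults are the study conditions:

| parameter | default | what it encodes |
|---|---|---|
| `n_males`, `conditions` | 12; fresh, DMSO, MeOH, glycerol | the paired design (48 samples) |
| `n_chrom` × `chrom_length` | 2 × 1.5 Mb | toy genome; ~3.7×10⁵ strand-resolved CpG cytosines, ~1.1×10⁵ observable |
| `mspi_density` | 5 /kb | planted CCGG sites; background CpGs come free with random sequence |
| `frag_min`–`frag_max` | 40–220 b | RRBS size selection; retained fragments define observability |
| `p_methylated_site` / `p_unmethylated_site` | 0.86 / 0.12 | the bimodal sperm methylome (>80% of deep cytosines at ratio 1); remainder intermediate, Uniform(0.05, 0.95) |
| `depth_mean`, `depth_size` | 30, 8 | negative-binomial depth; median ≈ 28–29, inside the study's 18–40 range |
| `conversion_rate` | 0.996 | bisulfite conversion; unconverted unmethylated Cs read as methylated: $r' = r + (1-r)(1-c)$ |
| `over_conversion_rate` | 0 | methylated Cs spuriously converted; the study reports only the conversion rate of unmethylated cytosines, so this stays off by default |
| `site_dropout_mean`, `site_dropout_shape1` | 4/9, 0.5 | partial representation (below) |
| `n_dmc_true`, `dmc_effect`, `dmc_concordance` | 300, 0.5, 0.75 | injected DMCs per cryoprotectant |

`calibrate_mixture()` retunes the fully-methylated weight so the analytic
mixture mean hits a requested global mean (86.34% for the fresh-control
reproduction); the intermediate weight stays fixed.

**Partial representation.** Each observable site receives a Beta(0.5,
0.625) sequencing propensity shared across all 48 samples, and each
sample includes the site with that probability. The mean 4/9 reproduces
the per-sample vs pooled representation ratio of the study (~4% of the
genome per sample vs ~9% per condition union) without any alignment
machinery — the absolute 4% is a property of the real genome and real
libraries, so on a toy genome only the ratio is meaningful. The U-shaped
propensity also makes paired cytosines concentrate in many-male sharing
classes, qualitatively like the real sharing histogram; a single Beta
cannot match the real 90%-shared-by-≥6-males figure *and* the
representation ratio simultaneously, and we prioritise the ratio. This
is a documented limitation, not a target.

**DMC injection.** Per cryoprotectant, 300 observable sites get a
direction and a ±0.5 shift of the true ratio, clipped to [0, 1], applied
in a random 9 of 12 males (concordance 0.75). Because ~86% of baseline
sites sit at ratio 1, a blindly sampled "hyper" direction would clip to
a zero effect; when the sampled direction cannot realise the full
effect, the opposite direction is used and *recorded*, so truth tables
always carry the realised direction. A consequence worth knowing: most
injected DMCs end up hypomethylating, which matches the intuition that a
near-saturated methylome can mostly lose methylation.

**What the generator does not emulate:** read-level errors, PCR
duplicates, fragment-level depth correlation (depth is independent
across sites), mapping artefacts, CpG islands or any non-uniform CpG
spatial organisation, and hydroxymethylation (indistinguishable from
methylation in bisulfite data anyway). Passing tests therefore validate
the *inference machinery* under the study's statistical structure, not
robustness to alignment pathology in real libraries.

## Numerical choices

* Ratio-histogram bins are left-closed with the top bin [0.95, 1]
  closed; bin indices are computed as `floor(ratio * 20 + 1e-9)` — the
  tiny guard keeps ratios like 19/20 (not exactly representable in
  binary) in the top bin.
* PCA intersects sites present in every sample (complete case, no
  imputation) and fixes component signs by making the largest-magnitude
  loading positive; low-coverage samples intersect fewer sites, which is
  exactly the behaviour seen in the real ordination.
* Global means are unweighted means of per-cytosine ratios (the cytosine
  is the analysis unit, deep sites do not dominate), by default over
  depth ≥ 10 for consistency with the histogram filter; the filter is a
  flag because the study does not state the one used for its averages.
* Rank tests use midranks for ties; an all-equal comparison returns
  p = 1 rather than NaN.
* The random-number stream is a single seed fanned out to named
  substreams (genome / truth / counts / quality / genes), so re-running
  one stage never perturbs another.

## Problem sizes

The test suite and the acceptance script run the generator at the
default 3 Mb genome (~1.1×10⁵ observable strand-resolved cytosines, 12
males) for the distributional checks, a 10⁴-site null grid for type-I
error, 200 six-male sites for the permutation-oracle comparison, and a
0.4 Mb genome for the power/recovery check (300 injected DMCs, no
dropout, so that what is measured is the test's power rather than
sequencing coverage). These sizes were chosen so every Monte-Carlo band
in the suite is comfortably narrower than the effect it guards.

## Known limitations

* The paired Wald test is a self-contained re-specification in the
  spirit of arcsine-link beta-binomial methods, not a reimplementation
  of any published tool's internals; results on real data will differ in
  detail from pipelines that shrink dispersions across sites.
* The per-male burden definition, the transitive 100-b chaining and the
  informative-male majority denominator are reconstructions of
  under-specified published choices; all three are flags or documented
  single-point decisions.
* With the default dropout model, roughly half of the paired universe
  reaches the 6-male sharing threshold, so recovery of injected DMCs on
  a *default* fixture is coverage-limited (~30%); the power property is
  asserted on dropout-free fixtures where it cleanly exceeds 80%.
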