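---
title: "Shared-haplotype (SPLoSH) diversity analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-haplotype (SPLoSH) diversity analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploshare)
```

## The problem and the statistic

Diversity panels of crop varieties genotyped on dense SNP arrays are
usually summarized marker by marker, treating every SNP as an unlinked
observation. That discards linkage: closely related varieties share long
chromosome stretches, and two varieties that agree at thousands of
scattered SNPs but never over a long contiguous stretch are less related
than marker-wise identity suggests. `haploshare` quantifies relatedness
through *summed potential lengths of shared haplotypes* (SPLoSH), an
identity-by-state proxy for long identity-by-descent sharing that works
directly on unphased diploid calls.

The key observation is that unphased calls can *refute* sharing but never
prove it: at a biallelic SNP the only call pair that excludes a shared
haplotype is the opposite-homozygote pair (AA vs BB). Every other pair —
including anything involving a heterozygote or a missing call — shares at
least one allele. For a pair of samples, each chromosome is scanned for
maximal runs of compatible markers. A run's *potential length* is the
distance between the nearest flanking incompatible markers (the evidence
bounds), falling back to the chromosome's mapped span ends where no flank
exists. Runs whose potential length reaches the threshold (30 cM by
default) are summed over all chromosomes:

$$\mathrm{SPLoSH}(i,j) \;=\; \sum_{\text{chrom } c}\ \sum_{\substack{\text{runs } r \text{ on } c \\ \ell_r \ge t}} \ell_r,
\qquad \ell_r = u_r - l_r,$$

where $l_r$ and $u_r$ are the flanking-incompatible positions (or span
ends) in centimorgans and $t$ is the threshold. The value lies in
$[0, L]$ with $L$ the total map length (sum of per-chromosome spans), and
can be read as a genome fraction via `splosh_percent()`.

Because the bounds are evidence bounds, the statistic is deliberately an
*upper* estimate: on error-free data it dominates the true IBD sharing of
any simulated pair (the `true_shared_length()` oracle), and a
parent–offspring pair — which can never show an opposite homozygote —
attains exactly $L$. Both properties are asserted in the test suite.

## Compatibility conventions

* **Missing calls are compatible** (default). A missing call cannot
  exhibit opposite homozygosity, so it cannot break a run. The flip side
  is that heavy missingness inflates SPLoSH — replacing any call by
  missing can only increase the value (a monotonicity property the tests
  check). For panels with outgroup-like samples missing tens of percent
  of calls, values against those samples should be read as upper bounds,
  or re-run with the strict mode (`missing_breaker_run = k`), which
  treats runs of at least *k* consecutive either-missing markers as
  breakers for sensitivity analysis.
* **A run must contain at least one compatible marker**; the empty
  interval between two adjacent incompatible markers contributes
  nothing. Markers where one sample is missing count as compatible
  anchors — the alternative (requiring a fully genotyped compatible
  marker) would break the missingness-monotonicity above.
* **The threshold is inclusive**: a run of exactly 30 cM counts.
* **Chromosome ends are the extreme mapped marker positions.** The map
  knows nothing about physical chromosome ends, and this convention makes
  "percent of the genetic map" self-contained: $L$ is the sum of mapped
  spans, so a clone pair scores exactly 100%.

The boundary convention (flanking-marker positions, not interval
midpoints and not run-end positions) is the main point of comparison with
other shared-haplotype implementations; midpoint conventions would halve
the inflation at run edges but lose the clean dominance guarantee.

## Quality control

Four marker-level filters are applied as independent predicates, each
tagging every marker it fails (no short-circuiting), so attrition
reporting is order-independent:

| rule | drops markers that… | default |
|------|---------------------|---------|
| `MISSING_RATE` | have strictly more than `max_missing_rate` missing calls | 0.02 |
| `NO_TWO_HOM` | lack one of the two homozygote classes among non-missing calls | on |
| `MONOMORPHIC` | show one identical call across all samples | on |
| `NULL_ALLELE` | have Norm R intensity spread above `normr_spread_threshold` | 0.09 |

Two operationalizations deserve a note. "Two homozygous groups" is
assessed at call level (both `HOM_A` and `HOM_B` observed at least once)
rather than at intensity-cluster level, which would require re-clustering
raw intensities — out of scope here. And "Norm R spread" is not a
uniquely defined statistic; the standard deviation of the non-missing
Norm R values per marker is used by default (`normr_statistic = "sd"`),
with the interquartile range selectable. When no intensity table is
supplied the rule is skipped and flagged as not evaluated. Sample-level
QC is deliberately absent: the filters are marker filters, and samples
with heavy missingness are kept (and reported) rather than dropped.

## Ordination and downstream outputs

All three dataset views — the QC-filtered SNP table, its map-anchored
subset, and the SPLoSH matrix — go through the same path: a samples ×
samples data matrix (Euclidean distances between dosage profiles for the
SNP views; the sharing-profile grid itself for SPLoSH), completion of the
undefined self-comparison cells, optional column standardization, then
PCA. Treating each sample's row of SPLoSH values as its feature profile
(rather than converting SPLoSH directly into a dissimilarity) keeps the
procedure uniform across views; the direct complement distance
$L - \mathrm{SPLoSH}$ is available as `splosh_distance = "complement"`.

Self-cells are imputed analytically by default — a sample shares its
whole genome with itself, so the SPLoSH diagonal is $L$ and a distance
diagonal is 0. The alternative `iterative_pca` method is a low-rank EM
completion (truncated-SVD reconstruction of the missing cells, rank 2,
convergence when imputed values move < 1e-6, capped at 1000 iterations)
for cases where off-diagonal cells are missing too.

Scaling is on by default for both the SNP and the SPLoSH views, one
switch for all analyses; zero-variance columns are dropped with a
message since they cannot be standardized. PCA component signs are fixed
by making each component's largest-magnitude loading positive, so runs
are comparable across platforms. Trees come from neighbor-joining
(`ape::nj`) with negative branches clamped to zero and the deficit moved
to the sister branch; admixture-type analyses (STRUCTURE), split
networks and Bayesian trees are *not* reimplemented — the package writes
the STRUCTURE, PHYLIP and NEXUS inputs those published tools consume.

## The pedigree simulator

Real kale-panel genotypes of this kind are typically unpublished, so
validation rests on a simulator that emulates the statistical structure
the analysis assumes, with truth recorded:

* **Founders** belong to subpopulations; each subpopulation draws a
  per-marker allele-B frequency from its own law (Beta($\alpha$, $\beta$)
  or fixed $p$), and founder haplotypes are Bernoulli draws from it.
* **Meiosis** follows Haldane's no-interference model: crossover counts
  Poisson(length/100), positions uniform, starting haplotype a fair
  coin. Crossover interference is out of scope; Haldane is the simplest
  defensible default and matches the cM→Morgan reading of the map.
* **Children** are defined by an explicit pedigree (crosses, selfing,
  clones); every sample carries two founder-origin mosaics per
  chromosome, recorded before corruption, from which true IBD segments
  for any pair are derived by interval overlay.
* **Corruption**: symmetric call-replacement error (probability
  `error_rate`, uniformly among the two other calls) exercises the
  statistic's sensitivity to spurious opposite homozygotes without
  modelling intensity space; missingness is per-call with per-sample
  overrides for outgroup-like samples.

Default conditions emulate a 72-variety panel on a ~1205 cM map: 19
chromosomes × 63.4 cM, 2.2 markers/cM (~2700 markers), three divergent
subpopulations of 24 founders (Beta(0.4, 0.4) frequencies, i.e. strongly
drifted), 1% missing calls, no genotyping error. A single integer seed
drives everything through fixed substreams (founders: `seed`; meiosis:
`seed + 1`; corruption: `seed + 2`), making outputs byte-reproducible.

What the simulator does **not** emulate: linkage disequilibrium within
founder populations (founder alleles are drawn independently per marker,
so unrelated-pair sharing is lower than in a real breeding pool),
ascertainment bias of array SNPs, clustered missingness, and intensity
space (Norm R tables must be supplied or synthesized separately).
Passing validation therefore demonstrates correctness of the segment
arithmetic and the expected ordering/dominance behaviour of the
statistic — not calibration against any particular real panel.

## Validation design and problem sizes

The test suite validates the scanner against an independent brute-force
oracle (nearest-incompatible scan per compatible marker) on hundreds of
random instances up to 500 markers, and checks on a 10 × 100 cM map at 1
marker/cM (50 families per relationship class): parent–offspring pairs
attain $L$ exactly; estimates dominate true IBD for sib pairs on clean
data (with the violation rate under 1% genotyping error reported, not
asserted); mean values order relationship classes by relatedness; and
k-means on the first two PCs of SPLoSH profiles recovers three simulated
subpopulations (36 samples). One caveat surfaced by this design: on
clean, complete data a clone pair and a parent–offspring pair both score
exactly $L$ — saturation at the map length is a theorem, not a bug — so
clones are *not* strictly separable from parent–offspring pairs by this
statistic, and genotyping error does not separate them either (both
classes acquire opposite homozygotes at the same first-order rate,
$e/2$ per hom-carrying marker at MAF 0.5). Pedigree reconstruction
methods that need that distinction must bring additional information.

## Known limitations

* Potential lengths are upper bounds by construction; absolute values
  are most meaningful comparatively (between pairs on the same map) or
  as percentages of $L$.
* Sparse marker coverage widens the evidence bounds and inflates values;
  the map-anchored marker density, not the array density, is the
  operative resolution.
* Heavy missingness inflates values (see the strict mode above).
* The statistic is symmetric IBS-compatibility, not probabilistic IBD:
  no genotyping-error model, no frequency weighting of sharing, no
  phasing. Pairs from small founder pools share long runs by chance.
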