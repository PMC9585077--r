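---
title: "Methods: mask-and-impute benchmarking of SNP arrays"
author: "snpArrayEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask-and-impute benchmarking of SNP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpArrayEval)
```

# The evaluation design

An array is only as good as the imputation it supports. `snpArrayEval`
quantifies this with a cross-validation design on a phased panel that acts
as the whole-genome gold standard. The cohort is split into *k* batches
(default `k = 10`) balanced within each population; in each turn one batch
is the test set, the rest the reference panel. Test genotypes are reduced to
the array's manifest positions with phase removed — what the array would
actually deliver — and imputed back. After all folds, every sample has been
imputed exactly once, and the merged dosages are scored per population
against the panel's true genotypes.

Stratified folding deals each population's shuffled samples evenly across
folds; each population's remainder goes to the folds with the smallest
current load (ties by fold index). This keeps fold sizes within one sample
of each other both overall and within every population, for any population
composition: a 2,504-sample cohort with populations of 504/503/489/661/347
yields four batches of 251 and six of 250; a single 1,008-sample population
yields eight of 101 and two of 100.

Pseudo-array extraction matches manifest entries to the panel by chromosome
and position (1-based, as in VCF). When a matched record's ref/alt alleles
disagree with the manifest's, the site is skipped and logged rather than
strand-flipped: real manifests carry strand ambiguities that silent flipping
would paper over, and an auditable skip list is cheap. Multiallelic records
are excluded when the panel is loaded, so everything downstream is
biallelic by construction.

# The imputation model

Imputation uses a diploid Li–Stephens haplotype-copying hidden Markov model.
The hidden state at a typed site is an **ordered pair of reference
haplotypes** (state space K²); the target's two chromosomes are each
modelled as an imperfect mosaic of the K reference haplotypes. Working on
genotypes directly means no separate phasing stage and no phasing-error
interactions to reason about; the price is the K² state space, handled by a
reference cap (below).

* **Transitions.** Between adjacent typed sites separated by `gap` bp, each
  state haplotype independently switches with probability
  `1 − exp(−θ · gap)`, destination uniform over the K haplotypes (self
  included) — the classic haplotype-copying transition. Applying it to a
  K×K table costs O(K²) because it factorises into row sums, column sums
  and a total.
* **Emissions.** An observed genotype g ∈ {0,1,2} at a typed site is the sum
  of two allele reads, each matching its state haplotype's allele with
  probability 1 − ε.
* **Recursions.** Forward and backward passes run on the linear scale with
  per-site rescaling (each site's forward mass is normalised to 1; the
  scaling factors are kept for diagnostics). Linear-scale with rescaling is
  materially faster than log-space and exact up to the `numericalFloor`
  guard (default 1e-300) that prevents division by a vanished scale.
* **Untyped sites.** The haplotype posterior at an untyped site is taken
  from the two flanking typed sites, linearly interpolated by physical
  distance (sites before the first or after the last typed site use the
  nearest one). The dosage is the posterior-expected ALT count smoothed by
  ε: `Σ_k m_k (a_k (1 − 2ε) + ε)`, with `m_k` the interpolated haplotype
  marginal (summing to 2). This is deterministic, cheap, and standard
  practice; it ignores recombination *between* the flanks, which is the
  usual approximation at array-scale marker spacing.

Typed sites pass the observed genotype through unchanged (flagged `typed`);
a typed site with a missing genotype in some sample is treated as untyped
for that sample. A target with no typed genotypes at all falls back to the
reference allele-frequency dosage 2·AF with a warning. The whole computation
is deterministic given its inputs; the forward–backward result is checked in
the test suite against exhaustive enumeration of all K^(2T) state paths on
small instances, to 1e-9.

Tunable parameters (all exposed, none hard-coded):

| parameter | default | units / meaning |
|---|---|---|
| `switchRate` (θ) | 1e-8 | per-bp switch intensity; set it near the panel's recombination scale |
| `errorRate` (ε) | 1e-3 | per-allele mismatch probability; also smooths dosages away from 0/2 |
| `kCap` | 64 | max reference haplotypes; larger panels are subsampled (seeded) |
| `numericalFloor` | 1e-300 | smallest admissible per-site scaling factor |

The O(M·K²) cost makes `kCap` the main speed dial: 64 haplotypes keep a
5,000-site, 400-sample tenfold run in the minutes range on one CPU while
leaving imputation quality near its plateau for panels whose LD comes from
a few dozen founder lineages. For real panels with deeper haplotype
diversity a larger cap (and correspondingly longer runtime) is appropriate.
The external-tool adapter preserves the module boundary for users who want
SHAPEIT/Minimac-class engines instead: it writes the pseudo-array and
reference VCFs, runs a user-templated command, and parses the returned `DS`
field.

# Scoring

**Imputation r²** is the squared Pearson correlation between imputed dosage
and true genotype across the evaluated samples, per SNP. It is computed per
population over the *merged* folds; MAF and minor-allele count likewise come
from the truth genotypes of the full evaluated population — the frequency
source is a documented choice, made because results are reported per
population. Sites are stratified into MAF bins (0–0.01], (0.01–0.05],
(0.05–0.5] (left-open, right-closed) plus the union bin (0.01–0.5] that is
the usual GWAS/PGS frequency cutoff. Exclusions, each with a recorded
reason: multiallelic records (everywhere), directly typed sites (the metric
evaluates imputation; flag-controlled), monomorphic sites, rare-bin sites
with minor-allele count < 2, and sites whose dosage vector is (numerically)
constant, where Pearson r is undefined — reported as excluded rather than
as r² = 0, because degeneracy is not error. A variance below 1e-10 counts
as constant: genuine dosage variation sits many orders of magnitude above
that, and the guard stops catastrophic cancellation from minting noise r²
values. **Coverage** is the fraction of scored SNPs with r² ≥ 0.8.
Aggregation reports the per-chromosome means' mean and sample SD (n − 1;
a single chromosome reports SD 0 with a `singleChrom` flag).

**Polygenic scores** follow the pruning-and-thresholding recipe:
`PGS_i(P_T) = Σ_j 1{P_j < P_T} x_ij β̂_j` (strict inequality) over the SNPs
retained by greedy LD clumping — repeatedly take the smallest-p unclumped
variant (ties by chromosome, then position), drop neighbours within 250 kb
whose genotype r² with it reaches 0.1. The threshold grid is
5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.2, 0.3, 0.5, 1.
Clumping is performed once on the truth genotypes of the evaluation cohort
and the same retained set scores both sources, so that score differences
isolate imputation error rather than clump-set drift; a per-source re-clump
is available by calling `clumpVariants()` per source. `x_ij` is the
expected dosage for the imputed source and the integer allele count for the
truth source (a hard-call mode rounds dosages first). Summary statistics
are harmonised by position with allele checking: exact match keeps β,
ref/alt-swapped match negates it, and A/T–C/G pairs needing a swap are
dropped as strand-ambiguous.

Concordance is reported two ways: per-threshold Pearson correlation between
array-derived and truth-derived scores (thresholds where either score
vector is constant are flagged and left out of the mean/SD), and ADPR — the
per-sample absolute difference in percentile rank, with percentile
`100 (rank − 0.5)/N` using mid-ranks for ties. That convention is symmetric
(percentiles average 50 exactly) and tie-stable; rank-based conventions
differ across tools, so it is configurable in effect by supplying
pre-ranked scores.

# The synthetic-data generator

The generator exists so the pipeline is testable end-to-end without
external data; it emulates the *features the pipeline is sensitive to*, not
human demography.

* **Haplotypes** are recombination mosaics of `nFounders` (default 24)
  founder haplotypes: between adjacent sites a copying switch occurs with
  probability `recombRate · gap` and each copied allele flips with
  probability `mutationRate`. Fewer founders mean stronger LD; the defaults
  (24 founders, 1e-6 switches/bp on a 10 Mb chromosome, flip rate 0.002)
  give distance-decaying LD on the ~1 Mb scale and imputation accuracies in
  the realistic range at array-like densities.
* **Site frequencies** are log-uniform between `mafFloor` (default 0.01)
  and 0.5 — an approximation to the 1/f neutral spectrum — with random
  major/minor orientation; together with founder sampling noise and the
  mutation flips this populates all three MAF bins, including several
  hundred rare-bin sites per 2,000 simulated variants.
* **Population structure** comes from per-population Dirichlet copying
  weights over the founders (`popDiff` is the concentration; default 3
  gives mild differentiation). This captures "different populations prefer
  different haplotypes", which is what drives population effects in
  imputation — not drift, admixture or selection.
* **Summary statistics** assign effects rather than run a GWAS, because the
  pipeline consumes summary statistics, it does not produce them:
  `nCausal` variants draw β ~ N(0, `betaVariance`) and p uniform below
  5e-8; the rest draw small noise effects (sd = √`betaVariance`/20) and p
  uniform above 5e-8, so "exactly n genome-wide-significant variants" holds
  by construction.
* **Manifests** subsample panel variants uniformly or MAF-weighted (the
  latter emulating common-variant tag selection). Real manifest design
  optimises tag-SNP LD coverage; these strategies are explicit stand-ins,
  not reconstructions.

All randomness flows from one explicit seed per operation; composite stages
derive child seeds from the master seed with fixed string tags, so a single
integer reproduces an entire run. Variant positions are drawn uniformly
without replacement and sorted, 1-based.

What passing tests on this generator do **not** show: robustness to
genotyping error and missingness (not simulated), sequencing artefacts,
X/Y/MT inheritance (autosomal model only), realistic recombination hotspot
structure, or the haplotype diversity of real cohorts (a few dozen founders
versus thousands of lineages). Conclusions about *relative* array
performance transfer better than absolute r² levels.

# The standard study and problem sizes

`densitySweepStudy()` is the package's reference experiment: a
two-population panel of 200 diploid samples per population and 5,000
variants, MAF-weighted manifests at densities 0.02 / 0.1 / 0.5, one trait
with 50 causal variants, tenfold evaluation, θ matched to the generator's
recombination rate (1e-6/bp), ε = 1e-3, `kCap` = 64. These sizes were
chosen as the smallest at which the density effect is unambiguous: at seed
1 the pooled mean imputation r² in the union bin rises 0.358 → 0.758 →
0.790 across densities, PGS correlation 0.597 → 0.877 → 0.978, and mean
ADPR falls 19.9 → 10.4 → 3.6 — the array-size effect the pipeline is built
to expose, at desk scale. `scripts/acceptance.R` recomputes exactly these
quantities (plus the combinatorial fold sizes and the oracle checks) for
any seed.

# Known limitations

* The built-in imputer has no state-space compression; `kCap` subsampling
  trades accuracy for speed on large references, and results depend
  (seeded, reproducibly) on the subsample.
* Flank interpolation at untyped sites ignores double recombination within
  an interval; dense reference sites between sparse typed sites inherit the
  flanks' posterior.
* Clumping uses the evaluation cohort itself as the LD reference — the
  usual choice when no external reference is supplied, but it couples the
  clump set to cohort composition.
* ADPR is rank-based and therefore insensitive to calibration shifts that
  preserve order; it answers "would this sample's standing change?", not
  "is the score unbiased?".
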