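# snpArrayEval

Genotyping SNP arrays measure a few hundred thousand to a few million "tag
SNPs" and rely on genotype imputation to recover the rest of the genome.
How well a given array supports downstream work — genome-wide association,
polygenic scores (PGS), risk stratification — therefore depends on how well
its tag-SNP set drives imputation in the population of interest.
`snpArrayEval` benchmarks arrays by **mask-and-impute cross-validation**
against a phased whole-genome panel treated as the gold standard:

1. Samples are split into *k* batches (default 10), balanced within each
   population (**stratified folds**).
2. For each fold, the panel genotypes are reduced to the array's manifest
   positions and stripped of phase (**pseudo-array data**), then imputed
   back against the phased haplotypes of the remaining samples.
3. Imputed folds are merged and scored per population:
   * **imputation r²** — per-SNP squared Pearson correlation between
     imputed dosage and the true genotype across samples;
   * **imputation coverage** — the proportion of scored SNPs with
     r² ≥ 0.8, stratified into MAF bins (0–0.01], (0.01–0.05], (0.05–0.5]
     and the union bin (0.01–0.5], with multiallelic sites excluded and
     allele-count < 2 sites excluded in the rare bin;
   * **P+T polygenic scores** — `PGS_i(P_T) = Σ_j 1{P_j < P_T} · x_ij · β̂_j`
     over an LD-clumped SNP set (250 kb window, r² 0.1) and a 12-value
     p-value threshold grid, compared between the imputed and the
     whole-genome source by Pearson correlation and by the **absolute
     difference of percentile ranking (ADPR)**.

The imputation engine is a diploid **Li–Stephens haplotype-copying HMM**
(state = ordered pair of reference haplotypes, switch intensity θ per bp,
per-allele mismatch ε), run by rescaled forward–backward recursions directly
on unphased genotypes, so no separate phasing stage is needed. An adapter
contract (`externalImputerAdapter()`) lets users plug in external
phasing/imputation tools instead.

A synthetic-data module (founder-mosaic haplotype simulator, manifest
sampler, sparse-causal GWAS summary statistics) makes the whole pipeline
runnable and testable with no external downloads.

## Worked example

```r
library(snpArrayEval)

panel <- simulatePanel(simConfig(nSamples = 50, nVariants = 2000, seed = 11))
manifests <- list(
  sparse = deriveManifest(panel, 0.02, "maf_weighted", seed = 21),
  medium = deriveManifest(panel, 0.10, "maf_weighted", seed = 22),
  dense  = deriveManifest(panel, 0.50, "maf_weighted", seed = 23)
)
traits <- list(trait1 = simulateSummaryStats(panel, effectModel(nCausal = 40, seed = 31)))

cfg <- runConfig(panel, manifests, traits, k = 5,
                 hmm = hmmParams(switchRate = 1e-6), seed = 99)
res <- runEvaluation(cfg)
tabs <- reportTables(res)
subset(tabs$imputation, bin == "(0.01-0.5]")[, c("array", "population", "meanR2", "meanCoverage")]
#>     array population    meanR2 meanCoverage
#> 3  sparse       POP1 0.1432006 0.0014534884
#> 4  sparse       POP2 0.1411168 0.0007153076
#> 9  medium       POP1 0.5868257 0.1862182116
#> 10 medium       POP2 0.5849538 0.1858407080
#> 15  dense       POP1 0.7527119 0.5450450450
#> 16  dense       POP2 0.7486002 0.5347826087
tabs$pgs[, c("array", "population", "corMean", "adprMean")]
#>    array population   corMean  adprMean
#> 1 sparse       POP1 0.1118276 32.386667
#> 2 sparse       POP2 0.5260569 28.246667
#> 3 medium       POP1 0.7162935 16.920000
#> 4 medium       POP2 0.9054412 10.306667
#> 5  dense       POP1 0.9790354  3.360000
#> 6  dense       POP2 0.9902838  2.726667
```

Reading the output: `meanR2` is the per-chromosome mean imputation r² in the
union MAF bin (0.01–0.5] and `meanCoverage` the fraction of those SNPs with
r² ≥ 0.8 — both rise steeply with manifest density, the array-size effect
this pipeline is built to expose. `corMean` is the Pearson correlation
between array-derived and whole-genome P+T scores averaged over the
12-threshold grid, and `adprMean` the mean absolute percentile-rank shift a
sample would experience if scored from the array instead of whole-genome
data (in percentile points).

Real data enter the same way: `readPanelVcf()` (phased VCF + population
map), `readManifest()` (chrom/pos/ref/alt TSV), `readSummaryStats()`
(chrom/pos/effect_allele/other_allele/beta/p TSV). A thin CLI wrapper with
`simulate` and `evaluate` verbs lives in `inst/scripts/snparrayeval`.

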