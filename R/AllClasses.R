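#' @import methods
NULL

#' Simulation configuration for synthetic haplotype panels
#'
#' Parameters of the founder-mosaic panel simulator. Haplotypes are built as
#' recombination mosaics of a small set of founder haplotypes: between
#' adjacent variants a copying switch occurs with probability
#' `recombRate * gap` (capped at 1), and each copied allele is flipped with
#' probability `mutationRate`. Population differentiation is induced by
#' giving each population its own Dirichlet-distributed founder copying
#' weights (`popDiff` is the Dirichlet concentration; smaller values give
#' stronger differentiation).
#'
#' @slot nSamples integer, diploid samples per population.
#' @slot nVariants integer, number of biallelic variants.
#' @slot nFounders integer, number of founder haplotypes (>= 2).
#' @slot chromLength integer, chromosome length in bp; positions are drawn
#'   uniformly without replacement in `[1, chromLength]` and sorted (1-based).
#' @slot recombRate numeric, per-bp switch probability of the copying mosaic.
#' @slot mutationRate numeric, per-site allele flip probability.
#' @slot populations character, population labels.
#' @slot popDiff numeric, Dirichlet concentration of per-population founder
#'   weights.
#' @slot mafFloor numeric, lower bound of the simulated site-frequency
#'   distribution (minor-allele scale).
#' @slot chrom character, chromosome name used in emitted variant tables.
#' @slot seed integer, master seed of the simulation.
#' @export
setClass("SimConfig", representation(
  nSamples = "integer", nVariants = "integer", nFounders = "integer",
  chromLength = "integer", recombRate = "numeric", mutationRate = "numeric",
  populations = "character", popDiff = "numeric", mafFloor = "numeric",
  chrom = "character", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(
    recombRate = object@recombRate, mutationRate = object@mutationRate,
    mafFloor = object@mafFloor
  )
  if (any(rates < 0 | rates > 1)) {
    msg <- c(msg, "recombRate, mutationRate and mafFloor must lie in [0, 1]")
  }
  if (object@nFounders < 2L) msg <- c(msg, "nFounders must be >= 2")
  if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
  if (object@chromLength < object@nVariants) {
    msg <- c(msg, "chromLength must admit nVariants distinct positions")
  }
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (length(object@populations) < 1L ||
    anyDuplicated(object@populations) > 0L) {
    msg <- c(msg, "populations must be a non-empty set of unique labels")
  }
  if (object@popDiff <= 0) msg <- c(msg, "popDiff must be > 0")
  if (object@mafFloor <= 0 || object@mafFloor > 0.5) {
    msg <- c(msg, "mafFloor must lie in (0, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' @param nSamples,nVariants,nFounders,chromLength,recombRate,mutationRate,populations,popDiff,mafFloor,chrom,seed
#'   see the corresponding slots.
#' @return `simConfig()` returns a validated [SimConfig-class] object.
#' @rdname SimConfig-class
#' @export
simConfig <- function(nSamples = 200L, nVariants = 5000L, nFounders = 24L,
                      chromLength = 1e7, recombRate = 1e-6,
                      mutationRate = 0.002,
                      populations = c("POP1", "POP2"), popDiff = 3,
                      mafFloor = 0.01, chrom = "1", seed = 1L) {
  new("SimConfig",
    nSamples = as.integer(nSamples), nVariants = as.integer(nVariants),
    nFounders = as.integer(nFounders), chromLength = as.integer(chromLength),
    recombRate = as.numeric(recombRate),
    mutationRate = as.numeric(mutationRate),
    populations = as.character(populations), popDiff = as.numeric(popDiff),
    mafFloor = as.numeric(mafFloor), chrom = as.character(chrom),
    seed = as.integer(seed)
  )
}

#' Effect model for synthetic GWAS summary statistics
#'
#' A sparse-causal effect model: `nCausal` variants receive effect sizes drawn
#' from N(0, `betaVariance`) and p-values below the genome-wide significance
#' threshold 5e-8; all remaining variants receive small zero-centred noise
#' effects (sd = sqrt(betaVariance)/20) and p-values uniform above the
#' threshold.
#'
#' @slot nCausal integer, number of causal variants.
#' @slot betaVariance numeric, variance of causal effect sizes.
#' @slot seed integer.
#' @export
setClass("EffectModel", representation(
  nCausal = "integer", betaVariance = "numeric", seed = "integer"
))

setValidity("EffectModel", function(object) {
  msg <- character()
  if (object@nCausal < 0L) msg <- c(msg, "nCausal must be >= 0")
  if (object@betaVariance <= 0) msg <- c(msg, "betaVariance must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param nCausal,betaVariance,seed see the corresponding slots.
#' @return `effectModel()` returns a validated [EffectModel-class] object.
#' @rdname EffectModel-class
#' @export
effectModel <- function(nCausal = 50L, betaVariance = 0.1, seed = 1L) {
  new("EffectModel",
    nCausal = as.integer(nCausal), betaVariance = as.numeric(betaVariance),
    seed = as.integer(seed)
  )
}

#' Phased haplotype panel
#'
#' Phased biallelic alleles for N diploid samples at M variants, with
#' population labels. This is the ground-truth (WGS stand-in) container of the
#' evaluation pipeline. Alleles are stored as an M x 2N integer matrix in
#' {0,1}; columns are haplotypes named `<sample>_1`, `<sample>_2`.
#'
#' @slot variants a [GenomicRanges::GRanges] of width-1 positions (1-based)
#'   with metadata columns `ref` and `alt`.
#' @slot haplotypes integer matrix, variants x haplotypes, entries in {0,1}.
#' @slot sampleIds character, N diploid sample identifiers.
#' @slot populations character, population label per sample (named by sample).
#' @export
setClass("HaplotypePanel", representation(
  variants = "GRanges", haplotypes = "matrix", sampleIds = "character",
  populations = "character"
))

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  M <- length(object@variants)
  N <- length(object@sampleIds)
  if (nrow(object@haplotypes) != M) {
    msg <- c(msg, "haplotype rows must match number of variants")
  }
  if (ncol(object@haplotypes) != 2L * N) {
    msg <- c(msg, "haplotype columns must be 2 x number of samples")
  }
  if (!all(object@haplotypes %in% c(0L, 1L))) {
    msg <- c(msg, "haplotype alleles must be 0/1")
  }
  if (anyDuplicated(object@sampleIds) > 0L) {
    msg <- c(msg, "sample ids must be unique")
  }
  if (!identical(names(object@populations), object@sampleIds)) {
    msg <- c(msg, "populations must be named by sampleIds, in order")
  }
  pos <- GenomicRanges::start(object@variants)
  chr <- as.character(GenomicRanges::seqnames(object@variants))
  if (M > 1L && any(diff(pos) <= 0 & chr[-1L] == chr[-M])) {
    msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

newHaplotypePanel <- function(variants, haplotypes, sampleIds, populations) {
  colnames(haplotypes) <- paste0(rep(sampleIds, each = 2L), "_", 1:2)
  new("HaplotypePanel",
    variants = variants, haplotypes = haplotypes,
    sampleIds = as.character(sampleIds),
    populations = setNames(as.character(populations), sampleIds)
  )
}

#' Array manifest: the tag-SNP positions an array genotypes
#'
#' @slot sites a [GenomicRanges::GRanges] of width-1 positions with metadata
#'   columns `ref` and `alt` (may be `NA` when the manifest carries positions
#'   only).
#' @export
setClass("ArrayManifest", representation(sites = "GRanges"))

setValidity("ArrayManifest", function(object) {
  if (anyDuplicated(posKey(
    as.character(GenomicRanges::seqnames(object@sites)),
    GenomicRanges::start(object@sites)
  ))) {
    return("manifest positions must be unique")
  }
  TRUE
})

#' GWAS summary statistics
#'
#' Per-variant effect allele, marginal effect size and p-value, the inputs of
#' pruning-and-thresholding polygenic scores.
#'
#' @slot stats data.frame with columns chrom, pos, effect_allele,
#'   other_allele, beta, p (and optionally causal).
#' @export
setClass("SummaryStats", representation(stats = "data.frame"))

setValidity("SummaryStats", function(object) {
  st <- object@stats
  need <- c("chrom", "pos", "effect_allele", "other_allele", "beta", "p")
  if (!all(need %in% names(st))) {
    return(paste("stats must contain columns:", paste(need, collapse = ", ")))
  }
  if (any(st$p <= 0 | st$p > 1)) return("p-values must lie in (0, 1]")
  if (anyDuplicated(posKey(st$chrom, st$pos)) > 0L) {
    return("variant keys (chrom:pos) must be unique")
  }
  ok <- c("A", "C", "G", "T")
  if (!all(st$effect_allele %in% ok) || !all(st$other_allele %in% ok)) {
    return("alleles must be one of A, C, G, T")
  }
  TRUE
})

#' Stratified cross-validation fold plan
#'
#' @slot k integer, number of folds.
#' @slot assignment integer fold index per sample, named by sample.
#' @slot populations character population label per sample, named by sample.
#' @export
setClass("FoldPlan", representation(
  k = "integer", assignment = "integer", populations = "character"
))

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (!identical(names(object@assignment), names(object@populations))) {
    msg <- c(msg, "assignment and populations must be named identically")
  }
  if (any(object@assignment < 1L | object@assignment > object@k)) {
    msg <- c(msg, "fold indices must lie in 1..k")
  }
  sizes <- tabulate(object@assignment, nbins = object@k)
  if (diff(range(sizes)) > 1L) {
    msg <- c(msg, "overall fold sizes must differ by at most 1")
  }
  for (p in unique(object@populations)) {
    ps <- tabulate(object@assignment[object@populations == p],
      nbins = object@k
    )
    if (diff(range(ps)) > 1L) {
      msg <- c(msg, sprintf(
        "fold sizes within population %s must differ by at most 1", p
      ))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pseudo-array genotypes
#'
#' Unphased ALT-allele counts extracted from a phased panel at the positions
#' of an array manifest — what the array "would have genotyped", with phase
#' discarded.
#'
#' @slot variants [GenomicRanges::GRanges] of typed positions (manifest
#'   intersected with the panel), with `ref`/`alt` metadata columns.
#' @slot genotypes integer matrix, variants x samples, entries in {0,1,2} or
#'   NA.
#' @slot sampleIds character.
#' @slot skipped data.frame of manifest entries not extracted, with columns
#'   chrom, pos, reason ("absent_from_panel" or "allele_mismatch").
#' @export
setClass("PseudoArrayGenotypes", representation(
  variants = "GRanges", genotypes = "matrix", sampleIds = "character",
  skipped = "data.frame"
))

setValidity("PseudoArrayGenotypes", function(object) {
  msg <- character()
  if (nrow(object@genotypes) != length(object@variants)) {
    msg <- c(msg, "genotype rows must match variants")
  }
  if (ncol(object@genotypes) != length(object@sampleIds)) {
    msg <- c(msg, "genotype columns must match samples")
  }
  g <- object@genotypes
  if (!all(g[!is.na(g)] %in% 0:2)) {
    msg <- c(msg, "genotypes must be ALT-allele counts in {0,1,2}")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of the diploid Li-Stephens imputation HMM
#'
#' The hidden state is an ordered pair of reference haplotypes; between
#' adjacent typed sites each haplotype switches with probability
#' `1 - exp(-switchRate * gap)`, the destination uniform over the K reference
#' haplotypes (including the current one); emissions allow a per-allele
#' mismatch probability `errorRate`.
#'
#' @slot switchRate numeric, per-bp haplotype switch intensity (theta).
#' @slot errorRate numeric, per-allele mismatch emission probability
#'   (epsilon), in (0, 0.5).
#' @slot kCap integer, maximum number of reference haplotypes used per
#'   imputation; larger references are subsampled (seeded). Controls the
#'   O(M * K^2) cost.
#' @slot numericalFloor numeric, smallest admissible per-site scaling factor
#'   of the rescaled recursions.
#' @export
setClass("HMMParams", representation(
  switchRate = "numeric", errorRate = "numeric", kCap = "integer",
  numericalFloor = "numeric"
))

setValidity("HMMParams", function(object) {
  msg <- character()
  if (object@errorRate <= 0 || object@errorRate >= 0.5) {
    msg <- c(msg, "errorRate must lie in (0, 0.5)")
  }
  if (object@switchRate < 0) msg <- c(msg, "switchRate must be >= 0")
  if (object@kCap < 2L) msg <- c(msg, "kCap must be >= 2")
  if (object@numericalFloor <= 0) msg <- c(msg, "numericalFloor must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param switchRate,errorRate,kCap,numericalFloor see the corresponding
#'   slots.
#' @return `hmmParams()` returns a validated [HMMParams-class] object.
#' @rdname HMMParams-class
#' @export
hmmParams <- function(switchRate = 1e-8, errorRate = 1e-3, kCap = 64L,
                      numericalFloor = 1e-300) {
  new("HMMParams",
    switchRate = as.numeric(switchRate), errorRate = as.numeric(errorRate),
    kCap = as.integer(kCap), numericalFloor = as.numeric(numericalFloor)
  )
}

#' Imputed dosage matrix
#'
#' Expected ALT-allele dosages in `[0, 2]`, variants x samples. Typed sites
#' carry the observed integer genotype and are flagged `typed`.
#'
#' @slot variants [GenomicRanges::GRanges] with `ref`/`alt` metadata columns.
#' @slot dosages numeric matrix, variants x samples, values in `[0, 2]`.
#' @slot typed logical per variant: genotyped directly (TRUE) or imputed.
#' @slot sampleIds character.
#' @export
setClass("DosageMatrix", representation(
  variants = "GRanges", dosages = "matrix", typed = "logical",
  sampleIds = "character"
))

setValidity("DosageMatrix", function(object) {
  msg <- character()
  if (nrow(object@dosages) != length(object@variants)) {
    msg <- c(msg, "dosage rows must match variants")
  }
  if (ncol(object@dosages) != length(object@sampleIds)) {
    msg <- c(msg, "dosage columns must match samples")
  }
  if (length(object@typed) != length(object@variants)) {
    msg <- c(msg, "typed flag must have one entry per variant")
  }
  d <- object@dosages
  if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE)) {
    msg <- c(msg, "dosages must lie in [0, 2]")
  }
  if (length(msg)) msg else TRUE
})

#' Clumping specification for P+T polygenic scores
#'
#' @slot windowBp numeric, clumping window (bp) around each index variant.
#' @slot r2Threshold numeric, genotype-correlation-squared threshold above
#'   which a neighbouring variant is removed.
#' @export
setClass("ClumpSpec", representation(
  windowBp = "numeric", r2Threshold = "numeric"
))

setValidity("ClumpSpec", function(object) {
  msg <- character()
  if (object@windowBp <= 0) msg <- c(msg, "windowBp must be > 0")
  if (object@r2Threshold < 0 || object@r2Threshold > 1) {
    msg <- c(msg, "r2Threshold must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @param windowBp,r2Threshold see the corresponding slots.
#' @return `clumpSpec()` returns a validated [ClumpSpec-class] object.
#' @rdname ClumpSpec-class
#' @export
clumpSpec <- function(windowBp = 250000, r2Threshold = 0.1) {
  new("ClumpSpec",
    windowBp = as.numeric(windowBp), r2Threshold = as.numeric(r2Threshold)
  )
}

#' Imputation metrics report
#'
#' Per-chromosome, per-MAF-bin means of site-wise imputation r-squared and
#' coverage, plus their mean and standard deviation (n - 1) across
#' chromosomes, stratified by population.
#'
#' @slot perChromosome data.frame: population, chrom, bin, nSites, meanR2,
#'   coverage.
#' @slot summary data.frame: population, bin, nChrom, meanR2, sdR2,
#'   meanCoverage, sdCoverage, singleChrom.
#' @export
setClass("MetricsReport", representation(
  perChromosome = "data.frame", summary = "data.frame"
))

#' Polygenic score comparison result
#'
#' P+T scores of one cohort from two genotype sources (array-imputed dosages
#' and WGS truth), with per-threshold Pearson correlation and per-sample
#' absolute difference of percentile ranking (ADPR).
#'
#' @slot arrayScores numeric matrix, samples x thresholds.
#' @slot wgsScores numeric matrix, samples x thresholds.
#' @slot thresholds numeric p-value threshold grid.
#' @slot correlation data.frame: threshold, r, defined.
#' @slot adpr data.frame per threshold x sample: threshold, sample, pctArray,
#'   pctWgs, adpr.
#' @export
setClass("PGSResult", representation(
  arrayScores = "matrix", wgsScores = "matrix", thresholds = "numeric",
  correlation = "data.frame", adpr = "data.frame"
))
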