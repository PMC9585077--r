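#' @importClassesFrom GenomicRanges GRanges
#' @import methods
NULL

#' Accessors for pipeline data objects
#'
#' `variants()` returns the variant coordinates as a
#' [GenomicRanges::GRanges]; `haplotypes()` the phased 0/1 allele matrix;
#' `samples()` the diploid sample identifiers; `populations()` the population
#' label per sample; `genotypes()` the diploid ALT-allele counts (truth
#' genotypes, haplotype-pair sums); `dosages()` the imputed expected
#' ALT-allele dosages; `typed()` the per-variant typed/imputed flag;
#' `variantKeys()` `"chrom:pos"` match keys.
#'
#' @param x a pipeline object ([HaplotypePanel-class],
#'   [PseudoArrayGenotypes-class], [DosageMatrix-class],
#'   [ArrayManifest-class], [FoldPlan-class], [SummaryStats-class]).
#' @param ... passed to methods.
#' @return the component named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x, ...) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x, ...) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("samples", function(x, ...) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("typed", function(x, ...) standardGeneric("typed"))

#' @rdname accessors
#' @export
setGeneric("variantKeys", function(x, ...) standardGeneric("variantKeys"))

#' @rdname accessors
#' @export
setMethod("variants", "HaplotypePanel", function(x, ...) x@variants)

#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x, ...) x@haplotypes)

#' @rdname accessors
#' @export
setMethod("samples", "HaplotypePanel", function(x, ...) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("populations", "HaplotypePanel", function(x, ...) x@populations)

#' @rdname accessors
#' @param subset optional character vector of sample ids.
#' @export
setMethod("genotypes", "HaplotypePanel", function(x, subset = NULL, ...) {
  ids <- if (is.null(subset)) x@sampleIds else as.character(subset)
  if (!all(ids %in% x@sampleIds)) stop("unknown sample id in `subset`")
  h <- x@haplotypes
  g <- h[, paste0(ids, "_1"), drop = FALSE] +
    h[, paste0(ids, "_2"), drop = FALSE]
  colnames(g) <- ids
  rownames(g) <- variantKeys(x)
  g
})

#' @rdname accessors
#' @export
setMethod("variantKeys", "HaplotypePanel", function(x, ...) {
  posKey(
    as.character(GenomicRanges::seqnames(x@variants)),
    GenomicRanges::start(x@variants)
  )
})

#' @rdname accessors
#' @export
setMethod("variants", "ArrayManifest", function(x, ...) x@sites)

#' @rdname accessors
#' @export
setMethod("variantKeys", "ArrayManifest", function(x, ...) {
  posKey(
    as.character(GenomicRanges::seqnames(x@sites)),
    GenomicRanges::start(x@sites)
  )
})

#' @rdname accessors
#' @export
setMethod("variants", "PseudoArrayGenotypes", function(x, ...) x@variants)

#' @rdname accessors
#' @export
setMethod("genotypes", "PseudoArrayGenotypes", function(x, ...) x@genotypes)

#' @rdname accessors
#' @export
setMethod("samples", "PseudoArrayGenotypes", function(x, ...) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("variantKeys", "PseudoArrayGenotypes", function(x, ...) {
  posKey(
    as.character(GenomicRanges::seqnames(x@variants)),
    GenomicRanges::start(x@variants)
  )
})

#' @rdname accessors
#' @export
setMethod("variants", "DosageMatrix", function(x, ...) x@variants)

#' @rdname accessors
#' @export
setMethod("dosages", "DosageMatrix", function(x, ...) x@dosages)

#' @rdname accessors
#' @export
setMethod("typed", "DosageMatrix", function(x, ...) x@typed)

#' @rdname accessors
#' @export
setMethod("samples", "DosageMatrix", function(x, ...) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("variantKeys", "DosageMatrix", function(x, ...) {
  posKey(
    as.character(GenomicRanges::seqnames(x@variants)),
    GenomicRanges::start(x@variants)
  )
})

#' @rdname accessors
#' @export
setMethod("samples", "FoldPlan", function(x, ...) names(x@assignment))

#' @rdname accessors
#' @export
setMethod("populations", "FoldPlan", function(x, ...) x@populations)

#' Fold utilities
#'
#' `foldAssignment()` returns the integer fold index per sample;
#' `foldSizes()` the per-fold sample counts; `foldSamples()` the samples of
#' one fold.
#'
#' @param plan a [FoldPlan-class].
#' @param fold integer fold index in `1..k`.
#' @return see above.
#' @export
foldAssignment <- function(plan) plan@assignment

#' @rdname foldAssignment
#' @export
foldSizes <- function(plan) tabulate(plan@assignment, nbins = plan@k)

#' @rdname foldAssignment
#' @export
foldSamples <- function(plan, fold) {
  fold <- as.integer(fold)
  if (fold < 1L || fold > plan@k) stop("fold index out of range")
  names(plan@assignment)[plan@assignment == fold]
}

#' @rdname accessors
#' @export
setGeneric("sumstats", function(x, ...) standardGeneric("sumstats"))

#' @rdname accessors
#' @export
setMethod("sumstats", "SummaryStats", function(x, ...) x@stats)

#' Number of variants / samples in a panel
#'
#' @param x a [HaplotypePanel-class].
#' @return integer count.
#' @export
nVariants <- function(x) length(variants(x))

#' @rdname nVariants
#' @export
nSamples <- function(x) length(samples(x))

setMethod("show", "HaplotypePanel", function(object) {
  cat(
    "HaplotypePanel:", nVariants(object), "variants x",
    nSamples(object), "samples (", ncol(object@haplotypes), "haplotypes )\n"
  )
  tb <- table(object@populations)
  cat(
    "populations:",
    paste(sprintf("%s (%d)", names(tb), as.integer(tb)), collapse = ", "),
    "\n"
  )
})

setMethod("show", "ArrayManifest", function(object) {
  cat("ArrayManifest:", length(object@sites), "tag-SNP positions\n")
})

setMethod("show", "DosageMatrix", function(object) {
  cat(
    "DosageMatrix:", length(object@variants), "variants x",
    length(object@sampleIds), "samples;",
    sum(object@typed), "typed,", sum(!object@typed), "imputed\n"
  )
})

setMethod("show", "PseudoArrayGenotypes", function(object) {
  cat(
    "PseudoArrayGenotypes:", length(object@variants), "typed variants x",
    length(object@sampleIds), "samples;",
    nrow(object@skipped), "manifest entries skipped\n"
  )
})

setMethod("show", "FoldPlan", function(object) {
  cat(
    "FoldPlan: k =", object@k, "; fold sizes:",
    paste(foldSizes(object), collapse = ", "), "\n"
  )
})

setMethod("show", "SummaryStats", function(object) {
  st <- object@stats
  cat("SummaryStats:", nrow(st), "variants;")
  cat(" min p =", format(min(st$p)), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport:\n")
  print(object@summary)
})

setMethod("show", "PGSResult", function(object) {
  cs <- pgsCorrelationSummary(object)
  cat(
    "PGSResult:", nrow(object@arrayScores), "samples x",
    length(object@thresholds), "thresholds; mean r =",
    format(cs$mean, digits = 4), "; mean ADPR =",
    format(mean(object@adpr$adpr), digits = 4), "\n"
  )
})
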