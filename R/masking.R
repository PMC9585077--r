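#' Stratified cross-validation folds
#'
#' Partitions samples into `k` folds balanced both overall and within each
#' population (fold sizes differ by at most one on both counts). Within each
#' population the samples are shuffled (seeded) and dealt so that every fold
#' receives the same base count; each population's remainder is dealt
#' greedily to the folds with the smallest current load (ties broken by fold
#' index), which keeps the overall partition maximally balanced for any
#' population composition.
#'
#' @param sampleIds character vector of sample identifiers.
#' @param populationOf character population label per sample (same length or
#'   named by sample).
#' @param k number of folds (>= 2, <= number of samples).
#' @param seed integer seed for the within-population shuffles.
#' @return a [FoldPlan-class].
#' @examples
#' plan <- stratifiedFolds(paste0("s", 1:23), rep(c("A", "B"), c(11, 12)), 5)
#' foldSizes(plan)
#' @export
stratifiedFolds <- function(sampleIds, populationOf, k, seed = 1L) {
  sampleIds <- as.character(sampleIds)
  k <- as.integer(k)
  n <- length(sampleIds)
  if (anyDuplicated(sampleIds) > 0L) stop("sample ids must be unique")
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of samples")
  if (!is.null(names(populationOf))) {
    populationOf <- populationOf[sampleIds]
  }
  populationOf <- as.character(populationOf)
  if (length(populationOf) != n || anyNA(populationOf)) {
    stop("`populationOf` must provide one label per sample")
  }

  assignment <- integer(n)
  names(assignment) <- sampleIds
  load <- integer(k) # extras dealt so far, per fold
  withSeed(seed, {
    for (p in sort(unique(populationOf))) {
      ids <- sampleIds[populationOf == p]
      ids <- sample(ids)
      np <- length(ids)
      q <- np %/% k
      r <- np %% k
      extraFolds <- order(load, seq_len(k))[seq_len(r)]
      folds <- c(rep(seq_len(k), q), extraFolds)
      assignment[ids] <- folds
      load[extraFolds] <- load[extraFolds] + 1L
    }
  })
  new("FoldPlan",
    k = k, assignment = assignment,
    populations = setNames(populationOf, sampleIds)
  )
}

#' Extract pseudo-array genotypes at manifest positions
#'
#' For each manifest variant found in the panel (matched on chromosome and
#' position), emits the unphased ALT-allele count (haplotype-pair sum) for
#' each requested sample — the genotypes the array "would have measured",
#' with phase discarded. Manifest entries absent from the panel, or whose
#' ref/alt alleles disagree with the panel's, are skipped and logged in the
#' `skipped` slot.
#'
#' @param panel a [HaplotypePanel-class].
#' @param manifest an [ArrayManifest-class].
#' @param sampleIds samples to extract (default: all panel samples).
#' @return a [PseudoArrayGenotypes-class], variants sorted by chrom, pos.
#' @export
makePseudoArray <- function(panel, manifest, sampleIds = NULL) {
  stopifnot(is(panel, "HaplotypePanel"), is(manifest, "ArrayManifest"))
  if (is.null(sampleIds)) sampleIds <- samples(panel)
  sampleIds <- as.character(sampleIds)
  if (!all(sampleIds %in% samples(panel))) {
    stop("requested samples must be a subset of the panel samples")
  }

  mkeys <- variantKeys(manifest)
  pkeys <- variantKeys(panel)
  hit <- match(mkeys, pkeys)

  msites <- variants(manifest)
  mref <- msites$ref
  malt <- msites$alt
  skippedReason <- rep(NA_character_, length(mkeys))
  skippedReason[is.na(hit)] <- "absent_from_panel"

  matched <- which(!is.na(hit))
  if (length(matched) && !is.null(mref)) {
    pv <- variants(panel)
    bad <- matched[
      !is.na(mref[matched]) & !is.na(malt[matched]) &
        (pv$ref[hit[matched]] != mref[matched] |
          pv$alt[hit[matched]] != malt[matched])
    ]
    skippedReason[bad] <- "allele_mismatch"
  }

  keep <- which(is.na(skippedReason))
  rows <- sort(hit[keep]) # panel order == sorted by chrom, pos
  g <- genotypes(panel, subset = sampleIds)[rows, , drop = FALSE]
  storage.mode(g) <- "integer"

  skipIdx <- which(!is.na(skippedReason))
  skipped <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(msites))[skipIdx],
    pos = GenomicRanges::start(msites)[skipIdx],
    reason = skippedReason[skipIdx],
    stringsAsFactors = FALSE
  )

  new("PseudoArrayGenotypes",
    variants = variants(panel)[rows], genotypes = g,
    sampleIds = sampleIds, skipped = skipped
  )
}

#' Split a panel into a test fold and its reference panel
#'
#' One fold of the plan becomes the test set; the phased haplotypes of all
#' remaining samples form the imputation reference panel.
#'
#' @param panel a [HaplotypePanel-class].
#' @param plan a [FoldPlan-class] over the panel's samples.
#' @param testFold integer fold index in `1..k`.
#' @return a list with elements `test` (character sample ids) and
#'   `reference` (a [HaplotypePanel-class]).
#' @export
splitReference <- function(panel, plan, testFold) {
  stopifnot(is(panel, "HaplotypePanel"), is(plan, "FoldPlan"))
  if (!setequal(samples(plan), samples(panel))) {
    stop("fold plan samples must match the panel samples")
  }
  test <- foldSamples(plan, testFold)
  ref <- setdiff(samples(panel), test)
  list(test = test, reference = subsetSamples(panel, ref))
}
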