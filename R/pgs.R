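#' Default p-value threshold grid for P+T scoring
#'
#' @return the 12-value grid 5e-08, 1e-07, 1e-06, 1e-05, 1e-04, 1e-03, 0.01,
#'   0.1, 0.2, 0.3, 0.5, 1.
#' @export
defaultThresholdGrid <- function() {
  c(5e-08, 1e-07, 1e-06, 1e-05, 1e-04, 1e-03, 0.01, 0.1, 0.2, 0.3, 0.5, 1)
}

strandAmbiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise summary statistics to a genotyped variant set
#'
#' Matches on chromosome + position. An exact effect/other to alt/ref match
#' keeps the effect as-is; a swapped match (effect allele equals the panel
#' REF) keeps the variant with the effect sign negated; strand-ambiguous
#' pairs (A/T, C/G) that would require a swap are dropped and counted;
#' unmatched variants are dropped.
#'
#' @param stats a [SummaryStats-class] (or its data.frame).
#' @param variants a [GenomicRanges::GRanges] with `ref`/`alt` metadata
#'   columns (e.g. `variants(panel)`), or a data.frame with chrom, pos, ref,
#'   alt.
#' @return list: `table` (data.frame chrom, pos, ref, alt, beta, p, aligned
#'   to the ALT allele), `nSwapped`, `nAmbiguousDropped`, `nUnmatched`.
#' @export
harmonizeSumstats <- function(stats, variants) {
  st <- if (is(stats, "SummaryStats")) sumstats(stats) else stats
  if (is(variants, "GRanges")) {
    variants <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(variants)),
      pos = GenomicRanges::start(variants),
      ref = variants$ref, alt = variants$alt, stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(posKey(st$chrom, st$pos)) > 0L ||
    anyDuplicated(posKey(variants$chrom, variants$pos)) > 0L) {
    stop("duplicate chrom:pos keys")
  }
  hit <- match(posKey(st$chrom, st$pos), posKey(variants$chrom, variants$pos))
  nUnmatched <- sum(is.na(hit))
  st <- st[!is.na(hit), , drop = FALSE]
  v <- variants[hit[!is.na(hit)], , drop = FALSE]

  exact <- st$effect_allele == v$alt & st$other_allele == v$ref
  swapped <- st$effect_allele == v$ref & st$other_allele == v$alt
  ambiguous <- swapped & strandAmbiguous(st$effect_allele, st$other_allele)
  swapped <- swapped & !ambiguous

  beta <- st$beta
  beta[swapped] <- -beta[swapped]
  keep <- exact | swapped
  out <- data.frame(
    chrom = v$chrom[keep], pos = v$pos[keep],
    ref = v$ref[keep], alt = v$alt[keep],
    beta = beta[keep], p = st$p[keep], stringsAsFactors = FALSE
  )
  list(
    table = out, nSwapped = sum(swapped),
    nAmbiguousDropped = sum(ambiguous),
    nUnmatched = nUnmatched + sum(!exact & !swapped & !ambiguous)
  )
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the unclumped variant with the smallest p-value as the
#' index (ties broken by ascending chromosome then position), retains it,
#' and removes every unclumped variant within `windowBp` on the same
#' chromosome whose squared genotype correlation with the index reaches
#' `r2Threshold`. Deterministic; the retained set is the "M SNPs after
#' clumping" of the P+T score.
#'
#' @param table harmonised effect table (data.frame with chrom, pos, beta,
#'   p), e.g. `harmonizeSumstats(...)$table`.
#' @param ldGenotypes numeric matrix of LD-reference genotypes, one row per
#'   `table` row (same order), samples in columns.
#' @param spec a [ClumpSpec-class].
#' @return integer vector: rows of `table` retained, in (chrom, pos) order.
#' @export
clumpVariants <- function(table, ldGenotypes, spec = clumpSpec()) {
  stopifnot(is(spec, "ClumpSpec"), nrow(table) == nrow(ldGenotypes))
  n <- nrow(table)
  if (n == 0L) return(integer())
  ord <- order(table$p, table$chrom, table$pos)
  active <- rep(TRUE, n)
  retained <- logical(n)
  for (i in ord) {
    if (!active[i]) next
    active[i] <- FALSE
    retained[i] <- TRUE
    nb <- which(
      active & table$chrom == table$chrom[i] &
        abs(table$pos - table$pos[i]) <= spec@windowBp
    )
    if (length(nb)) {
      gi <- ldGenotypes[i, ]
      if (stats::var(gi) > 0) {
        r <- suppressWarnings(
          as.vector(stats::cor(gi, t(ldGenotypes[nb, , drop = FALSE])))
        )
        r2 <- r * r
        r2[is.na(r2)] <- 0 # monomorphic neighbour: no LD evidence
        active[nb[r2 >= spec@r2Threshold]] <- FALSE
      }
    }
  }
  which(retained)[order(table$chrom[retained], table$pos[retained])]
}

#' P+T polygenic scores over a threshold grid
#'
#' For each threshold P_T of the grid, the score of sample i is the sum over
#' clumped variants j with P_j < P_T (strict) of `x_ij * beta_j`, where
#' `x_ij` is the expected dosage (imputed source) or the ALT-allele count
#' (truth source). Variants of the effect table missing from the genotype
#' source contribute 0 and are counted in the `nMissing` attribute.
#'
#' @param x genotype source: a [DosageMatrix-class], or a numeric matrix
#'   (variants x samples) with `"chrom:pos"` rownames.
#' @param effects clumped effect table (data.frame with chrom, pos, beta, p).
#' @param grid p-value thresholds (default [defaultThresholdGrid()]).
#' @param hardCall round dosages to the nearest integer genotype first.
#' @return numeric matrix samples x thresholds, with attribute `nMissing`.
#' @export
scorePGS <- function(x, effects, grid = defaultThresholdGrid(),
                     hardCall = FALSE) {
  if (is(x, "DosageMatrix")) {
    keys <- variantKeys(x)
    x <- dosages(x)
    rownames(x) <- keys
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (hardCall) x <- round(x)
  rows <- match(posKey(effects$chrom, effects$pos), rownames(x))
  nMissing <- sum(is.na(rows))
  eff <- effects[!is.na(rows), , drop = FALSE]
  X <- x[rows[!is.na(rows)], , drop = FALSE]

  scores <- sapply(grid, function(pt) {
    sel <- eff$p < pt
    if (!any(sel)) {
      rep(0, ncol(X))
    } else {
      as.vector(crossprod(X[sel, , drop = FALSE], eff$beta[sel]))
    }
  })
  scores <- matrix(scores,
    nrow = ncol(X),
    dimnames = list(colnames(X), format(grid, trim = TRUE))
  )
  attr(scores, "nMissing") <- nMissing
  scores
}

#' Per-threshold Pearson correlation between two PGS score sets
#'
#' @param arrayScores,wgsScores numeric matrices samples x thresholds with
#'   identical dimensions and sample order (e.g. from [scorePGS()] on the
#'   imputed and the WGS source).
#' @param thresholds the p-value grid (defaults to the score column names).
#' @return list: `perThreshold` (data.frame threshold, r, defined), `mean`
#'   and `sd` (n - 1) over the thresholds where the correlation is defined
#'   (non-constant score vectors); undefined thresholds are flagged, not
#'   averaged.
#' @export
pgsCorrelation <- function(arrayScores, wgsScores, thresholds = NULL) {
  if (!identical(dim(arrayScores), dim(wgsScores))) {
    stop("score matrices must have identical dimensions")
  }
  if (!identical(rownames(arrayScores), rownames(wgsScores))) {
    stop("score matrices must cover the same samples in the same order")
  }
  if (is.null(thresholds)) {
    thresholds <- as.numeric(colnames(arrayScores))
  }
  r <- vapply(seq_len(ncol(arrayScores)), function(j) {
    a <- arrayScores[, j]
    w <- wgsScores[, j]
    if (stats::var(a) == 0 || stats::var(w) == 0) NA_real_ else stats::cor(a, w)
  }, numeric(1))
  defined <- !is.na(r)
  list(
    perThreshold = data.frame(
      threshold = thresholds, r = r, defined = defined
    ),
    mean = if (any(defined)) mean(r[defined]) else NA_real_,
    sd = if (sum(defined) > 1L) stats::sd(r[defined]) else NA_real_
  )
}

percentileRank <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Absolute difference of percentile ranking (ADPR)
#'
#' Each sample's percentile within a score vector is
#' `100 * (rank - 0.5) / N` with mid-ranks for ties; the ADPR of a sample is
#' the absolute difference between its percentile under the array-imputed
#' scores and under the WGS scores.
#'
#' @param arrayScores,wgsScores numeric score vectors over the same samples
#'   (same order).
#' @return list: `perSample` (data.frame sample, pctArray, pctWgs, adpr) and
#'   `mean`.
#' @export
adpr <- function(arrayScores, wgsScores) {
  if (length(arrayScores) != length(wgsScores)) {
    stop("score vectors must have equal length")
  }
  n <- length(arrayScores)
  if (n < 2L) stop("ADPR requires a cohort of at least 2 samples")
  pa <- percentileRank(arrayScores)
  pw <- percentileRank(wgsScores)
  ids <- names(arrayScores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  list(
    perSample = data.frame(
      sample = ids, pctArray = pa, pctWgs = pw, adpr = abs(pa - pw),
      stringsAsFactors = FALSE
    ),
    mean = mean(abs(pa - pw))
  )
}

#' Compare P+T scores from an imputed and a truth genotype source
#'
#' Convenience wrapper: scores both sources over the grid with a shared
#' clumped effect table, then computes the per-threshold PGS correlation and
#' ADPR.
#'
#' @param dosage a [DosageMatrix-class] (array-imputed source).
#' @param truthGenotypes numeric matrix variants x samples with `"chrom:pos"`
#'   rownames (WGS source), same samples as `dosage`.
#' @param effects clumped effect table.
#' @param grid p-value thresholds.
#' @param hardCall score the imputed source on rounded dosages.
#' @return a [PGSResult-class].
#' @export
comparePGS <- function(dosage, truthGenotypes, effects,
                       grid = defaultThresholdGrid(), hardCall = FALSE) {
  arr <- scorePGS(dosage, effects, grid, hardCall = hardCall)
  wgs <- scorePGS(truthGenotypes, effects, grid)
  corr <- pgsCorrelation(arr, wgs, thresholds = grid)
  adprRows <- do.call(rbind, lapply(seq_along(grid), function(j) {
    a <- adpr(arr[, j], wgs[, j])
    cbind(threshold = grid[j], a$perSample)
  }))
  new("PGSResult",
    arrayScores = arr, wgsScores = wgs, thresholds = grid,
    correlation = corr$perThreshold, adpr = adprRows
  )
}

#' Summaries of a PGS comparison
#'
#' `pgsCorrelationSummary()` returns the mean and SD (n - 1) of the defined
#' per-threshold correlations; `adprSummary()` the mean ADPR per threshold
#' and overall.
#'
#' @param x a [PGSResult-class].
#' @return see above.
#' @export
pgsCorrelationSummary <- function(x) {
  stopifnot(is(x, "PGSResult"))
  r <- x@correlation$r[x@correlation$defined]
  list(
    mean = if (length(r)) mean(r) else NA_real_,
    sd = if (length(r) > 1L) stats::sd(r) else NA_real_
  )
}

#' @rdname pgsCorrelationSummary
#' @export
adprSummary <- function(x) {
  stopifnot(is(x, "PGSResult"))
  perThreshold <- vapply(
    split(x@adpr$adpr, x@adpr$threshold), mean, numeric(1)
  )
  perThreshold <- perThreshold[order(as.numeric(names(perThreshold)))]
  list(perThreshold = perThreshold, mean = mean(x@adpr$adpr))
}
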