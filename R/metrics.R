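#' SNP-wise imputation r-squared
#'
#' Squared Pearson correlation between imputed dosages and truth genotypes
#' across samples — the per-variant imputation accuracy metric.
#'
#' @param dosage numeric vector of imputed dosages.
#' @param truth numeric vector of true genotypes (same samples, same order).
#' @return squared Pearson correlation in `[0, 1]`, or `NA` when either
#'   vector has zero variance (undefined).
#' @examples
#' siteR2(c(0.1, 0.9, 1.8, 1.1), c(0, 1, 2, 1))
#' @export
siteR2 <- function(dosage, truth) {
  if (length(dosage) != length(truth)) {
    stop("dosage and truth must have equal length")
  }
  if (length(dosage) < 2L) stop("need at least 2 samples")
  if (stats::var(dosage) < varFloor || stats::var(truth) < varFloor) {
    return(NA_real_)
  }
  stats::cor(dosage, truth)^2
}

mafBinLevels <- c("(0-0.01]", "(0.01-0.05]", "(0.05-0.5]")
unionBinLabel <- "(0.01-0.5]"

#' Assign minor-allele-frequency bins
#'
#' Bins are left-open, right-closed: (0-0.01], (0.01-0.05], (0.05-0.5].
#' Monomorphic sites (MAF = 0) get `NA` (excluded). The derived union bin
#' (0.01-0.5] — the usual GWAS/PGS frequency cutoff — is available through
#' `inUnionBin()`.
#'
#' @param maf numeric minor-allele frequencies in `[0, 0.5]`.
#' @return factor of bin labels (levels `(0-0.01]`, `(0.01-0.05]`,
#'   `(0.05-0.5]`), `NA` for MAF 0.
#' @examples
#' assignMafBin(c(0.01, 0.05, 0.3))
#' @export
assignMafBin <- function(maf) {
  if (any(is.na(maf))) stop("MAF must not be NA")
  if (any(maf < 0)) stop("MAF must be >= 0")
  if (any(maf > 0.5)) stop("MAF above 0.5 is not a minor-allele frequency")
  cut(maf,
    breaks = c(0, 0.01, 0.05, 0.5), right = TRUE,
    labels = mafBinLevels
  )
}

#' @rdname assignMafBin
#' @return `inUnionBin()`: logical, membership in the union bin (0.01-0.5].
#' @export
inUnionBin <- function(maf) {
  if (any(maf > 0.5)) stop("MAF above 0.5 is not a minor-allele frequency")
  maf > 0.01 & maf <= 0.5
}

#' Apply the scoring exclusions to a per-site table
#'
#' Sets the `status` column: multiallelic records are excluded everywhere;
#' monomorphic sites (MAF 0) are excluded; sites in the rare bin (0-0.01]
#' with minor-allele count below 2 are excluded; typed (directly genotyped)
#' sites are excluded when `excludeTyped` — the metric evaluates imputation;
#' sites whose dosage vector has zero variance (undefined Pearson r) are
#' excluded as `zero_variance`. All remaining sites are `scored`.
#'
#' @param sites data.frame with columns `maf`, `ac`, `r2` and logical
#'   `multiallelic` and `typed` columns (missing flag columns are treated as
#'   all-FALSE).
#' @param excludeTyped exclude directly genotyped sites (default TRUE).
#' @return `sites` with a `status` column: `"scored"` or
#'   `"excluded:<reason>"`. Every input row appears exactly once.
#' @export
applyExclusions <- function(sites, excludeTyped = TRUE) {
  stopifnot(is.data.frame(sites), all(c("maf", "ac", "r2") %in% names(sites)))
  n <- nrow(sites)
  multi <- if ("multiallelic" %in% names(sites)) {
    sites$multiallelic
  } else {
    rep(FALSE, n)
  }
  typedF <- if ("typed" %in% names(sites)) sites$typed else rep(FALSE, n)
  status <- rep("scored", n)
  zeroVar <- is.na(sites$r2)
  status[zeroVar] <- "excluded:zero_variance"
  rare <- !is.na(sites$maf) & sites$maf > 0 & sites$maf <= 0.01
  status[rare & sites$ac < 2] <- "excluded:AC<2"
  status[!is.na(sites$maf) & sites$maf == 0] <- "excluded:monomorphic"
  if (excludeTyped) status[typedF] <- "excluded:typed"
  status[multi] <- "excluded:multiallelic"
  sites$status <- status
  sites
}

#' Per-site imputation metrics against truth genotypes
#'
#' Computes, for every variant of a [DosageMatrix-class], the minor-allele
#' frequency and count from the truth genotypes of the evaluated samples,
#' the MAF bin, the imputation r-squared, and the scoring status after the
#' standard exclusions ([applyExclusions()]).
#'
#' @param dosage a [DosageMatrix-class].
#' @param truth a [HaplotypePanel-class] holding the same variants (the WGS
#'   gold standard).
#' @param sampleIds the evaluated samples (default: the dosage samples).
#' @param excludeTyped exclude directly genotyped sites from scoring.
#' @param multiallelicKeys optional `"chrom:pos"` keys of records flagged
#'   multiallelic upstream (e.g. by [readPanelVcf()]).
#' @return data.frame: chrom, pos, ref, alt, maf, ac, bin, unionBin, typed,
#'   multiallelic, r2, status.
#' @export
computeSiteMetrics <- function(dosage, truth, sampleIds = NULL,
                               excludeTyped = TRUE,
                               multiallelicKeys = character()) {
  stopifnot(is(dosage, "DosageMatrix"), is(truth, "HaplotypePanel"))
  if (is.null(sampleIds)) sampleIds <- samples(dosage)
  sampleIds <- as.character(sampleIds)
  if (!all(sampleIds %in% samples(dosage))) {
    stop("evaluated samples must be present in the dosage matrix")
  }

  dkeys <- variantKeys(dosage)
  rows <- match(dkeys, variantKeys(truth))
  if (anyNA(rows)) stop("every dosage variant must be present in the truth panel")

  G <- genotypes(truth, subset = sampleIds)[rows, , drop = FALSE]
  D <- dosages(dosage)[, sampleIds, drop = FALSE]

  n2 <- 2L * length(sampleIds)
  acAlt <- rowSums(G)
  maf <- pmin(acAlt, n2 - acAlt) / n2
  ac <- pmin(acAlt, n2 - acAlt)

  gr <- variants(dosage)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    ref = gr$ref, alt = gr$alt,
    maf = maf, ac = as.integer(ac),
    bin = assignMafBin(maf),
    unionBin = inUnionBin(maf),
    typed = typed(dosage),
    multiallelic = dkeys %in% multiallelicKeys,
    r2 = rowR2(D, G),
    stringsAsFactors = FALSE
  )
  applyExclusions(out, excludeTyped = excludeTyped)
}

#' Imputation coverage at an r-squared cutoff
#'
#' The proportion of scored variants whose imputation r-squared reaches the
#' cutoff (0.8 by default).
#'
#' @param r2 numeric vector of site r-squared values (scored sites only).
#' @param cutoff r-squared cutoff.
#' @return fraction in `[0, 1]`; `NA` (with a message) for an empty set.
#' @export
coverage <- function(r2, cutoff = 0.8) {
  r2 <- r2[!is.na(r2)]
  if (length(r2) == 0L) {
    message("coverage undefined on an empty scored set")
    return(NA_real_)
  }
  mean(r2 >= cutoff)
}

#' Aggregate site metrics into a per-chromosome report
#'
#' For each population x chromosome x MAF bin (the three bins plus the union
#' bin (0.01-0.5]) computes the mean r-squared and the coverage over scored
#' sites, then summarises each population x bin across chromosomes by the
#' mean and the sample standard deviation (n - 1). With a single chromosome
#' the SD is reported as 0 and flagged `singleChrom`.
#'
#' @param sites a site-metric data.frame from [computeSiteMetrics()]; an
#'   optional `population` column stratifies the report.
#' @param cutoff coverage cutoff on r-squared.
#' @return a [MetricsReport-class].
#' @export
aggregateMetrics <- function(sites, cutoff = 0.8) {
  stopifnot(is.data.frame(sites))
  if (!"population" %in% names(sites)) sites$population <- "all"
  scored <- sites[sites$status == "scored", , drop = FALSE]

  expand <- function(df) {
    # one row per bin membership; the union bin duplicates its members
    base <- df
    base$binLabel <- as.character(base$bin)
    uni <- df[df$unionBin, , drop = FALSE]
    if (nrow(uni)) uni$binLabel <- unionBinLabel
    rbind(base[!is.na(base$binLabel), , drop = FALSE], uni)
  }
  ex <- expand(scored)

  if (nrow(ex) == 0L) {
    empty <- data.frame(
      population = character(), chrom = character(), bin = character(),
      nSites = integer(), meanR2 = numeric(), coverage = numeric()
    )
    emptySum <- data.frame(
      population = character(), bin = character(), nChrom = integer(),
      meanR2 = numeric(), sdR2 = numeric(), meanCoverage = numeric(),
      sdCoverage = numeric(), singleChrom = logical()
    )
    return(new("MetricsReport", perChromosome = empty, summary = emptySum))
  }

  groups <- split(
    ex,
    list(ex$population, ex$chrom, ex$binLabel),
    drop = TRUE, sep = "\r"
  )
  perChrom <- do.call(rbind, lapply(names(groups), function(g) {
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    df <- groups[[g]]
    data.frame(
      population = parts[1L], chrom = parts[2L], bin = parts[3L],
      nSites = nrow(df), meanR2 = mean(df$r2),
      coverage = mean(df$r2 >= cutoff), stringsAsFactors = FALSE
    )
  }))
  perChrom <- perChrom[order(
    perChrom$population, perChrom$bin, perChrom$chrom
  ), , drop = FALSE]
  rownames(perChrom) <- NULL

  sgroups <- split(
    perChrom, list(perChrom$population, perChrom$bin),
    drop = TRUE, sep = "\r"
  )
  summ <- do.call(rbind, lapply(names(sgroups), function(g) {
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    df <- sgroups[[g]]
    nc <- nrow(df)
    data.frame(
      population = parts[1L], bin = parts[2L], nChrom = nc,
      meanR2 = mean(df$meanR2),
      sdR2 = if (nc > 1L) stats::sd(df$meanR2) else 0,
      meanCoverage = mean(df$coverage),
      sdCoverage = if (nc > 1L) stats::sd(df$coverage) else 0,
      singleChrom = nc == 1L, stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  new("MetricsReport", perChromosome = perChrom, summary = summ)
}
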