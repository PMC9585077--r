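#' @importFrom vcfR read.vcfR extract.gt getFIX
NULL

vcfFix <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCF drops to a vector
  as.data.frame(fix, stringsAsFactors = FALSE)
}

vcfHeader <- function(formats, infos = character()) {
  c(
    "##fileformat=VCFv4.2",
    "##source=snpArrayEval",
    infos,
    formats
  )
}

writeVcfLines <- function(lines, path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".vcf")
    writeLines(lines, tmp)
    if (requireNamespace("Rsamtools", quietly = TRUE)) {
      Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
    } else {
      con <- gzfile(path, "w")
      writeLines(lines, con)
      close(con)
    }
    unlink(tmp)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

vcfBodyCols <- function(gr) {
  data.frame(
    CHROM = as.character(GenomicRanges::seqnames(gr)),
    POS = GenomicRanges::start(gr),
    ID = ".",
    REF = gr$ref, ALT = gr$alt, QUAL = ".", FILTER = "PASS",
    stringsAsFactors = FALSE
  )
}

#' Write / read a phased haplotype panel as VCF 4.2
#'
#' Haplotypes are written as phased `GT` (`0|1`); multiallelic records
#' encountered on read are excluded and returned in the `"excluded"`
#' attribute (data.frame chrom, pos, reason), mirroring the pipeline's
#' multiallelic filter. A two-column sample-to-population TSV can accompany
#' the VCF.
#'
#' @param panel a [HaplotypePanel-class].
#' @param path VCF path (`.vcf` or `.gz` for bgzip).
#' @return `writePanelVcf()` the path, invisibly; `readPanelVcf()` a
#'   [HaplotypePanel-class] with an `"excluded"` attribute.
#' @export
writePanelVcf <- function(panel, path) {
  stopifnot(is(panel, "HaplotypePanel"))
  H <- haplotypes(panel)
  N <- nSamples(panel)
  gt <- matrix(
    paste0(
      H[, 2L * seq_len(N) - 1L, drop = FALSE], "|",
      H[, 2L * seq_len(N), drop = FALSE]
    ),
    ncol = N
  )
  body <- cbind(vcfBodyCols(variants(panel)), INFO = ".", FORMAT = "GT", gt)
  names(body)[10:(9 + N)] <- samples(panel)
  lines <- c(
    vcfHeader('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
    paste0("#", paste(names(body), collapse = "\t")),
    do.call(paste, c(unname(as.list(body)), sep = "\t"))
  )
  writeVcfLines(lines, path)
}

#' @rdname writePanelVcf
#' @param popMap optional path to a two-column TSV (sample, population) or a
#'   named character vector; defaults to a single population `"ALL"`.
#' @export
readPanelVcf <- function(path, popMap = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfFix(vcf)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  excluded <- data.frame(
    chrom = fix$CHROM[multi], pos = as.integer(fix$POS[multi]),
    reason = rep("multiallelic", sum(multi)), stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("panel VCF must contain phased genotypes (GT with '|')")
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  N <- ncol(gt)
  M <- nrow(gt)
  H <- matrix(0L, nrow = M, ncol = 2L * N)
  H[, 2L * seq_len(N) - 1L] <- as.integer(a1)
  H[, 2L * seq_len(N)] <- as.integer(a2)
  ids <- colnames(gt)
  pops <- rep("ALL", N)
  if (!is.null(popMap)) {
    if (is.character(popMap) && length(popMap) == 1L && file.exists(popMap)) {
      pm <- utils::read.table(popMap,
        header = FALSE, sep = "\t",
        col.names = c("sample", "population"), stringsAsFactors = FALSE
      )
      popMap <- setNames(pm$population, pm$sample)
    }
    pops <- unname(popMap[ids])
    if (anyNA(pops)) stop("population map is missing some VCF samples")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = fix$CHROM,
    ranges = IRanges::IRanges(start = as.integer(fix$POS), width = 1L),
    ref = fix$REF, alt = fix$ALT
  )
  panel <- newHaplotypePanel(gr, H, ids, pops)
  attr(panel, "excluded") <- excluded
  panel
}

#' @rdname writePanelVcf
#' @export
writePopulationMap <- function(panel, path) {
  utils::write.table(
    data.frame(sample = samples(panel), population = populations(panel)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write / read pseudo-array genotypes as unphased VCF
#'
#' Genotypes are written as unphased `GT` (`0/1` style; missing as `./.`) so
#' external phasing + imputation tools can consume them.
#'
#' @param pseudo a [PseudoArrayGenotypes-class].
#' @param path VCF path.
#' @return `writePseudoArrayVcf()` the path invisibly;
#'   `readPseudoArrayVcf()` a [PseudoArrayGenotypes-class].
#' @export
writePseudoArrayVcf <- function(pseudo, path) {
  stopifnot(is(pseudo, "PseudoArrayGenotypes"))
  G <- genotypes(pseudo)
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(G), ncol = ncol(G))
  ok <- !is.na(G)
  gt[ok] <- codes[G[ok] + 1L]
  body <- cbind(vcfBodyCols(variants(pseudo)), INFO = ".", FORMAT = "GT", gt)
  names(body)[10:(9 + ncol(G))] <- samples(pseudo)
  lines <- c(
    vcfHeader('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
    paste0("#", paste(names(body), collapse = "\t")),
    do.call(paste, c(unname(as.list(body)), sep = "\t"))
  )
  writeVcfLines(lines, path)
}

#' @rdname writePseudoArrayVcf
#' @export
readPseudoArrayVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfFix(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  g <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  g[clean == "0/0"] <- 0L
  g[clean %in% c("0/1", "1/0")] <- 1L
  g[clean == "1/1"] <- 2L
  gr <- GenomicRanges::GRanges(
    seqnames = fix$CHROM,
    ranges = IRanges::IRanges(start = as.integer(fix$POS), width = 1L),
    ref = fix$REF, alt = fix$ALT
  )
  new("PseudoArrayGenotypes",
    variants = gr, genotypes = g, sampleIds = colnames(gt),
    skipped = data.frame(
      chrom = character(), pos = integer(), reason = character()
    )
  )
}

#' Write / read an imputed dosage matrix as VCF with GT:DS
#'
#' Dosages are written in the `DS` FORMAT field (4 decimal places), hard
#' calls (rounded dosage) in `GT`; the per-variant typed/imputed flag is
#' encoded in `INFO` as `TYPED` or `IMPUTED`.
#'
#' @param dosage a [DosageMatrix-class].
#' @param path VCF path.
#' @return `writeDosageVcf()` the path invisibly; `readDosageVcf()` a
#'   [DosageMatrix-class].
#' @export
writeDosageVcf <- function(dosage, path) {
  stopifnot(is(dosage, "DosageMatrix"))
  D <- dosages(dosage)
  hard <- pmin(2L, pmax(0L, round(D)))
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(
    paste0(codes[hard + 1L], ":", sprintf("%.4f", D)),
    nrow = nrow(D)
  )
  body <- cbind(
    vcfBodyCols(variants(dosage)),
    INFO = ifelse(typed(dosage), "TYPED", "IMPUTED"),
    FORMAT = "GT:DS", gt
  )
  names(body)[10:(9 + ncol(D))] <- samples(dosage)
  lines <- c(
    vcfHeader(
      c(
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Hard-call genotype">',
        '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Expected ALT dosage">'
      ),
      '##INFO=<ID=TYPED,Number=0,Type=Flag,Description="Directly genotyped">'
    ),
    paste0("#", paste(names(body), collapse = "\t")),
    do.call(paste, c(unname(as.list(body)), sep = "\t"))
  )
  writeVcfLines(lines, path)
}

#' @rdname writeDosageVcf
#' @export
readDosageVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfFix(vcf)
  info <- vcf@fix[, "INFO"]
  ds <- vcfR::extract.gt(vcf, element = "DS")
  D <- matrix(as.numeric(ds), nrow = nrow(ds), dimnames = dimnames(ds))
  if (any(D < 0 | D > 2, na.rm = TRUE)) {
    stop("parsed dosages outside [0, 2]")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = fix$CHROM,
    ranges = IRanges::IRanges(start = as.integer(fix$POS), width = 1L),
    ref = fix$REF, alt = fix$ALT
  )
  new("DosageMatrix",
    variants = gr, dosages = D,
    typed = grepl("TYPED", info, fixed = TRUE), sampleIds = colnames(ds)
  )
}

#' Write / read an array manifest as TSV (chrom, pos, ref, alt)
#'
#' @param manifest an [ArrayManifest-class].
#' @param path TSV path.
#' @return `writeManifest()` the path invisibly; `readManifest()` an
#'   [ArrayManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  gr <- variants(manifest)
  utils::write.table(
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      pos = GenomicRanges::start(gr), ref = gr$ref, alt = gr$alt
    ),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, colClasses = c(chrom = "character")
  )
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos, width = 1L),
    ref = if ("ref" %in% names(df)) df$ref else NA_character_,
    alt = if ("alt" %in% names(df)) df$alt else NA_character_
  )
  new("ArrayManifest", sites = sort(gr))
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns: chrom, pos, effect_allele, other_allele, beta, p.
#'
#' @param stats a [SummaryStats-class].
#' @param path TSV path.
#' @return `writeSummaryStats()` the path invisibly; `readSummaryStats()` a
#'   [SummaryStats-class].
#' @export
writeSummaryStats <- function(stats, path) {
  st <- sumstats(stats)
  utils::write.table(
    st[, c("chrom", "pos", "effect_allele", "other_allele", "beta", "p")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeSummaryStats
#' @export
readSummaryStats <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, colClasses = c(chrom = "character")
  )
  new("SummaryStats", stats = df)
}

#' Write a fold plan as TSV (sample, population, fold)
#'
#' @param plan a [FoldPlan-class].
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
writeFoldPlan <- function(plan, path) {
  utils::write.table(
    data.frame(
      sample = samples(plan), population = populations(plan),
      fold = foldAssignment(plan)
    ),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
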