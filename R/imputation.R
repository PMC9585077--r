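#' Impute one sample's dosages with the diploid Li-Stephens HMM
#'
#' Runs a rescaled forward-backward recursion over ordered pairs of reference
#' haplotypes (state space K^2). Between adjacent typed sites each state
#' haplotype switches with probability `1 - exp(-switchRate * gap)`, the
#' destination uniform over the K reference haplotypes; at a typed site the
#' observed genotype is emitted from the state's allele pair with per-allele
#' error `errorRate`. At untyped sites the haplotype posterior is taken from
#' the flanking typed sites with linear distance interpolation, and the
#' dosage is the posterior-expected ALT-allele count smoothed by the error
#' rate. Deterministic given its inputs.
#'
#' @param target integer vector of length M: unphased genotypes (0/1/2) at
#'   typed sites, `NA` at untyped (or typed-but-missing) sites.
#' @param reference an M x K matrix of phased reference haplotype alleles
#'   (0/1), or a [HaplotypePanel-class] (all of whose samples are used).
#' @param positions numeric bp positions of the M sites (ascending); taken
#'   from the panel when `reference` is a [HaplotypePanel-class].
#' @param params an [HMMParams-class].
#' @param details if `TRUE`, also return the typed-site haplotype posterior
#'   marginals and per-site scaling factors.
#' @return numeric dosage vector of length M in `[0, 2]` (a list when
#'   `details = TRUE`). With no typed genotypes, returns the
#'   population-frequency dosage `2 * AF` per site, with a warning.
#' @export
imputeSample <- function(target, reference, positions = NULL,
                         params = hmmParams(), details = FALSE) {
  if (is(reference, "HaplotypePanel")) {
    if (is.null(positions)) {
      positions <- GenomicRanges::start(variants(reference))
    }
    reference <- haplotypes(reference)
  }
  stopifnot(is.matrix(reference), is(params, "HMMParams"))
  validObject(params)
  M <- nrow(reference)
  K <- ncol(reference)
  if (K < 2L) stop("need at least 2 reference haplotypes")
  if (length(target) != M) stop("target length must match reference sites")
  if (is.null(positions) || length(positions) != M) {
    stop("`positions` must give one bp position per site")
  }

  typedIdx <- which(!is.na(target))
  if (length(typedIdx) == 0L) {
    warning("no typed genotypes; returning allele-frequency dosages 2*AF")
    return(2 * rowMeans(reference))
  }
  g <- as.integer(target[typedIdx])
  if (any(g < 0L | g > 2L)) stop("genotypes must be 0, 1 or 2")

  storage.mode(reference) <- "integer"
  res <- ls_impute_cpp(
    g, as.integer(typedIdx), reference, as.numeric(positions),
    params@switchRate, params@errorRate, params@numericalFloor
  )
  if (details) res else res$dosage
}

#' Impute a cohort of pseudo-array samples against a reference panel
#'
#' Applies [imputeSample()] to every target sample over all reference-panel
#' sites. Typed sites (manifest positions present in the reference panel)
#' pass through as the observed integer genotypes; all other panel sites
#' receive HMM dosages. When the reference holds more than `kCap` haplotypes
#' a seeded subsample of haplotype columns is used.
#'
#' @param pseudo a [PseudoArrayGenotypes-class].
#' @param reference a [HaplotypePanel-class]; its sample set must be disjoint
#'   from the pseudo-array samples (no data leakage).
#' @param params an [HMMParams-class].
#' @param seed integer seed (used only for reference subsampling).
#' @return a [DosageMatrix-class] covering every reference-panel site.
#' @export
imputeCohort <- function(pseudo, reference, params = hmmParams(), seed = 1L) {
  stopifnot(is(pseudo, "PseudoArrayGenotypes"), is(reference, "HaplotypePanel"))
  overlap <- intersect(samples(pseudo), samples(reference))
  if (length(overlap)) {
    stop(
      "target and reference samples overlap (data leakage): ",
      paste(utils::head(overlap, 3L), collapse = ", ")
    )
  }

  refKeys <- variantKeys(reference)
  typedRows <- match(variantKeys(pseudo), refKeys)
  usable <- which(!is.na(typedRows))
  if (length(usable) < length(typedRows)) {
    message(
      sum(is.na(typedRows)),
      " typed site(s) absent from the reference panel were ignored"
    )
  }

  H <- haplotypes(reference)
  K <- ncol(H)
  if (K > params@kCap) {
    keep <- withSeed(
      deriveSeed(seed, "kcap"),
      sort(sample.int(K, params@kCap))
    )
    H <- H[, keep, drop = FALSE]
  }
  positions <- GenomicRanges::start(variants(reference))

  ids <- samples(pseudo)
  M <- length(refKeys)
  D <- matrix(NA_real_, nrow = M, ncol = length(ids),
    dimnames = list(refKeys, ids)
  )
  G <- genotypes(pseudo)
  for (j in seq_along(ids)) {
    target <- rep(NA_integer_, M)
    target[typedRows[usable]] <- G[usable, j]
    d <- imputeSample(target, H, positions, params)
    obs <- !is.na(target)
    d[obs] <- as.numeric(target[obs]) # typed sites carry observed genotypes
    D[, j] <- d
  }

  typedFlag <- logical(M)
  typedFlag[typedRows[usable]] <- TRUE
  new("DosageMatrix",
    variants = variants(reference), dosages = D,
    typed = typedFlag, sampleIds = ids
  )
}

#' Adapter contract for external phasing + imputation tools
#'
#' Writes the pseudo-array and reference VCFs, invokes a user-configured
#' command (a template with `{pseudo}`, `{reference}` and `{out}`
#' placeholders), and parses the returned VCF `DS` field into a
#' [DosageMatrix-class]. This is an optional integration point; the built-in
#' HMM imputer is the default engine and the pipeline falls back to it when
#' no external tool is configured.
#'
#' @param pseudoVcf path to the unphased pseudo-array VCF.
#' @param referenceVcf path to the phased reference VCF.
#' @param config list with elements `command` (template string) and
#'   optionally `binary` (checked on `PATH`).
#' @param outPath path where the tool writes its dosage VCF.
#' @return a [DosageMatrix-class].
#' @export
externalImputerAdapter <- function(pseudoVcf, referenceVcf, config,
                                   outPath = tempfile(fileext = ".vcf")) {
  if (is.null(config) || is.null(config$command) || !nzchar(config$command)) {
    stop(
      "external imputer unavailable: no command configured. ",
      "Provide config$command with {pseudo}, {reference}, {out} ",
      "placeholders, or use the built-in imputeCohort().",
      call. = FALSE
    )
  }
  if (!is.null(config$binary) && Sys.which(config$binary) == "") {
    stop(
      "external imputer unavailable: binary '", config$binary,
      "' not found on PATH. Install it or use the built-in imputeCohort().",
      call. = FALSE
    )
  }
  cmd <- config$command
  cmd <- gsub("{pseudo}", pseudoVcf, cmd, fixed = TRUE)
  cmd <- gsub("{reference}", referenceVcf, cmd, fixed = TRUE)
  cmd <- gsub("{out}", outPath, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) stop("external imputer exited with status ", status)
  readDosageVcf(outPath)
}
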