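#' Simulate a phased haplotype panel with LD structure
#'
#' Generates `2 * nSamples * length(populations)` haplotypes over
#' `nVariants` biallelic variants as recombination mosaics of `nFounders`
#' founder haplotypes. Founder alleles at each site are Bernoulli draws from
#' a log-uniform site-frequency spectrum bounded below by `mafFloor`; the
#' mosaic copying process (switch probability `recombRate * gap` per
#' interval, per-site flip probability `mutationRate`) induces
#' distance-decaying linkage disequilibrium, and per-population Dirichlet
#' founder copying weights induce allele-frequency differentiation between
#' populations.
#'
#' @param config a [SimConfig-class].
#' @return a [HaplotypePanel-class].
#' @examples
#' panel <- simulatePanel(simConfig(nSamples = 20, nVariants = 200))
#' panel
#' @export
simulatePanel <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, {
    M <- config@nVariants
    Fk <- config@nFounders
    pos <- sort(sample.int(config@chromLength, M))

    # log-uniform minor-allele-scale frequency, then random major/minor
    # orientation of the ALT allele
    f <- config@mafFloor * (0.5 / config@mafFloor)^runif(M)
    flip <- runif(M) < 0.5
    f[flip] <- 1 - f[flip]

    founders <- matrix(
      as.integer(runif(Fk * M) < rep(f, each = Fk)),
      nrow = Fk, ncol = M
    )

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, M, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

    pops <- config@populations
    N <- config@nSamples * length(pops)
    sampleIds <- sprintf("S%04d", seq_len(N))
    popOf <- rep(pops, each = config@nSamples)

    # per-population founder copying weights (Dirichlet)
    w <- lapply(pops, function(p) {
      g <- rgamma(Fk, shape = config@popDiff)
      g / sum(g)
    })
    names(w) <- pops

    gaps <- diff(pos)
    pSwitch <- pmin(1, config@recombRate * gaps)

    H <- matrix(0L, nrow = M, ncol = 2L * N)
    for (j in seq_len(2L * N)) {
      wp <- w[[popOf[(j + 1L) %/% 2L]]]
      switches <- runif(M - 1L) < pSwitch
      seg <- cumsum(c(1L, switches))
      fid <- sample.int(Fk, seg[M], replace = TRUE, prob = wp)
      hap <- founders[cbind(fid[seg], seq_len(M))]
      if (config@mutationRate > 0) {
        mut <- runif(M) < config@mutationRate
        hap[mut] <- 1L - hap[mut]
      }
      H[, j] <- hap
    }

    gr <- GenomicRanges::GRanges(
      seqnames = config@chrom,
      ranges = IRanges::IRanges(start = pos, width = 1L),
      ref = ref, alt = alt
    )
    newHaplotypePanel(gr, H, sampleIds, popOf)
  })
}

#' Derive an array manifest from a panel
#'
#' Selects `round(density * M)` distinct variants as the array's tag SNPs.
#' Strategy `"random"` samples uniformly; `"maf_weighted"` samples with
#' probability proportional to each site's minor-allele frequency, emulating
#' the common-variant bias of real tag-SNP selection.
#'
#' @param panel a [HaplotypePanel-class].
#' @param density fraction of panel variants on the array, in (0, 1].
#' @param strategy `"random"` or `"maf_weighted"`.
#' @param seed integer seed.
#' @return an [ArrayManifest-class] whose sites are a subset of the panel's.
#' @export
deriveManifest <- function(panel, density, strategy = c("random", "maf_weighted"),
                           seed = 1L) {
  stopifnot(is(panel, "HaplotypePanel"))
  strategy <- match.arg(strategy)
  if (!is.numeric(density) || length(density) != 1L ||
    density <= 0 || density > 1) {
    stop("`density` must lie in (0, 1]")
  }
  M <- nVariants(panel)
  n <- round(density * M)
  if (n < 1L) stop("density selects no variants")
  idx <- withSeed(seed, {
    if (strategy == "random") {
      sample.int(M, n)
    } else {
      p <- rowMeans(haplotypes(panel))
      maf <- pmin(p, 1 - p)
      sample.int(M, n, prob = maf + 1e-9)
    }
  })
  new("ArrayManifest", sites = sort(variants(panel)[idx]))
}

#' Simulate GWAS summary statistics over a panel's variants
#'
#' Every panel variant receives an effect allele (the ALT allele), a marginal
#' effect size and a p-value. `nCausal` variants, sampled uniformly, draw
#' effects from N(0, `betaVariance`) and p-values uniform below 5e-8 (the
#' genome-wide significance threshold); the remaining variants draw
#' zero-centred noise effects (sd = sqrt(betaVariance)/20) and p-values
#' uniform above 5e-8, so exactly `nCausal` variants are genome-wide
#' significant by construction.
#'
#' @param panel a [HaplotypePanel-class].
#' @param model an [EffectModel-class].
#' @return a [SummaryStats-class] with a `causal` indicator column.
#' @export
simulateSummaryStats <- function(panel, model) {
  stopifnot(is(panel, "HaplotypePanel"), is(model, "EffectModel"))
  validObject(model)
  M <- nVariants(panel)
  if (model@nCausal > M) stop("nCausal exceeds the number of panel variants")
  gwSig <- 5e-8
  withSeed(model@seed, {
    causal <- logical(M)
    causal[sample.int(M, model@nCausal)] <- TRUE
    beta <- rnorm(M, 0, sqrt(model@betaVariance) / 20)
    beta[causal] <- rnorm(model@nCausal, 0, sqrt(model@betaVariance))
    p <- runif(M, min = gwSig, max = 1)
    p[causal] <- runif(model@nCausal, min = 0, max = gwSig)
    gr <- variants(panel)
    st <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      pos = GenomicRanges::start(gr),
      effect_allele = gr$alt, other_allele = gr$ref,
      beta = beta, p = p, causal = causal,
      stringsAsFactors = FALSE
    )
    new("SummaryStats", stats = st)
  })
}

#' Subset a panel to a set of samples
#'
#' @param panel a [HaplotypePanel-class].
#' @param keep character vector of sample ids to retain.
#' @return a [HaplotypePanel-class] with the retained samples.
#' @export
subsetSamples <- function(panel, keep) {
  keep <- as.character(keep)
  if (!all(keep %in% samples(panel))) stop("unknown sample id in `keep`")
  cols <- paste0(rep(keep, each = 2L), "_", 1:2)
  newHaplotypePanel(
    variants(panel), haplotypes(panel)[, cols, drop = FALSE],
    keep, populations(panel)[keep]
  )
}
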