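#' Configuration of a full mask-and-impute evaluation run
#'
#' Bundles the inputs of [runEvaluation()]: the truth panel, one manifest per
#' evaluated array, one set of summary statistics per trait, the fold count,
#' the HMM and clumping parameters, the p-value grid and the master seed.
#'
#' @slot panel a [HaplotypePanel-class] (the WGS gold standard).
#' @slot manifests named list of [ArrayManifest-class] objects.
#' @slot sumstats named list of [SummaryStats-class] objects (one per trait).
#' @slot k integer fold count (default 10).
#' @slot hmm an [HMMParams-class].
#' @slot clump a [ClumpSpec-class].
#' @slot thresholds numeric p-value grid.
#' @slot seed integer master seed; all per-stage seeds derive from it.
#' @slot outDir character; optional directory for intermediate artifacts
#'   (`NA` disables writing).
#' @export
setClass("RunConfig", representation(
  panel = "HaplotypePanel", manifests = "list", sumstats = "list",
  k = "integer", hmm = "HMMParams", clump = "ClumpSpec",
  thresholds = "numeric", seed = "integer", outDir = "character"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (length(object@manifests) == 0L ||
    is.null(names(object@manifests)) ||
    !all(vapply(object@manifests, is, logical(1), "ArrayManifest"))) {
    msg <- c(msg, "manifests must be a named list of ArrayManifest objects")
  }
  if (length(object@sumstats) &&
    (is.null(names(object@sumstats)) ||
      !all(vapply(object@sumstats, is, logical(1), "SummaryStats")))) {
    msg <- c(msg, "sumstats must be a named list of SummaryStats objects")
  }
  if (any(object@thresholds <= 0 | object@thresholds > 1)) {
    msg <- c(msg, "thresholds must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @param panel,manifests,sumstats,k,hmm,clump,thresholds,seed,outDir see
#'   the corresponding slots.
#' @return `runConfig()` returns a validated [RunConfig-class] object.
#' @rdname RunConfig-class
#' @export
runConfig <- function(panel, manifests, sumstats = list(), k = 10L,
                      hmm = hmmParams(), clump = clumpSpec(),
                      thresholds = defaultThresholdGrid(), seed = 1L,
                      outDir = NA_character_) {
  new("RunConfig",
    panel = panel, manifests = manifests, sumstats = sumstats,
    k = as.integer(k), hmm = hmm, clump = clump,
    thresholds = as.numeric(thresholds), seed = as.integer(seed),
    outDir = as.character(outDir)
  )
}

#' Run the full mask-and-impute array evaluation
#'
#' For every array manifest: each cross-validation fold is masked to its
#' pseudo-array genotypes and imputed against the phased haplotypes of the
#' remaining samples; the imputed folds are merged; imputation metrics (site
#' r-squared, MAF-binned means and coverage) are computed per population; and
#' P+T polygenic scores from the imputed dosages are compared per trait and
#' population against scores from the WGS truth genotypes (shared clump set,
#' computed once on the truth genotypes of each population cohort).
#'
#' @param config a [RunConfig-class].
#' @param verbose print per-stage progress.
#' @return a list with elements
#'   * `foldPlan`: the [FoldPlan-class] used;
#'   * `dosages`: named list of merged [DosageMatrix-class] per array;
#'   * `imputation`: per array, a list with the per-site metric table
#'     (`sites`) and the [MetricsReport-class] (`report`);
#'   * `pgs`: per array x trait x population, a [PGSResult-class];
#'   * `provenance`: seed, fold sizes, parameters, package version.
#' @export
runEvaluation <- function(config, verbose = FALSE) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  panel <- config@panel
  plan <- stratifiedFolds(
    samples(panel), populations(panel), config@k,
    seed = deriveSeed(config@seed, "folds")
  )
  pops <- sort(unique(populations(panel)))
  popSamples <- lapply(pops, function(p) {
    samples(panel)[populations(panel) == p]
  })
  names(popSamples) <- pops
  truthAll <- genotypes(panel)

  imputation <- list()
  pgs <- list()
  dosagesByArray <- list()

  for (arrayName in names(config@manifests)) {
    manifest <- config@manifests[[arrayName]]
    if (verbose) message("array ", arrayName, ": imputing ", config@k, " folds")
    M <- nVariants(panel)
    D <- matrix(NA_real_, nrow = M, ncol = nSamples(panel),
      dimnames = list(variantKeys(panel), samples(panel))
    )
    typedFlag <- NULL
    for (fold in seq_len(config@k)) {
      res <- tryCatch(
        {
          sp <- splitReference(panel, plan, fold)
          stopifnot(length(intersect(sp$test, samples(sp$reference))) == 0L)
          pseudo <- makePseudoArray(panel, manifest, sp$test)
          imputeCohort(pseudo, sp$reference, config@hmm,
            seed = deriveSeed(config@seed, paste0("fold:", fold))
          )
        },
        error = function(e) {
          stop(
            "evaluation failed for array '", arrayName, "' at fold ", fold,
            ": ", conditionMessage(e),
            call. = FALSE
          )
        }
      )
      D[, samples(res)] <- dosages(res)
      typedFlag <- typed(res) # identical across folds: same manifest/panel
    }
    merged <- new("DosageMatrix",
      variants = variants(panel), dosages = D,
      typed = typedFlag, sampleIds = samples(panel)
    )
    dosagesByArray[[arrayName]] <- merged

    sites <- do.call(rbind, lapply(pops, function(p) {
      sm <- computeSiteMetrics(merged, panel, sampleIds = popSamples[[p]])
      sm$population <- p
      sm
    }))
    imputation[[arrayName]] <- list(
      sites = sites, report = aggregateMetrics(sites)
    )

    if (length(config@sumstats)) {
      pgs[[arrayName]] <- lapply(config@sumstats, function(ss) {
        harm <- harmonizeSumstats(ss, variants(panel))
        res <- lapply(pops, function(p) {
          ids <- popSamples[[p]]
          truth <- truthAll[, ids, drop = FALSE]
          rows <- match(
            posKey(harm$table$chrom, harm$table$pos), rownames(truth)
          )
          kept <- clumpVariants(
            harm$table, truth[rows, , drop = FALSE], config@clump
          )
          effects <- harm$table[kept, , drop = FALSE]
          sub <- new("DosageMatrix",
            variants = variants(merged),
            dosages = dosages(merged)[, ids, drop = FALSE],
            typed = typed(merged), sampleIds = ids
          )
          comparePGS(sub, truth, effects, grid = config@thresholds)
        })
        names(res) <- pops
        res
      })
    }
  }

  out <- list(
    foldPlan = plan,
    dosages = dosagesByArray,
    imputation = imputation,
    pgs = pgs,
    provenance = list(
      seed = config@seed,
      foldSizes = foldSizes(plan),
      k = config@k,
      arrays = names(config@manifests),
      traits = names(config@sumstats),
      thresholds = config@thresholds,
      hmm = list(
        switchRate = config@hmm@switchRate, errorRate = config@hmm@errorRate,
        kCap = config@hmm@kCap
      ),
      clump = list(
        windowBp = config@clump@windowBp,
        r2Threshold = config@clump@r2Threshold
      ),
      package = as.character(utils::packageVersion("snpArrayEval")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )
  if (!is.na(config@outDir)) writeReport(out, config@outDir)
  out
}

#' Tabular report of an evaluation run
#'
#' `reportTables()` flattens a [runEvaluation()] result into two data.frames:
#' the imputation table (array x population x MAF bin, mean +/- SD of
#' per-chromosome mean r-squared and coverage) and the PGS table (array x
#' trait x population, mean +/- SD of the per-threshold PGS correlation and
#' the mean ADPR). The rows come verbatim from [aggregateMetrics()] and the
#' per-threshold summaries — a single source of truth.
#'
#' @param results a [runEvaluation()] result.
#' @return list of data.frames `imputation` and `pgs`.
#' @export
reportTables <- function(results) {
  imp <- do.call(rbind, lapply(names(results$imputation), function(a) {
    s <- results$imputation[[a]]$report@summary
    if (nrow(s) == 0L) return(NULL)
    cbind(array = a, s, stringsAsFactors = FALSE)
  }))
  if (is.null(imp)) {
    imp <- data.frame(
      array = character(), population = character(), bin = character(),
      nChrom = integer(), meanR2 = numeric(), sdR2 = numeric(),
      meanCoverage = numeric(), sdCoverage = numeric(),
      singleChrom = logical()
    )
  }
  pgsRows <- list()
  for (a in names(results$pgs)) {
    for (tr in names(results$pgs[[a]])) {
      for (p in names(results$pgs[[a]][[tr]])) {
        x <- results$pgs[[a]][[tr]][[p]]
        cs <- pgsCorrelationSummary(x)
        as_ <- adprSummary(x)
        pgsRows[[length(pgsRows) + 1L]] <- data.frame(
          array = a, trait = tr, population = p,
          corMean = cs$mean, corSD = cs$sd, adprMean = as_$mean,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  pgsTab <- if (length(pgsRows)) {
    do.call(rbind, pgsRows)
  } else {
    data.frame(
      array = character(), trait = character(), population = character(),
      corMean = numeric(), corSD = numeric(), adprMean = numeric()
    )
  }
  list(imputation = imp, pgs = pgsTab)
}

#' Write evaluation reports to disk
#'
#' Writes the imputation and PGS tables as TSV, the fold plan as TSV, and a
#' machine-readable JSON summary (tables + provenance) that round-trips to
#' the identical in-memory summary.
#'
#' @param results a [runEvaluation()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeReport <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- reportTables(results)
  utils::write.table(tabs$imputation, file.path(dir, "imputation_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(tabs$pgs, file.path(dir, "pgs_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeFoldPlan(results$foldPlan, file.path(dir, "fold_plan.tsv"))
  jsonlite::write_json(
    list(
      imputation = tabs$imputation, pgs = tabs$pgs,
      provenance = results$provenance
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
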