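#' @importFrom methods new validObject is slot
#' @importFrom stats cor sd rnorm runif rgamma setNames
#' @importFrom utils read.table write.table packageVersion
NULL

# Seed-splitting rule: every stochastic operation receives one explicit integer
# seed; internal sub-steps (per-fold imputation, reference subsampling, ...)
# derive child seeds as deriveSeed(seed, tag) with a fixed string tag, so a
# single top-level seed reproduces the whole run while sub-steps stay
# decorrelated. Kept below 2^31 - 1 to fit an R integer.
deriveSeed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# "chrom:pos" keys used to match variants across panels, manifests and
# summary statistics (position-based matching; alleles are checked separately).
posKey <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Row-wise squared Pearson correlation between two matrices of equal shape.
# Rows with zero variance in either matrix return NA (undefined).
rowR2 <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 samples to compute r2")
  cx <- x - rowMeans(x)
  cy <- y - rowMeans(y)
  sxy <- rowSums(cx * cy)
  sxx <- rowSums(cx * cx)
  syy <- rowSums(cy * cy)
  r2 <- (sxy * sxy) / (sxx * syy)
  # centred sums of squares below the degeneracy floor mean an (effectively)
  # constant vector: Pearson r is undefined, not near-zero noise
  r2[sxx < varFloor * (n - 1) | syy < varFloor * (n - 1)] <- NA_real_
  r2
}

# variance below this is treated as zero when deciding whether a site's
# Pearson r2 is defined (dosages live on [0, 2]; genuine variation across
# samples is many orders of magnitude larger)
varFloor <- 1e-10
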