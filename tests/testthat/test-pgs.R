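makeStats <- function(chrom, pos, ea, oa, beta, p) {
  data.frame(
    chrom = chrom, pos = pos, effect_allele = ea, other_allele = oa,
    beta = beta, p = p, stringsAsFactors = FALSE
  )
}

test_that("harmonisation handles the four allele-match cases", {
  panelVars <- data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "A", "A", "C"), alt = c("G", "G", "T", "G")
  )
  st <- makeStats(
    "1", c(100L, 200L, 300L, 400L),
    ea = c("G", "A", "A", "T"), oa = c("A", "G", "T", "A"),
    beta = c(0.1, 0.2, 0.3, 0.4), p = rep(0.01, 4)
  )
  h <- harmonizeSumstats(st, panelVars)
  # exact match kept as-is; swapped match sign-negated; A/T swap dropped
  # as strand-ambiguous; mismatching alleles dropped
  expect_equal(h$table$pos, c(100L, 200L))
  expect_equal(h$table$beta, c(0.1, -0.2))
  expect_equal(h$nSwapped, 1L)
  expect_equal(h$nAmbiguousDropped, 1L)
  expect_equal(h$nUnmatched, 1L)

  dup <- rbind(st, st[1, ])
  expect_error(harmonizeSumstats(dup, panelVars), "duplicate")
})

test_that("clumping follows window and LD rules", {
  set.seed(1)
  g1 <- sample(0:2, 50, replace = TRUE)
  g2 <- g1
  g2[1:10] <- sample(0:2, 10, replace = TRUE) # correlated neighbour
  tab <- data.frame(
    chrom = "1", pos = c(100000L, 200000L),
    beta = c(0.1, 0.2), p = c(1e-10, 1e-4)
  )
  geno <- rbind(g1, g2)
  expect_equal(clumpVariants(tab, geno, clumpSpec()), 1L)

  # outside the window both survive regardless of correlation
  far <- tab
  far$pos <- c(100000L, 400000L)
  expect_equal(clumpVariants(far, geno, clumpSpec()), c(1L, 2L))
})

test_that("clumping matches the brute-force rescan oracle", {
  for (s in 1:40) {
    set.seed(s)
    n <- 20
    tab <- data.frame(
      chrom = sample(c("1", "2"), n, replace = TRUE),
      pos = sample.int(1e6, n),
      beta = rnorm(n), p = runif(n)^2
    )
    base <- matrix(sample(0:2, 15 * 5, replace = TRUE), 5, 15)
    geno <- base[sample(5, n, replace = TRUE), ] +
      matrix(sample(0:1, n * 15, replace = TRUE), n, 15)
    geno <- pmin(geno, 2)
    spec <- clumpSpec(windowBp = 200000, r2Threshold = 0.3)
    expect_equal(
      sort(clumpVariants(tab, geno, spec)),
      bruteClump(tab, geno, 200000, 0.3)
    )
  }
})

test_that("clumping is invariant to input row order", {
  set.seed(9)
  n <- 30
  tab <- data.frame(
    chrom = "1", pos = sort(sample.int(5e5, n)), beta = rnorm(n),
    p = runif(n)
  )
  geno <- matrix(sample(0:2, n * 20, replace = TRUE), n, 20)
  kept1 <- tab$pos[clumpVariants(tab, geno, clumpSpec())]
  perm <- sample(n)
  kept2 <- tab$pos[perm][clumpVariants(tab[perm, ], geno[perm, ], clumpSpec())]
  expect_identical(sort(kept1), sort(kept2))
})

test_that("P+T scores are indicator-gated beta-weighted allele sums", {
  X <- matrix(c(0, 1, 2), nrow = 1, dimnames = list("1:100", NULL))
  eff <- data.frame(chrom = "1", pos = 100L, beta = 0.5, p = 0.005)
  s <- scorePGS(X, eff, grid = c(0.01))
  expect_equal(as.vector(s), c(0, 0.5, 1.0))

  # strict inequality: p == threshold does not pass
  expect_equal(as.vector(scorePGS(X, eff, grid = c(0.005))), c(0, 0, 0))

  X3 <- matrix(c(2, 1, 0), ncol = 1,
    dimnames = list(c("1:100", "1:200", "1:300"), "s1")
  )
  eff3 <- data.frame(
    chrom = "1", pos = c(100L, 200L, 300L),
    beta = c(0.1, -0.2, 0.3), p = rep(1e-9, 3)
  )
  expect_equal(as.vector(scorePGS(X3, eff3, grid = 1)), 0.0)

  # missing source variants contribute zero and are counted
  s2 <- scorePGS(X3[1:2, , drop = FALSE], eff3, grid = 1)
  expect_equal(as.vector(s2), 0.1 * 2 - 0.2 * 1)
  expect_equal(attr(s2, "nMissing"), 1L)
})

test_that("scores are linear in beta and in genotypes; threshold sets nest", {
  set.seed(11)
  n <- 25
  X <- matrix(runif(n * 10, 0, 2), n,
    dimnames = list(paste0("1:", 1:n * 10), NULL)
  )
  eff <- data.frame(
    chrom = "1", pos = 1:n * 10L, beta = rnorm(n), p = runif(n)
  )
  g <- defaultThresholdGrid()
  s1 <- scorePGS(X, eff, g)
  eff2 <- eff
  eff2$beta <- 2 * eff$beta
  expect_equal(scorePGS(X, eff2, g), 2 * s1, ignore_attr = TRUE)
  expect_equal(scorePGS(3 * X, eff, g), 3 * s1, ignore_attr = TRUE)
  effsum <- eff
  effsum$beta <- eff$beta + eff2$beta
  expect_equal(
    scorePGS(X, effsum, g), s1 + scorePGS(X, eff2, g),
    ignore_attr = TRUE
  )
  # nesting of the passing sets along the grid
  for (j in 2:length(g)) {
    expect_true(all(which(eff$p < g[j - 1]) %in% which(eff$p < g[j])))
  }
})

test_that("PGS correlation matches the two-pass oracle and its properties", {
  set.seed(13)
  a <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("s", 1:5), NULL))
  cors <- pgsCorrelation(a, a, thresholds = c(0.1, 0.5, 1))
  expect_equal(cors$perThreshold$r, rep(1, 3))
  expect_equal(cors$mean, 1)

  b <- 2 * a + 3
  expect_equal(
    pgsCorrelation(a, b, thresholds = c(0.1, 0.5, 1))$perThreshold$r,
    rep(1, 3)
  )

  w <- matrix(rnorm(5 * 3), 5, 3, dimnames = dimnames(a))
  pc <- pgsCorrelation(a, w, thresholds = c(0.1, 0.5, 1))
  for (j in 1:3) {
    expect_lt(abs(pc$perThreshold$r[j] - pearsonOracle(a[, j], w[, j])), 1e-12)
  }

  const <- w
  const[, 2] <- 7
  pc2 <- pgsCorrelation(a, const, thresholds = c(0.1, 0.5, 1))
  expect_false(pc2$perThreshold$defined[2])
  expect_equal(
    pc2$mean, mean(pc2$perThreshold$r[c(1, 3)])
  )
})

test_that("ADPR uses mid-rank percentiles and detects swaps", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(adpr(x, x)$perSample$adpr, rep(0, 4))

  swapped <- c(a = 2, b = 1, c = 3, d = 4)
  res <- adpr(swapped, x)
  expect_equal(res$perSample$adpr, c(25, 25, 0, 0))
  expect_equal(res$mean, 12.5)

  # invariant under a common monotone transform
  res2 <- adpr(exp(swapped), exp(x))
  expect_equal(res2$perSample$adpr, res$perSample$adpr)

  expect_error(adpr(1, 1), "at least 2")
})

test_that("identical score sources give correlation 1 and ADPR 0 end-to-end", {
  p <- simulatePanel(simConfig(nSamples = 25, nVariants = 400, seed = 61))
  ss <- simulateSummaryStats(p, effectModel(nCausal = 20, seed = 3))
  h <- harmonizeSumstats(ss, variants(p))
  g <- genotypes(p)
  rows <- match(
    snpArrayEval:::posKey(h$table$chrom, h$table$pos), rownames(g)
  )
  kept <- clumpVariants(h$table, g[rows, , drop = FALSE])
  eff <- h$table[kept, , drop = FALSE]
  dm <- new("DosageMatrix",
    variants = variants(p), dosages = g + 0.0,
    typed = rep(FALSE, nVariants(p)), sampleIds = samples(p)
  )
  res <- comparePGS(dm, g, eff)
  expect_equal(res@correlation$r[res@correlation$defined],
    rep(1, sum(res@correlation$defined)),
    tolerance = 1e-12
  )
  expect_true(all(res@correlation$defined))
  expect_equal(max(res@adpr$adpr), 0)
})
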