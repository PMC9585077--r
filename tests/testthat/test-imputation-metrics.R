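test_that("site r2 matches the textbook Pearson formula and its edge cases", {
  expect_equal(siteR2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1.0)
  expect_true(is.na(siteR2(c(0.1, 0.5, 0.9, 1.2), c(1, 1, 1, 1))))
  expect_error(siteR2(1:3, 1:4), "equal length")

  d <- c(0.1, 0.9, 1.8, 1.1)
  t_ <- c(0, 1, 2, 1)
  expect_lt(abs(siteR2(d, t_) - pearsonOracle(d, t_)^2), 1e-12)

  set.seed(2)
  for (i in 1:50) {
    x <- runif(20, 0, 2)
    y <- sample(0:2, 20, replace = TRUE)
    if (stats::var(y) == 0) next
    expect_lt(abs(siteR2(x, y) - pearsonOracle(x, y)^2), 1e-12)
    # Pearson r2 is invariant under affine rescaling of the dosages
    expect_lt(abs(siteR2(3.7 * x - 1.2, y) - siteR2(x, y)), 1e-12)
  }
})

test_that("MAF bins are left-open right-closed with the union bin", {
  b <- assignMafBin(c(0.01, 0.05, 0.30, 0.005, 0.5))
  expect_equal(
    as.character(b),
    c("(0-0.01]", "(0.01-0.05]", "(0.05-0.5]", "(0-0.01]", "(0.05-0.5]")
  )
  expect_true(is.na(assignMafBin(0)))
  expect_error(assignMafBin(0.6), "minor-allele")
  expect_error(assignMafBin(-0.1), ">= 0")
  expect_identical(inUnionBin(c(0.30, 0.01, 0.011)), c(TRUE, FALSE, TRUE))
})

test_that("scoring exclusions follow the filtering rules and conserve sites", {
  sites <- data.frame(
    maf = c(0.004, 0.004, 0.2, 0.0, 0.3, 0.02),
    ac = c(1L, 2L, 40L, 0L, 60L, 4L),
    r2 = c(0.5, 0.6, 0.9, NA, NA, 0.7),
    multiallelic = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    typed = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  out <- applyExclusions(sites)
  expect_equal(out$status, c(
    "excluded:AC<2", "scored", "scored", "excluded:monomorphic",
    "excluded:multiallelic", "excluded:typed"
  ))
  # conservation: every site is either scored or excluded with one reason
  expect_equal(
    sum(out$status == "scored") + sum(startsWith(out$status, "excluded:")),
    nrow(sites)
  )
  # typed sites are retained when the metric is asked to keep them
  keep <- applyExclusions(sites, excludeTyped = FALSE)
  expect_equal(keep$status[6], "scored")
})

test_that("coverage counts the fraction of sites at the cutoff", {
  expect_equal(coverage(rep(1, 5)), 1.0)
  expect_equal(coverage(c(0.9, 0.7, 0.85)), 2 / 3)
  set.seed(3)
  r2 <- runif(200)
  expect_lte(coverage(r2, 0.9), coverage(r2, 0.8))
  expect_message(cv <- coverage(numeric(0)), "empty")
  expect_true(is.na(cv))
})

test_that("MAF is invariant to which allele is labelled REF", {
  p <- simulatePanel(simConfig(nSamples = 20, nVariants = 100, seed = 51))
  man <- deriveManifest(p, 0.5, seed = 1)
  plan <- stratifiedFolds(samples(p), populations(p), 4, seed = 1)
  sp <- splitReference(p, plan, 1)
  ps <- makePseudoArray(p, man, sp$test)
  dm <- imputeCohort(ps, sp$reference, hmmParams(switchRate = 1e-6))
  sm <- computeSiteMetrics(dm, p, sampleIds = sp$test)

  flipped <- panelFromMatrix(
    1L - haplotypes(p), GenomicRanges::start(variants(p)),
    pops = unname(populations(p)),
    ref = variants(p)$alt, alt = variants(p)$ref, ids = samples(p)
  )
  # same dosage matrix evaluated against allele-swapped truth: the dosage
  # r2 changes meaning, but MAF and AC must be identical
  dmF <- new("DosageMatrix",
    variants = variants(flipped), dosages = 2 - dosages(dm),
    typed = typed(dm), sampleIds = samples(dm)
  )
  smF <- computeSiteMetrics(dmF, flipped, sampleIds = sp$test)
  expect_equal(sm$maf, smF$maf)
  expect_equal(sm$ac, smF$ac)
  expect_equal(sm$r2, smF$r2)
})

test_that("aggregation reports per-chromosome means and n-1 SD", {
  sites <- data.frame(
    chrom = rep(c("1", "2"), each = 2),
    pos = c(10L, 20L, 10L, 20L), ref = "A", alt = "G",
    maf = rep(0.3, 4), ac = rep(10L, 4),
    bin = factor(rep("(0.05-0.5]", 4),
      levels = c("(0-0.01]", "(0.01-0.05]", "(0.05-0.5]")
    ),
    unionBin = TRUE, typed = FALSE, multiallelic = FALSE,
    r2 = c(0.8, 0.8, 0.9, 0.9), status = "scored"
  )
  rep_ <- aggregateMetrics(sites)
  s <- rep_@summary
  row <- s[s$bin == "(0.01-0.5]", ]
  expect_equal(row$meanR2, 0.85)
  expect_equal(row$sdR2, stats::sd(c(0.8, 0.9)))
  expect_equal(round(row$sdR2, 4), 0.0707)
  expect_false(row$singleChrom)

  one <- aggregateMetrics(sites[sites$chrom == "1", ])
  expect_true(all(one@summary$sdR2 == 0))
  expect_true(all(one@summary$singleChrom))

  # shape: chromosomes x bins represented in the per-chromosome table
  expect_equal(nrow(rep_@perChromosome), 2L * 2L) # 2 chrom x (bin + union)
})

test_that("per-site metrics flow from dosages and truth genotypes", {
  p <- simulatePanel(simConfig(nSamples = 25, nVariants = 300, seed = 55))
  man <- deriveManifest(p, 0.3, seed = 1)
  plan <- stratifiedFolds(samples(p), populations(p), 5, seed = 1)
  sp <- splitReference(p, plan, 1)
  ps <- makePseudoArray(p, man, sp$test)
  dm <- imputeCohort(ps, sp$reference, hmmParams(switchRate = 1e-6))
  sm <- computeSiteMetrics(dm, p, sampleIds = sp$test)

  expect_equal(nrow(sm), nVariants(p)) # conservation
  expect_true(all(sm$status[sm$typed] == "excluded:typed"))
  scored <- sm[sm$status == "scored", ]
  expect_true(all(scored$r2 >= 0 & scored$r2 <= 1))
  # spot-check one scored site against the scalar definition
  i <- which(sm$status == "scored")[1]
  g <- genotypes(p, subset = sp$test)
  expect_equal(
    sm$r2[i], siteR2(dosages(dm)[i, ], g[i, ])
  )
})
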