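# the 1KGP-like super-population composition used in the fold-size checks
kgpLikeCohort <- function() {
  sizes <- c(EAS = 504, EUR = 503, SAS = 489, AFR = 661, AMR = 347)
  list(
    ids = sprintf("I%04d", seq_len(sum(sizes))),
    pops = rep(names(sizes), sizes)
  )
}

test_that("stratified folds reproduce the reference cohort batch sizes", {
  co <- kgpLikeCohort()
  plan <- stratifiedFolds(co$ids, co$pops, k = 10, seed = 1)
  expect_identical(sort(foldSizes(plan)), c(rep(250L, 6), rep(251L, 4)))

  vn <- stratifiedFolds(
    sprintf("V%04d", 1:1008), rep("VNP", 1008), k = 10, seed = 1
  )
  expect_identical(sort(foldSizes(vn)), c(rep(100L, 2), rep(101L, 8)))

  tiny <- stratifiedFolds(letters[1:10], rep("x", 10), k = 10, seed = 1)
  expect_identical(foldSizes(tiny), rep(1L, 10))
})

test_that("fold balance invariants hold over random compositions", {
  set.seed(42)
  for (rep in 1:25) {
    nPop <- sample(1:5, 1)
    sizes <- sample(3:120, nPop, replace = TRUE)
    n <- sum(sizes)
    k <- sample(2:min(10, n), 1)
    ids <- sprintf("s%04d", seq_len(n))
    pops <- rep(sprintf("P%d", seq_len(nPop)), sizes)
    plan <- stratifiedFolds(ids, pops, k, seed = rep)
    # disjoint folds covering all samples
    expect_identical(sort(names(foldAssignment(plan))), sort(ids))
    sz <- foldSizes(plan)
    expect_lte(diff(range(sz)), 1L)
    for (p in unique(pops)) {
      ps <- tabulate(foldAssignment(plan)[pops == p], nbins = k)
      expect_lte(diff(range(ps)), 1L)
    }
  }
  expect_error(stratifiedFolds(letters[1:5], rep("x", 5), k = 6), "exceed")
  expect_error(stratifiedFolds(letters[1:5], rep("x", 5), k = 1), ">= 2")
})

test_that("fold shuffling is seeded and population-stratified", {
  ids <- sprintf("s%03d", 1:60)
  pops <- rep(c("A", "B", "C"), each = 20)
  p1 <- stratifiedFolds(ids, pops, 4, seed = 7)
  p2 <- stratifiedFolds(ids, pops, 4, seed = 7)
  p3 <- stratifiedFolds(ids, pops, 4, seed = 8)
  expect_identical(foldAssignment(p1), foldAssignment(p2))
  expect_false(identical(foldAssignment(p1), foldAssignment(p3)))
})

test_that("pseudo-array extraction sums haplotypes and discards phase", {
  p <- simulatePanel(simConfig(nSamples = 15, nVariants = 200, seed = 31))
  full <- deriveManifest(p, 1, seed = 1)
  ps <- makePseudoArray(p, full)
  expect_identical(genotypes(ps), {
    g <- genotypes(p)
    storage.mode(g) <- "integer"
    g
  })
  expect_equal(nrow(ps@skipped), 0L)

  # a phased 1|0 genotype becomes the unphased allele count 1
  H <- matrix(c(1L, 0L, 0L, 1L), nrow = 2) # sample 1: site1 1|0, site2 0|1
  tiny <- panelFromMatrix(H, pos = c(100L, 200L))
  m <- new("ArrayManifest", sites = variants(tiny))
  expect_identical(
    as.vector(genotypes(makePseudoArray(tiny, m))), c(1L, 1L)
  )
})

test_that("manifest entries absent or allele-discordant are skipped and logged", {
  p <- simulatePanel(simConfig(nSamples = 10, nVariants = 100, seed = 33))
  gr <- variants(p)[1:5]
  ghost <- GenomicRanges::GRanges(
    seqnames = "1",
    ranges = IRanges::IRanges(
      start = max(GenomicRanges::start(variants(p))) + 1000L, width = 1L
    ),
    ref = "A", alt = "G"
  )
  bad <- variants(p)[6]
  bad$ref <- ifelse(bad$ref == "A", "C", "A") # force an allele mismatch
  man <- new("ArrayManifest", sites = sort(c(gr, ghost, bad)))
  ps <- makePseudoArray(p, man)
  expect_equal(length(variants(ps)), 5L)
  expect_setequal(ps@skipped$reason, c("absent_from_panel", "allele_mismatch"))
  expect_equal(sum(ps@skipped$reason == "absent_from_panel"), 1L)
  expect_equal(sum(ps@skipped$reason == "allele_mismatch"), 1L)
  # output sorted by position, idempotent
  expect_true(all(diff(GenomicRanges::start(variants(ps))) > 0))
  expect_identical(genotypes(makePseudoArray(p, man)), genotypes(ps))
})

test_that("reference splits partition the cohort across folds", {
  p <- simulatePanel(simConfig(nSamples = 25, nVariants = 100, seed = 35))
  plan <- stratifiedFolds(samples(p), populations(p), 5, seed = 2)
  seen <- character()
  for (f in 1:5) {
    sp <- splitReference(p, plan, f)
    expect_length(intersect(sp$test, samples(sp$reference)), 0L)
    expect_setequal(c(sp$test, samples(sp$reference)), samples(p))
    expect_equal(
      ncol(haplotypes(sp$reference)), 2L * (50L - length(sp$test))
    )
    seen <- c(seen, sp$test)
  }
  expect_setequal(seen, samples(p))
  expect_equal(length(seen), length(samples(p)))
})

test_that("reference split sizes follow the fold arithmetic", {
  co <- kgpLikeCohort()
  plan <- stratifiedFolds(co$ids, co$pops, k = 10, seed = 1)
  big <- which(foldSizes(plan) == 251L)[1]
  expect_equal(sum(foldSizes(plan)[-big]) + 251L, 2504L)
  # reference complement of a 251-sample fold has 2253 samples (4506 haplotypes)
  expect_equal(2504L - 251L, 2253L)
  expect_equal(length(foldSamples(plan, big)), 251L)
})
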