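test_that("forward-backward dosages equal exhaustive path enumeration", {
  for (s in 1:40) {
    inst <- randomHmmInstance(s)
    target <- rep(NA_integer_, inst$M)
    target[inst$typedIdx] <- inst$g
    fb <- imputeSample(
      target, inst$H, inst$pos,
      hmmParams(switchRate = inst$theta, errorRate = inst$eps)
    )
    oracle <- bruteForceDosage(
      inst$g, inst$typedIdx, inst$H, inst$pos, inst$theta, inst$eps
    )
    expect_lt(max(abs(fb - oracle)), 1e-9)
  }
})

test_that("typed-site posteriors are normalised and dosages bounded", {
  inst <- randomHmmInstance(99)
  target <- rep(NA_integer_, inst$M)
  target[inst$typedIdx] <- inst$g
  det <- imputeSample(
    target, inst$H, inst$pos,
    hmmParams(switchRate = inst$theta, errorRate = inst$eps),
    details = TRUE
  )
  # haplotype marginals of the pair posterior sum to 2 per typed site
  expect_lt(max(abs(rowSums(det$marginals) - 2)), 1e-9)
  expect_true(all(det$dosage >= 0 & det$dosage <= 2))
})

test_that("a masked site in perfect LD with a typed site is recovered", {
  set.seed(4)
  K <- 40
  M <- 6
  H <- matrix(sample(0:1, M * K, replace = TRUE), M, K)
  H[4, ] <- H[3, ] # masked site 4 duplicates typed site 3
  pos <- c(1000, 5000, 9000, 9400, 15000, 20000)
  params <- hmmParams(switchRate = 1e-6, errorRate = 1e-4)
  worst <- 0
  for (i in 1:50) {
    pair <- sample(K, 2, replace = TRUE)
    truth <- H[, pair[1]] + H[, pair[2]]
    target <- truth
    target[4] <- NA # mask the duplicated site
    d <- imputeSample(as.integer(target), H, pos, params)
    worst <- max(worst, abs(d[4] - truth[4]))
  }
  expect_lt(worst, 0.05)
})

test_that("an all-ALT reference column forces a near-2 dosage", {
  set.seed(5)
  K <- 10
  H <- matrix(sample(0:1, 5 * K, replace = TRUE), 5, K)
  H[3, ] <- 1L
  pos <- c(100, 200, 300, 400, 500)
  eps <- 1e-3
  for (g in list(c(0L, 1L, NA, 2L, 1L), c(2L, NA, NA, 0L, 0L))) {
    d <- imputeSample(g, H, pos, hmmParams(errorRate = eps))
    expect_gte(d[3], 2 * (1 - eps) - 0.01)
  }
})

test_that("dosages are invariant to reference haplotype order", {
  inst <- randomHmmInstance(7)
  target <- rep(NA_integer_, inst$M)
  target[inst$typedIdx] <- inst$g
  params <- hmmParams(switchRate = inst$theta, errorRate = inst$eps)
  d1 <- imputeSample(target, inst$H, inst$pos, params)
  set.seed(1)
  perm <- sample(ncol(inst$H))
  d2 <- imputeSample(target, inst$H[, perm], inst$pos, params)
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("with the truth in the reference and tiny error, dosage converges", {
  set.seed(8)
  K <- 20
  M <- 40
  H <- matrix(sample(0:1, M * K, replace = TRUE), M, K)
  pos <- sort(sample.int(1e6, M))
  params <- hmmParams(switchRate = 1e-8, errorRate = 1e-6)
  for (i in 1:5) {
    pair <- sample(K, 2)
    truth <- H[, pair[1]] + H[, pair[2]]
    target <- truth
    masked <- sample(M, 10)
    target[masked] <- NA
    d <- imputeSample(as.integer(target), H, pos, params)
    expect_lt(max(abs(d[masked] - truth[masked])), 0.01)
  }
})

test_that("degenerate inputs follow the contract", {
  H <- matrix(sample(0:1, 20, replace = TRUE), 10, 2)
  pos <- seq(100, 1000, by = 100)
  expect_warning(
    d <- imputeSample(rep(NA_integer_, 10), H, pos),
    "allele-frequency"
  )
  expect_equal(d, 2 * rowMeans(H))
  expect_error(
    imputeSample(rep(1L, 10), H[, 1, drop = FALSE], pos),
    "at least 2"
  )
})

test_that("cohort imputation passes typed sites through and rejects leakage", {
  p <- simulatePanel(simConfig(nSamples = 20, nVariants = 150, seed = 41))
  plan <- stratifiedFolds(samples(p), populations(p), 4, seed = 1)
  sp <- splitReference(p, plan, 1)
  full <- deriveManifest(p, 1, seed = 1)
  ps <- makePseudoArray(p, full, sp$test)

  dm <- imputeCohort(ps, sp$reference, hmmParams(switchRate = 1e-6))
  expect_true(all(typed(dm)))
  expect_equal(
    dosages(dm),
    {
      g <- genotypes(p, subset = sp$test)
      storage.mode(g) <- "double"
      g
    },
    ignore_attr = TRUE
  )

  leaky <- makePseudoArray(p, full, samples(p)[1:4])
  expect_error(imputeCohort(leaky, p), "leakage")
})

test_that("reference subsampling under the haplotype cap is seeded", {
  p <- simulatePanel(simConfig(nSamples = 30, nVariants = 120, seed = 43))
  plan <- stratifiedFolds(samples(p), populations(p), 3, seed = 1)
  sp <- splitReference(p, plan, 1)
  man <- deriveManifest(p, 0.4, seed = 2)
  ps <- makePseudoArray(p, man, sp$test)
  params <- hmmParams(switchRate = 1e-6, kCap = 16L)
  d1 <- imputeCohort(ps, sp$reference, params, seed = 5)
  d2 <- imputeCohort(ps, sp$reference, params, seed = 5)
  d3 <- imputeCohort(ps, sp$reference, params, seed = 6)
  expect_identical(dosages(d1), dosages(d2))
  expect_false(identical(dosages(d1), dosages(d3)))
})
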