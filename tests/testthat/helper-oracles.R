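# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Pearson oracle is the textbook two-pass
# formula, the HMM oracle enumerates every hidden state path explicitly, and
# the clumping oracle rescans all pairs at every step.

# textbook two-pass Pearson correlation
pearsonOracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Exhaustive path-sum oracle for the diploid haplotype-copying HMM.
# g: genotypes at typed sites; typedIdx: rows of the typed sites among the
# panel sites; H: sites x K reference alleles; pos: bp positions.
# Enumerates all K^(2T) ordered-haplotype-pair paths, computes exact
# posterior haplotype marginals per typed site, and interpolates dosages at
# untyped sites by the flanking-distance rule.
bruteForceDosage <- function(g, typedIdx, H, pos, theta, eps) {
  K <- ncol(H)
  M <- nrow(H)
  T <- length(g)
  K2 <- K * K
  stateH1 <- rep(seq_len(K), each = K)
  stateH2 <- rep(seq_len(K), times = K)

  emis <- function(t, s) {
    m <- typedIdx[t]
    p1 <- H[m, stateH1[s]] * (1 - eps) + (1 - H[m, stateH1[s]]) * eps
    p2 <- H[m, stateH2[s]] * (1 - eps) + (1 - H[m, stateH2[s]]) * eps
    if (g[t] == 0) {
      (1 - p1) * (1 - p2)
    } else if (g[t] == 1) {
      p1 * (1 - p2) + (1 - p1) * p2
    } else {
      p1 * p2
    }
  }

  paths <- as.matrix(expand.grid(rep(list(seq_len(K2)), T)))
  w <- rep(1 / K2, nrow(paths)) * emis(1, paths[, 1])
  if (T > 1) {
    for (t in 2:T) {
      gap <- pos[typedIdx[t]] - pos[typedIdx[t - 1]]
      rho <- 1 - exp(-theta * gap)
      hapTrans <- matrix(rho / K, K, K) + diag(1 - rho, K)
      TM <- outer(seq_len(K2), seq_len(K2), function(a, b) {
        hapTrans[cbind(stateH1[a], stateH1[b])] *
          hapTrans[cbind(stateH2[a], stateH2[b])]
      })
      w <- w * TM[cbind(paths[, t - 1], paths[, t])] * emis(t, paths[, t])
    }
  }
  w <- w / sum(w)

  marg <- matrix(0, T, K)
  for (t in seq_len(T)) {
    ps <- tapply(w, factor(paths[, t], levels = seq_len(K2)), sum)
    ps[is.na(ps)] <- 0
    for (s in seq_len(K2)) {
      marg[t, stateH1[s]] <- marg[t, stateH1[s]] + ps[s]
      marg[t, stateH2[s]] <- marg[t, stateH2[s]] + ps[s]
    }
  }

  dosage <- numeric(M)
  for (m in seq_len(M)) {
    after <- which(typedIdx >= m)
    before <- which(typedIdx <= m)
    if (m %in% typedIdx) {
      mv <- marg[which(typedIdx == m), ]
    } else if (length(before) == 0L) {
      mv <- marg[1, ]
    } else if (length(after) == 0L) {
      mv <- marg[T, ]
    } else {
      tl <- max(before)
      tr <- min(after)
      wR <- (pos[m] - pos[typedIdx[tl]]) /
        (pos[typedIdx[tr]] - pos[typedIdx[tl]])
      mv <- (1 - wR) * marg[tl, ] + wR * marg[tr, ]
    }
    dosage[m] <- sum(mv * (H[m, ] * (1 - 2 * eps) + eps))
  }
  dosage
}

# brute-force clumping: at every step rescan all remaining pairs
bruteClump <- function(table, geno, windowBp, r2th) {
  remaining <- seq_len(nrow(table))
  retained <- integer()
  while (length(remaining)) {
    o <- order(
      table$p[remaining], table$chrom[remaining], table$pos[remaining]
    )
    idx <- remaining[o[1]]
    retained <- c(retained, idx)
    remaining <- setdiff(remaining, idx)
    drop <- integer()
    for (j in remaining) {
      if (table$chrom[j] == table$chrom[idx] &&
        abs(table$pos[j] - table$pos[idx]) <= windowBp) {
        r <- suppressWarnings(cor(geno[idx, ], geno[j, ]))
        if (!is.na(r) && r * r >= r2th) drop <- c(drop, j)
      }
    }
    remaining <- setdiff(remaining, drop)
  }
  sort(retained)
}

# build a HaplotypePanel directly from an allele matrix (sites x haplotypes)
panelFromMatrix <- function(H, pos, chrom = "1", pops = NULL,
                            ref = NULL, alt = NULL, ids = NULL) {
  M <- nrow(H)
  N <- ncol(H) / 2L
  if (is.null(ids)) ids <- sprintf("T%03d", seq_len(N))
  if (is.null(pops)) pops <- rep("ALL", N)
  if (is.null(ref)) ref <- rep("A", M)
  if (is.null(alt)) alt <- rep("G", M)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start = pos, width = 1L),
    ref = ref, alt = alt
  )
  snpArrayEval:::newHaplotypePanel(gr, H, ids, pops)
}

# random small HMM instance for the oracle suite
randomHmmInstance <- function(seed) {
  set.seed(seed)
  K <- sample(2:3, 1)
  M <- sample(3:5, 1)
  T <- sample(2:(M - 1), 1)
  H <- matrix(sample(0:1, M * K, replace = TRUE), M, K)
  pos <- sort(sample.int(1e6, M))
  typedIdx <- sort(sample.int(M, T))
  g <- sample(0:2, T, replace = TRUE)
  theta <- 10^runif(1, -7, -5)
  eps <- 10^runif(1, -4, -1.5)
  list(K = K, M = M, H = H, pos = pos, typedIdx = typedIdx, g = g,
    theta = theta, eps = eps)
}
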