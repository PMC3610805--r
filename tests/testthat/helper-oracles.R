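# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Full-sort nearest-neighbor regression: ties at the k-th rank broken by
# ascending training index.
bruteKnnPredict <- function(trainX, trainY, testX, k, w = rep(1, ncol(trainX))) {
  apply(testX, 1, function(x) {
    d <- vapply(seq_len(nrow(trainX)), function(i)
      sum(w * abs(trainX[i, ] - x)), numeric(1))
    ord <- order(d, seq_along(d))
    mean(trainY[ord[seq_len(k)]])
  })
}

# Direct Shannon formula -sum p log2 p on the two derived allele
# distributions (A = homozygous-minor indicator, B = carries-minor indicator).
entropyOracle <- function(counts) {
  h <- function(v) {
    p <- c(mean(v == 0), mean(v == 1))
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  (h(as.integer(counts == 2)) + h(as.integer(counts >= 1))) / 2
}

# Hypergeometric tails by explicit summation of the pmf.
hyperTailsOracle <- function(N, K, n, k) {
  pmf <- function(j) choose(K, j) * choose(N - K, n - j) / choose(N, n)
  js <- max(0, n + K - N):min(K, n)
  list(pEnriched = sum(vapply(js[js >= k], pmf, numeric(1))),
       pDepleted = sum(vapply(js[js <= k], pmf, numeric(1))))
}

# Hand step-up Benjamini-Hochberg.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Small valid dataset generator used by io and property tests.
makeSmallDataset <- function(seed = 1, nPerPop = 8, nPops = 2, nGenes = 2,
                             snpsPerGene = 6, h2 = 0.5) {
  spec <- simulationSpec(nPerPop = nPerPop, nPopulations = nPops,
    nGenes = nGenes, snpsPerGene = snpsPerGene, h2 = h2, nCausal = 2,
    featureSpec = list(M = 3L, nInformative = 1L, pTagCausal = 1,
      pTagNull = 0, pNoise = 0.3),
    seed = seed)
  simulateDataset(spec)
}
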