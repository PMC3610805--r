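test_that("hypergeometric tails match explicit pmf summation for small urns", {
  # the fully-enriched worked case: all 5 draws carry the feature
  ht <- hypergeometricTest(20, 10, 5, 5)
  expect_equal(ht$pEnriched, choose(10, 5) / choose(20, 5), tolerance = 1e-12)
  set.seed(19)
  for (rep in 1:40) {
    N <- sample(5:25, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    kRange <- max(0, n + K - N):min(K, n)
    k <- if (length(kRange) == 1) kRange else sample(kRange, 1)
    got <- hypergeometricTest(N, K, n, k)
    want <- hyperTailsOracle(N, K, n, k)
    expect_equal(got$pEnriched, want$pEnriched, tolerance = 1e-10)
    expect_equal(got$pDepleted, want$pDepleted, tolerance = 1e-10)
    # the two tails overlap exactly at k
    pk <- want$pEnriched + want$pDepleted - 1
    expect_equal(pk, choose(K, k) * choose(N - K, n - k) / choose(N, n),
      tolerance = 1e-10)
  }
})

test_that("hypergeometric degenerate and boundary cases", {
  # K = 0: k must be 0 and both tails are 1
  ht0 <- hypergeometricTest(10, 0, 4, 0)
  expect_equal(ht0$pEnriched, 1)
  expect_equal(ht0$pDepleted, 1)
  # k at its minimum attainable value: upper tail is the whole distribution
  htMin <- hypergeometricTest(10, 8, 6, 4)   # k_min = 6 + 8 - 10 = 4
  expect_equal(htMin$pEnriched, 1)
  expect_error(hypergeometricTest(10, 11, 4, 2), "out-of-range")
  expect_error(hypergeometricTest(10, 4, 4, 5), "attainable")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.37), 0.37)
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(29)
  for (rep in 1:20) {
    p <- runif(sample(3:30, 1))
    q <- bhFdr(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    # monotone: larger raw p never gets smaller q
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bhFdr(c(0.5, 0)), "0, 1")
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("a feature tagging exactly the selected SNPs is called enriched", {
  set.seed(59)
  hits <- 0
  for (rep in 1:20) {
    nGenes <- 6; nSnp <- 30; nSel <- 6
    background <- setNames(lapply(seq_len(nGenes), function(g)
      sprintf("g%d_s%02d", g, seq_len(nSnp))), sprintf("gene%d", seq_len(nGenes)))
    sel <- lapply(background, function(bg) sample(bg, nSel))
    allSnps <- unlist(background)
    causal <- unlist(sel)
    fv <- cbind(
      featA = as.numeric(allSnps %in% causal),
      featB = rbinom(length(allSnps), 1, 0.3))
    rownames(fv) <- allSnps
    fm <- FeatureMatrix(fv)
    res <- featureEnrichmentAcrossGenes(list(sel), background,
      featureMatrix = fm, alpha = 0.01)
    if (res$enriched[res$feature == "featA"]) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of seeds
})

test_that("saturated selections are never called enriched", {
  background <- list(g1 = c("a", "b", "c"), g2 = c("d", "e"))
  sel <- background  # every SNP selected: k = n and K = N per feature
  fv <- cbind(f1 = c(1, 0, 1, 1, 0))
  rownames(fv) <- c("a", "b", "c", "d", "e")
  res <- featureEnrichmentAcrossGenes(list(sel), background,
    featureMatrix = FeatureMatrix(fv), alpha = 0.01)
  expect_false(any(res$enriched))
  expect_equal(res$max_q_enriched, 1)
})

test_that("a feature must clear the threshold in every partition to be called", {
  set.seed(61)
  nGenes <- 8; nSnp <- 24
  background <- setNames(lapply(seq_len(nGenes), function(g)
    sprintf("g%d_s%02d", g, seq_len(nSnp))), sprintf("gene%d", seq_len(nGenes)))
  allSnps <- unlist(background)
  causal <- unlist(lapply(background, `[`, 1:5))
  fv <- cbind(featA = as.numeric(allSnps %in% causal))
  rownames(fv) <- allSnps
  strongSel <- lapply(background, `[`, 1:5)        # selects exactly the carriers
  nullSel <- lapply(background, function(bg) sample(bg, 5))
  both <- featureEnrichmentAcrossGenes(list(strongSel, nullSel), background,
    featureMatrix = FeatureMatrix(fv), alpha = 0.01)
  one <- featureEnrichmentAcrossGenes(list(strongSel), background,
    featureMatrix = FeatureMatrix(fv), alpha = 0.01)
  expect_true(one$enriched[1])
  expect_false(both$enriched[1])   # significant in one partition only
})

test_that("selections outside the background are rejected", {
  background <- list(g1 = c("a", "b"))
  sel <- list(g1 = c("a", "z"))
  fv <- cbind(f1 = c(1, 0)); rownames(fv) <- c("a", "b")
  expect_error(featureEnrichmentAcrossGenes(list(sel), background,
    featureMatrix = FeatureMatrix(fv)), "outside background")
})

test_that("KNN-IGF mode tests feature-coefficient selections directly", {
  # three genes, three candidate features each; feature f1 always selected
  background <- list(g1 = c("f1", "f2", "f3"), g2 = c("f1", "f2", "f3"),
    g3 = c("f1", "f2", "f3"))
  sel <- list(g1 = "f1", g2 = "f1", g3 = "f1")
  res <- featureEnrichmentAcrossGenes(list(sel), background, alpha = 0.5)
  r1 <- res[res$feature == "f1", ]
  expect_equal(r1$K, 3); expect_equal(r1$k, 3); expect_equal(r1$n, 3)
  # urn: 9 gene-feature pairs, 3 carry f1, 3 drawn, all 3 are f1
  expect_equal(hypergeometricTest(9, 3, 3, 3)$pEnriched, 1 / 84,
    tolerance = 1e-12)
  expect_true(r1$max_q_enriched < 0.05)
})

test_that("selected entities are extracted from fitted models by weight", {
  enet <- new("ElasticNetModel", snpWeights = c(0.5, 0, 1e-12, -0.2),
    intercept = 0, lambda = 0.1, l1Ratio = 0.5, trainR2Cv = 0.2)
  expect_equal(selectedEntities(enet, c("s1", "s2", "s3", "s4")),
    c("s1", "s4"))
  knn <- new("KnnModel", k = 3L, snpWeights = c(1, 1),
    trainX = matrix(0, 5, 2), trainY = rnorm(5), looR2 = 0,
    alpha = c(0.7, 0, 0.3))
  expect_equal(selectedEntities(knn, c("f1", "f2", "f3")), c("f1", "f3"))
})

test_that("gene-set enrichment flags a planted term and respects the universe", {
  universe <- sprintf("g%02d", 1:40)
  selected <- universe[1:10]
  ann <- rbind(
    data.frame(entity = universe[1:12], term = "planted"),
    data.frame(entity = universe[sample(1:40, 15)], term = "random"))
  res <- geneSetEnrichment(selected, universe, ann, alpha = 0.05)
  planted <- res[res$term == "planted", ]
  oracle <- hyperTailsOracle(40, 12, 10, sum(selected %in% universe[1:12]))
  expect_equal(planted$p_enriched, oracle$pEnriched, tolerance = 1e-10)
  expect_error(geneSetEnrichment(c("zz"), universe, ann), "outside universe")
})
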