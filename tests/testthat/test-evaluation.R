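mkPops <- function(sizes) {
  labs <- rep(names(sizes), unname(sizes))
  setNames(factor(labs), sprintf("i%03d", seq_along(labs)))
}

test_that("cross-pop folds hold out one whole population each", {
  pops <- mkPops(c(CEU = 10, YRI = 12, CHB = 8, JPT = 9))
  fa <- makeCvFolds(pops, "cross_pop", seed = 1)
  expect_length(fa@folds, 4)
  for (p in levels(pops)) {
    fold <- fa@folds[[p]]
    expect_setequal(fold$test, names(pops)[pops == p])
    expect_setequal(fold$train, names(pops)[pops != p])
  }
})

test_that("mixed-pop folds partition everyone with per-population balance", {
  pops <- mkPops(c(A = 23, B = 31, C = 17))
  fa <- makeCvFolds(pops, "mixed_pop", nFolds = 5, seed = 9)
  tests <- lapply(fa@folds, `[[`, "test")
  expect_setequal(unlist(tests), names(pops))
  expect_equal(sum(lengths(tests)), length(pops))  # disjoint partition
  for (p in levels(pops)) {
    perFold <- vapply(tests, function(t) sum(pops[t] == p), numeric(1))
    expect_lte(max(perFold) - min(perFold), 1)
  }
  # deterministic given the seed
  fa2 <- makeCvFolds(pops, "mixed_pop", nFolds = 5, seed = 9)
  expect_identical(fa@folds, fa2@folds)
})

test_that("intra-pop folds never mix populations", {
  pops <- mkPops(c(A = 11, B = 14))
  fa <- makeCvFolds(pops, "intra_pop", nFolds = 5, seed = 2)
  expect_length(fa@folds, 10)
  for (fold in fa@folds) {
    popSet <- unique(pops[c(fold$train, fold$test)])
    expect_length(popSet, 1)
  }
  # each population's test sets partition that population
  for (p in levels(pops)) {
    tests <- unlist(lapply(fa@folds[grep(paste0("^", p, "_"),
      names(fa@folds))], `[[`, "test"))
    expect_setequal(tests, names(pops)[pops == p])
  }
  expect_error(makeCvFolds(mkPops(c(A = 3)), "intra_pop", nFolds = 5),
    "fewer individuals")
})

test_that("R-squared matches its closed forms and shift invariance", {
  y <- c(1, 2, 3, 4)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 4)), 0)
  expect_equal(rSquared(c(0, 1), c(1, 0)), -3)
  set.seed(3)
  yy <- rnorm(10); pp <- rnorm(10)
  expect_equal(rSquared(yy + 7, pp + 7), rSquared(yy, pp))
  expect_error(rSquared(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("the CV loop yields one row per gene, fold and model, deterministically", {
  sim <- makeSmallDataset(12, nPerPop = 10, nPops = 4, nGenes = 1)
  res <- runGeneCv(sim$dataset, models = c("single", "enet", "knn"),
    scheme = "cross_pop", config = list(kMax = 8), seed = 5)
  expect_equal(nrow(res$summary), 1 * 4 * 3)
  expect_false(any(is.na(res$summary$test_r2)))
  res2 <- runGeneCv(sim$dataset, models = c("single", "enet", "knn"),
    scheme = "cross_pop", config = list(kMax = 8), seed = 5)
  expect_identical(res$summary, res2$summary)
  # test individuals are disjoint from training in the predictions table
  for (fname in names(res$folds@folds)) {
    fold <- res$folds@folds[[fname]]
    predIds <- res$predictions$individual_id[res$predictions$fold == fname]
    expect_true(all(predIds %in% fold$test))
    expect_length(intersect(predIds, fold$train), 0)
  }
})

test_that("robustness fraction matches hand counts and is monotone in the threshold", {
  expect_equal(robustnessFraction(c(0.2, 0.4), c(0.1, 0.1), 0.5), 0.5)
  expect_equal(robustnessFraction(c(0.2, 0.4), c(0.0, 0.1), 0), 1)
  tr <- c(0.3, 0.2, 0.5)
  expect_equal(robustnessFraction(tr, tr, 1), 1)
  expect_error(robustnessFraction(c(0.01, 0.02), c(1, 1), 0.5), "empty gene set")
  set.seed(41)
  for (rep in 1:20) {
    tr <- runif(30, 0, 0.6); te <- tr + rnorm(30, sd = 0.2)
    fr <- vapply(seq(0, 1, by = 0.1), function(th)
      robustnessFraction(tr, te, th), numeric(1))
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("concordance statistics and training-R2 bins behave as defined", {
  tr <- c(0.05, 0.15, 0.22, 0.28, 0.4)
  out <- concordanceAndBins(tr, tr, binEdges = seq(0, 0.5, 0.1))
  expect_equal(out$pearson, 1)
  expect_equal(out$spearman, 1)
  expect_equal(concordanceAndBins(tr, -tr)$pearson, -1)
  bin23 <- out$bins[out$bins$bin == "[0.2,0.3)", ]
  expect_equal(bin23$n, 2L)
  expect_equal(bin23$mean_train_r2, mean(c(0.22, 0.28)))
  empty <- out$bins[out$bins$bin == "[0.4,0.5]", ]
  expect_equal(empty$n, 1L)  # 0.4 falls in the right-closed last bin
})

test_that("top-gene overlaps equal brute-force set intersections", {
  lists <- list(knn = c("g1", "g2", "g3", "g4"),
    enet = c("g2", "g1", "g5", "g3"), single = c("g9", "g2", "g1", "g7"))
  ov <- modelOverlap(lists, 3)
  brute <- function(a, b, n) length(intersect(lists[[a]][1:n], lists[[b]][1:n]))
  for (r in seq_len(nrow(ov$pairwise)))
    expect_equal(ov$pairwise$overlap[r],
      brute(ov$pairwise$model_a[r], ov$pairwise$model_b[r], 3))
  expect_equal(ov$all,
    length(Reduce(intersect, lapply(lists, `[`, 1:3))))
  ident <- list(a = letters[1:10], b = letters[1:10])
  expect_equal(modelOverlap(ident, 10)$all, 10)
  disj <- list(a = letters[1:5], b = letters[6:10])
  expect_equal(modelOverlap(disj, 5)$all, 0)
  expect_error(modelOverlap(disj, 6), "exceeds")
})

test_that("gene characterization separates groups it should and not ones it should not", {
  set.seed(77)
  same <- data.frame(k = rnorm(40, 10, 2))
  mask <- rep(c(TRUE, FALSE), 20)
  outSame <- characterizeGenes(same, mask)
  expect_gt(outSame$p_value, 0.05)
  far <- data.frame(x = c(rnorm(50, 0), rnorm(50, 5)))
  outFar <- characterizeGenes(far, rep(c(TRUE, FALSE), each = 50))
  expect_lt(outFar$p_value, 1e-10)
  constant <- data.frame(c0 = rep(1, 10))
  expect_equal(characterizeGenes(constant, rep(c(TRUE, FALSE), 5))$p_value, 1)
  # coefficient of variation closed form on {2, 4}
  expect_equal(coefficientOfVariation(c(2, 4)), sqrt(2) / 3, tolerance = 1e-12)
})
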