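mkTask <- function(X, y, F = matrix(1, ncol(X), 1,
                     dimnames = list(colnames(X), "f1"))) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("i%02d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("s%02d", seq_len(ncol(X)))
  rownames(F) <- colnames(X)
  storage.mode(X) <- "double"
  new("GeneTask", geneId = "g", y = setNames(y, rownames(X)), X = X, F = F,
    populations = setNames(factor(rep("A", nrow(X))), rownames(X)),
    constantSnps = apply(X, 2, function(v) all(v == v[1])))
}

test_that("single best-SNP recovers an exact linear signal", {
  set.seed(1)
  X <- cbind(s1 = rep(0:2, each = 5), s2 = sample(0:2, 15, TRUE),
    s3 = sample(0:2, 15, TRUE))
  y <- 2 * X[, "s1"]
  m <- fitSingleBestSnp(mkTask(X, y))
  expect_identical(m@snpId, "s1")
  expect_equal(m@slope, 2)
  expect_equal(m@intercept, 0)
  expect_equal(rSquared(y, predict(m, mkTask(X, y)@X)), 1)
})

test_that("single best-SNP ties go to the lower column index and shifts move only the intercept", {
  X <- cbind(s1 = c(0, 1, 2, 0, 1, 2), s2 = c(0, 1, 2, 0, 1, 2),
    s3 = c(2, 1, 0, 2, 1, 0))
  y <- c(0.1, 1, 2, 0, 1.1, 2.2)
  m <- fitSingleBestSnp(mkTask(X, y))
  expect_identical(m@snpIndex, 1L)  # s1 and s2 perfectly tied
  m2 <- fitSingleBestSnp(mkTask(X, y + 5))
  expect_identical(m2@snpId, m@snpId)
  expect_equal(m2@slope, m@slope)
  expect_equal(m2@intercept, m@intercept + 5)
  # all-constant SNPs are an error
  Xc <- matrix(1, 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fitSingleBestSnp(mkTask(Xc, y)), "no informative SNP")
})

test_that("under a pure null the single-SNP model has near-zero expected test R2", {
  set.seed(99)
  r2s <- replicate(50, {
    X <- matrix(rbinom(200 * 10, 2, 0.3), 200, 10)
    y <- rnorm(200)
    tr <- 1:150; te <- 151:200
    m <- fitSingleBestSnp(mkTask(X[tr, ], y[tr]))
    rSquared(y[te], predict(m, mkTask(X, y)@X[te, ]))
  })
  expect_lt(abs(mean(r2s)), 0.05)
})

test_that("elastic net at the largest penalty predicts the training mean", {
  set.seed(3)
  X <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8)
  y <- rnorm(60) + X[, 1]
  task <- mkTask(X, y)
  full <- glmnet::glmnet(task@X, task@y, alpha = 0.5)
  w <- coef(full, s = max(full$lambda))
  expect_true(all(abs(w[-1]) < 1e-10))
  expect_equal(w[1], mean(y), tolerance = 1e-6)
})

test_that("elastic net recovers planted coefficient signs and reports honest CV R2", {
  set.seed(17)
  hits <- 0
  optimism <- numeric(20)
  for (rep in 1:20) {
    X <- matrix(rbinom(300 * 12, 2, runif(12, 0.2, 0.5)), 300, 12, byrow = TRUE)
    beta <- numeric(12); beta[c(2, 5, 9)] <- c(1.5, -2, 1)
    y <- drop(X %*% beta)
    task <- mkTask(X, y)
    m <- fitElasticNet(task, seed = rep)
    top3 <- order(abs(m@snpWeights), decreasing = TRUE)[1:3]
    if (setequal(top3, c(2, 5, 9)) &&
        all(sign(m@snpWeights[c(2, 5, 9)]) == sign(beta[c(2, 5, 9)])))
      hits <- hits + 1
    inSample <- rSquared(task@y, predict(m, task@X))
    optimism[rep] <- inSample - m@trainR2Cv
  }
  expect_gte(hits, 19)            # >= 95% of 20 seeds
  expect_gte(mean(optimism), 0)   # internal-CV R2 does not exceed in-sample on average
})

test_that("weighted L1 distances match hand-computed values", {
  Xa <- rbind(a = c(0, 2, 1)); Xb <- rbind(b = c(1, 0, 1))
  expect_equal(knnDistanceMatrix(Xa, Xb)[1, 1], 3)
  expect_equal(knnDistanceMatrix(Xa, Xb, c(2, 0, 1))[1, 1], 2)
  expect_equal(knnDistanceMatrix(Xa, Xa)[1, 1], 0)
  expect_error(knnDistanceMatrix(Xa, Xb, c(-1, 0, 1)), "negative")
  # integer distances under all-ones weights on {0,1,2} data
  set.seed(5)
  X <- matrix(sample(0:2, 40, TRUE), 8, 5)
  D <- knnDistanceMatrix(X, X)
  expect_true(all(D == round(D)))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("simple KNN selects k by exhaustive leave-one-out and hits its limits", {
  set.seed(23)
  # two genotype clusters with distinct response levels
  X <- rbind(matrix(0L, 10, 4), matrix(2L, 10, 4))
  storage.mode(X) <- "double"
  y <- c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  task <- mkTask(X, y)
  m <- fitSimpleKnn(task)
  # oracle: brute-force LOO R2 for every k
  bruteLoo <- vapply(seq_len(19), function(k) {
    preds <- vapply(seq_len(20), function(i)
      bruteKnnPredict(task@X[-i, , drop = FALSE], y[-i],
        task@X[i, , drop = FALSE], k), numeric(1))
    rSquared(y, preds)
  }, numeric(1))
  expect_equal(m@looR2, max(bruteLoo))
  expect_equal(m@k, which.max(bruteLoo))
  # k = N-1: every LOO prediction is the mean of the other responses
  loo <- cisxpred:::looKnnPredictions(knnDistanceMatrix(task@X, task@X), y, 19)
  expect_equal(loo[19, ], vapply(1:20, function(i) mean(y[-i]), numeric(1)))
})

test_that("KNN prediction equals the brute-force full-sort oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:25, 1); d <- sample(3:10, 1)
    X <- matrix(sample(0:2, n * d, TRUE), n, d)
    y <- rnorm(n)
    Xt <- matrix(sample(0:2, 5 * d, TRUE), 5, d)
    task <- mkTask(X, y)
    k <- sample(seq_len(n - 1), 1)
    model <- new("KnnModel", k = as.integer(k), snpWeights = rep(1, d),
      trainX = task@X, trainY = task@y, looR2 = 0, alpha = numeric(0))
    expect_equal(unname(predictKnn(model, Xt)),
      unname(bruteKnnPredict(task@X, y, Xt, k)))
  }
  # k = 1 with an exact genotype match returns that individual's response
  X <- rbind(c(0, 0), c(2, 2), c(1, 1)); y <- c(1, 2, 3)
  task <- mkTask(X, y)
  m1 <- new("KnnModel", k = 1L, snpWeights = c(1, 1), trainX = task@X,
    trainY = task@y, looR2 = 0, alpha = numeric(0))
  expect_equal(unname(predictKnn(m1, rbind(c(2, 2)))), 2)
  # k = N returns the training mean everywhere
  mN <- new("KnnModel", k = 3L, snpWeights = c(1, 1), trainX = task@X,
    trainY = task@y, looR2 = 0, alpha = numeric(0))
  expect_equal(unname(predictKnn(mN, rbind(c(0, 1), c(2, 0)))), rep(2, 2))
})

test_that("combining predictions is the element-wise mean", {
  expect_equal(combinePredictions(c(1, 3), c(3, 1)), c(2, 2))
  expect_equal(combinePredictions(c(1, 2), c(1, 2)), c(1, 2))
  expect_error(combinePredictions(1:3, 1:2), "mismatch")
})
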