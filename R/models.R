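## The four per-gene predictors: single best-SNP, elastic net, simple KNN and
## the averaged combination. All share a fit-on-GeneTask / predict-on-matrix
## contract.

#' Proportion of variance explained
#'
#' \code{1 - sum((y - yhat)^2) / sum((y - mean(y))^2)}, with the mean taken on
#' the evaluated set itself, so training and test sets are each scored against
#' their own variance. May be negative out of sample.
#'
#' @param yTrue observed values (length >= 2, non-zero variance)
#' @param yPred predictions, same length
#' @return R-squared
#' @export
rSquared <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2) stop("need at least 2 observations")
  sst <- sum((yTrue - mean(yTrue))^2)
  if (sst == 0) stop("zero variance in observed values")
  1 - sum((yTrue - yPred)^2) / sst
}

#' Fit the single best-SNP model
#'
#' Selects the cis-SNP with the highest absolute Pearson correlation to the
#' response among non-constant SNPs (ties broken toward the lower column
#' index) and fits ordinary least squares of the response on its allele
#' counts.
#'
#' @param task a \linkS4class{GeneTask} restricted to training individuals
#' @param signed if TRUE select by signed rather than absolute correlation
#' @return a \linkS4class{SingleSnpModel}
#' @export
fitSingleBestSnp <- function(task, signed = FALSE) {
  X <- task@X; y <- task@y
  if (length(y) < 3) stop("need at least 3 training individuals")
  vars <- apply(X, 2, var)
  usable <- which(vars > 0)
  if (!length(usable)) stop("no informative SNP (all cis-SNPs constant)")
  if (var(y) == 0) stop("degenerate response (zero variance)")
  rs <- suppressWarnings(as.vector(cor(X[, usable, drop = FALSE], y)))
  score <- if (signed) rs else abs(rs)
  best <- usable[which.max(score)]   # which.max: first max -> lowest index
  x <- X[, best]
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  new("SingleSnpModel", snpId = colnames(X)[best], snpIndex = as.integer(best),
    slope = slope, intercept = intercept,
    trainCorr = rs[match(best, usable)])
}

#' @describeIn fitSingleBestSnp predict from a cis-genotype matrix
#' @param object fitted model
#' @param newX individuals x cis-SNPs matrix (same columns as the task)
#' @export
setMethod("predict", "SingleSnpModel", function(object, newX) {
  object@intercept + object@slope * newX[, object@snpIndex]
})

#' Fit the elastic-net multi-SNP model
#'
#' Regresses the response on all cis-SNP allele counts with an elastic-net
#' penalty (via glmnet). The penalty strength lambda is chosen by internal
#' cross-validation on the training set: the lambda path is glmnet's own
#' (\code{nLambda} log-spaced values down to \code{lambdaMinRatio} of the
#' maximal lambda), each internal fold is scored by validation R-squared
#' against the validation set's own variance, and the lambda maximizing the
#' mean validation R-squared wins. Weights are then refit on the full
#' training set at that lambda. The reported training R-squared
#' (\code{trainR2Cv}) is the internal-CV mean, not the in-sample value.
#'
#' @param task a \linkS4class{GeneTask} restricted to training individuals
#' @param internalFolds number of internal CV folds (default 5)
#' @param l1Ratio elastic-net mixing parameter in [0,1] (default 0.5)
#' @param nLambda,lambdaMinRatio lambda path controls
#' @param seed integer seed for the internal fold assignment
#' @return an \linkS4class{ElasticNetModel}
#' @export
fitElasticNet <- function(task, internalFolds = 5L, l1Ratio = 0.5,
                          nLambda = 50L, lambdaMinRatio = 1e-3, seed = 1L) {
  X <- task@X; y <- task@y
  n <- length(y)
  if (n < internalFolds) stop("fewer training individuals than internal folds")
  if (var(y) == 0) stop("degenerate response (zero variance)")
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, `.pad` = 0)  # glmnet needs >= 2 columns
  full <- glmnet::glmnet(X, y, alpha = l1Ratio, nlambda = nLambda,
    lambda.min.ratio = lambdaMinRatio, standardize = TRUE)
  lambdas <- full$lambda
  foldId <- withSeed(seed, sample(rep_len(seq_len(internalFolds), n)))
  r2sum <- matrix(NA_real_, internalFolds, length(lambdas))
  for (f in seq_len(internalFolds)) {
    holdIn <- foldId != f
    fit <- glmnet::glmnet(X[holdIn, , drop = FALSE], y[holdIn],
      alpha = l1Ratio, lambda = lambdas, standardize = TRUE)
    pred <- predict(fit, X[!holdIn, , drop = FALSE], s = lambdas)
    yv <- y[!holdIn]
    sst <- sum((yv - mean(yv))^2)
    if (sst == 0) next  # degenerate validation fold carries no information
    r2sum[f, seq_len(ncol(pred))] <-
      1 - colSums((yv - pred)^2) / sst
  }
  meanR2 <- colMeans(r2sum, na.rm = TRUE)
  best <- which.max(meanR2)
  lambda <- lambdas[best]
  w <- as.vector(coef(full, s = lambda))
  intercept <- w[1]
  snpW <- w[-1]
  if (padded) snpW <- snpW[-length(snpW)]
  new("ElasticNetModel", snpWeights = snpW, intercept = intercept,
    lambda = lambda, l1Ratio = l1Ratio, trainR2Cv = meanR2[best])
}

#' @describeIn fitElasticNet predict from a cis-genotype matrix
#' @param object fitted model
#' @param newX individuals x cis-SNPs matrix
#' @export
setMethod("predict", "ElasticNetModel", function(object, newX) {
  drop(newX %*% object@snpWeights) + object@intercept
})

#' Weighted L1 genotype distance matrix
#'
#' \code{d(a,b) = sum_i w_i |X_a,i - X_b,i|}: the sum of absolute
#' differences in minor-allele counts over cis-SNPs, each SNP weighted by a
#' nonnegative weight (all ones for the simple KNN metric).
#'
#' @param Xa,Xb individuals x SNPs matrices with equal column counts
#' @param snpWeights nonnegative weights, one per SNP (default all ones)
#' @return \code{nrow(Xa)} x \code{nrow(Xb)} distance matrix
#' @export
knnDistanceMatrix <- function(Xa, Xb, snpWeights = rep(1, ncol(Xa))) {
  if (ncol(Xa) != ncol(Xb)) stop("column count mismatch")
  if (length(snpWeights) != ncol(Xa)) stop("snpWeights length mismatch")
  if (any(snpWeights < 0)) stop("negative SNP weight")
  D <- matrix(0, nrow(Xa), nrow(Xb))
  for (i in which(snpWeights > 0))
    D <- D + snpWeights[i] * abs(outer(Xa[, i], Xb[, i], "-"))
  dimnames(D) <- list(rownames(Xa), rownames(Xb))
  D
}

## Leave-one-out KNN predictions for every k at once.
## Returns a max(kGrid) x n matrix: row k = LOO prediction with k neighbors.
## Neighbor ties are broken by ascending individual index (stable order()).
looKnnPredictions <- function(D, y, kMax) {
  n <- length(y)
  out <- matrix(NA_real_, kMax, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(D[i, others], others)]
    out[, i] <- cumsum(y[ord][seq_len(kMax)]) / seq_len(kMax)
  }
  out
}

#' Fit the simple KNN model
#'
#' For each candidate k, every training individual is predicted as the mean
#' response of its k nearest other training individuals under the (weighted)
#' L1 allele-count metric, and k is chosen to maximize this leave-one-out
#' R-squared (ties toward the smallest k). Neighbor ties at the k-th rank are
#' broken by ascending individual index, making runs reproducible.
#'
#' @param task a \linkS4class{GeneTask} restricted to training individuals
#' @param kGrid candidate neighbor counts (default 1..min(50, N-1))
#' @param snpWeights metric weights (default all ones = simple KNN)
#' @param alpha genomic-feature coefficients to record on the model (used by
#'   the metric-learning extension; length 0 for simple KNN)
#' @return a \linkS4class{KnnModel}
#' @export
fitSimpleKnn <- function(task, kGrid = NULL, snpWeights = NULL,
                         alpha = numeric(0)) {
  X <- task@X; y <- task@y
  n <- length(y)
  if (n < 3) stop("need at least 3 training individuals")
  if (is.null(kGrid)) kGrid <- seq_len(min(50L, n - 1L))
  kGrid <- kGrid[kGrid >= 1 & kGrid <= n - 1]
  if (!length(kGrid)) stop("empty k grid")
  if (is.null(snpWeights)) snpWeights <- rep(1, ncol(X))
  D <- knnDistanceMatrix(X, X, snpWeights)
  loo <- looKnnPredictions(D, y, max(kGrid))
  r2s <- vapply(kGrid, function(k) rSquared(y, loo[k, ]), numeric(1))
  best <- kGrid[which.max(r2s)]   # first max -> smallest k on ties
  new("KnnModel", k = as.integer(best), snpWeights = snpWeights,
    trainX = X, trainY = y, looR2 = max(r2s), alpha = alpha)
}

#' KNN prediction for new individuals
#'
#' Each test individual is predicted as the unweighted mean training response
#' of its k nearest training individuals under the model's weighted L1
#' metric; distance ties are broken by ascending training-individual index.
#'
#' @param model a \linkS4class{KnnModel}
#' @param newX individuals x cis-SNPs matrix (columns as in training)
#' @return numeric predictions, one per row of \code{newX}
#' @export
predictKnn <- function(model, newX) {
  if (ncol(newX) != ncol(model@trainX)) stop("column count mismatch")
  n <- nrow(model@trainX)
  if (model@k > n) stop("k exceeds number of training individuals")
  D <- knnDistanceMatrix(newX, model@trainX, model@snpWeights)
  apply(D, 1, function(d) {
    ord <- order(d, seq_len(n))
    mean(model@trainY[ord[seq_len(model@k)]])
  })
}

#' @describeIn predictKnn method dispatch for \code{predict}
#' @param object fitted model
#' @export
setMethod("predict", "KnnModel", function(object, newX) predictKnn(object, newX))

#' Average two models' predictions
#'
#' The combined multi-SNP model: element-wise arithmetic mean of the KNN and
#' elastic-net predictions for each individual.
#'
#' @param predKnn,predLinear equal-length numeric prediction vectors
#' @return their element-wise mean
#' @export
combinePredictions <- function(predKnn, predLinear) {
  if (length(predKnn) != length(predLinear)) stop("prediction length mismatch")
  (predKnn + predLinear) / 2
}

## Evaluate an expression under a temporary RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
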