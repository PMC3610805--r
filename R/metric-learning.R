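## Metric learning for the extended KNN (KNN-IGF): a genomic-feature
## coefficient vector alpha induces per-SNP distance weights; alpha is learned
## by a greedy search that maximizes the metric-to-response correlation (MRC)
## over training pairs, after which k is selected exactly as in simple KNN.

#' Metric-learning configuration
#'
#' @param rMax pool truncation size: the number of best predictors kept each
#'   iteration (pairwise combinations give a pool of rMax^2). Default 5.
#' @param maxIterations safety cap on greedy iterations (default 50)
#' @param convergenceTol stop when the best objective improves by less than
#'   this (default 1e-6)
#' @param kGrid candidate neighbor counts for the final k selection (NULL =
#'   1..min(50, N-1))
#' @param correlation "pearson" (default) or "spearman" for the MRC objective
#' @param standardizeFeatures scale continuous feature columns to unit
#'   variance before the search (default FALSE; indicator features need none)
#' @return a list of class "MetricLearningConfig"
#' @export
metricLearningConfig <- function(rMax = 5L, maxIterations = 50L,
                                 convergenceTol = 1e-6, kGrid = NULL,
                                 correlation = c("pearson", "spearman"),
                                 standardizeFeatures = FALSE) {
  stopifnot(rMax >= 1)
  structure(list(rMax = as.integer(rMax),
    maxIterations = as.integer(maxIterations),
    convergenceTol = convergenceTol, kGrid = kGrid,
    correlation = match.arg(correlation),
    standardizeFeatures = standardizeFeatures),
    class = "MetricLearningConfig")
}

#' SNP weights induced by genomic-feature coefficients
#'
#' \code{w_i = sum_m alpha_m * f_im}: each SNP's metric weight is the
#' alpha-weighted sum of its genomic-feature values. Negative induced weights
#' are clamped to zero, since an L1 metric requires nonnegative weights.
#'
#' @param alpha feature coefficient vector (length M)
#' @param Fgene cis-SNPs x features matrix (D x M)
#' @return nonnegative weight vector of length D
#' @export
inducedSnpWeights <- function(alpha, Fgene) {
  if (length(alpha) != ncol(Fgene)) stop("alpha length must equal feature count")
  pmax(drop(Fgene %*% alpha), 0)
}

#' Metric-to-response correlation objective
#'
#' The correlation, over all unordered training pairs a < b, between the
#' metric distances d(a,b) and the response gaps |y_a - y_b|. A metric under
#' which nearby individuals have similar expression scores near +1. Constant
#' pair distances (or constant response gaps) carry no metric information and
#' score 0, with a warning.
#'
#' @param distanceMatrix symmetric individuals x individuals distance matrix
#' @param y response vector over the same individuals (length >= 3)
#' @param correlation "pearson" or "spearman"
#' @return objective value in [-1, 1]
#' @export
mrcObjective <- function(distanceMatrix, y,
                         correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  n <- length(y)
  if (n < 3) stop("need at least 3 individuals")
  lo <- lower.tri(distanceMatrix)
  dPairs <- distanceMatrix[lo]
  gPairs <- abs(outer(y, y, "-"))[lo]
  pairCorrelation(dPairs, gPairs, correlation)
}

pairCorrelation <- function(dPairs, gPairs, correlation = "pearson") {
  if (sd(dPairs) == 0 || sd(gPairs) == 0) {
    warning("degenerate metric or response: zero variance across pairs")
    return(0)
  }
  cor(dPairs, gPairs, method = correlation)
}

## Npairs x D matrix of per-SNP absolute count differences over pairs a<b,
## so the pair-distance vector for any weight vector w is a single P %*% w.
pairAbsDiff <- function(X) {
  n <- nrow(X)
  lo <- lower.tri(matrix(0, n, n))
  vapply(seq_len(ncol(X)), function(j) abs(outer(X[, j], X[, j], "-"))[lo],
    numeric(sum(lo)))
}

#' Combine two predictors of the greedy pool
#'
#' Objective-weighted convex combination: \code{alpha_new =
#' (g_i alpha_i + g_j alpha_j) / (g_i + g_j)} with \code{g = max(f, 1e-6)},
#' so a strong predictor dominates a weak one and non-positive objectives are
#' floored rather than flipping the weighting. The returned predictor's
#' objective is NA; callers re-evaluate it before use.
#'
#' @param pi,pj \linkS4class{Predictor} objects with evaluated objectives
#' @return a new \linkS4class{Predictor} (objective NA)
#' @export
combinePredictors <- function(pi, pj) {
  if (is.na(pi@objective) || is.na(pj@objective))
    stop("both predictors must have evaluated objectives")
  gi <- max(pi@objective, 1e-6)
  gj <- max(pj@objective, 1e-6)
  new("Predictor", alpha = (gi * pi@alpha + gj * pj@alpha) / (gi + gj),
    objective = NA_real_)
}

#' Greedy search for the genomic-feature metric
#'
#' Starts from M one-hot predictors (one per genomic feature), then
#' iteratively keeps the rMax best by MRC objective and replaces the pool
#' with all rMax^2 pairwise objective-weighted combinations (self-pairs
#' included, so the incumbent is always retained and the best objective can
#' never decrease). Stops when the best objective improves by less than
#' \code{convergenceTol} or after \code{maxIterations}.
#'
#' @param task a \linkS4class{GeneTask} restricted to training individuals
#' @param config a \code{\link{metricLearningConfig}}
#' @return list with \code{alpha} (best-ever coefficients), \code{objective}
#'   (its MRC value) and \code{history} (best objective per iteration,
#'   non-decreasing)
#' @export
greedyMetricLearning <- function(task, config = metricLearningConfig()) {
  Fg <- task@F
  M <- ncol(Fg)
  if (M == 0) stop("no genomic features")
  if (length(task@y) < 3) stop("need at least 3 training individuals")
  if (config$standardizeFeatures) {
    sds <- apply(Fg, 2, sd)
    Fg <- sweep(Fg, 2, ifelse(sds > 0, sds, 1), "/")
  }
  P <- pairAbsDiff(task@X)
  gPairs <- abs(outer(task@y, task@y, "-"))[lower.tri(diag(length(task@y)))]
  evalAlpha <- function(alpha) {
    w <- pmax(drop(Fg %*% alpha), 0)
    d <- drop(P %*% w)
    if (sd(d) == 0 || sd(gPairs) == 0) return(0)
    cor(d, gPairs, method = config$correlation)
  }
  alphas <- lapply(seq_len(M), function(m) { a <- numeric(M); a[m] <- 1; a })
  fs <- vapply(alphas, evalAlpha, numeric(1))
  bestIdx <- which.max(fs)
  bestAlpha <- alphas[[bestIdx]]
  bestF <- fs[bestIdx]
  history <- bestF
  for (iter in seq_len(config$maxIterations)) {
    keep <- order(fs, decreasing = TRUE)[seq_len(min(config$rMax, length(fs)))]
    topA <- alphas[keep]
    topG <- pmax(fs[keep], 1e-6)
    newAlphas <- vector("list", length(keep)^2)
    idx <- 1L
    for (i in seq_along(keep)) for (j in seq_along(keep)) {
      newAlphas[[idx]] <- (topG[i] * topA[[i]] + topG[j] * topA[[j]]) /
        (topG[i] + topG[j])
      idx <- idx + 1L
    }
    alphas <- newAlphas
    fs <- vapply(alphas, evalAlpha, numeric(1))
    newBest <- max(fs)
    if (newBest > bestF) {
      bestF <- newBest
      bestAlpha <- alphas[[which.max(fs)]]
    }
    history <- c(history, bestF)
    if (newBest - history[length(history) - 1] < config$convergenceTol) break
  }
  list(alpha = bestAlpha, objective = bestF, history = history)
}

#' Fit the extended KNN with learned genomic-feature metric (KNN-IGF)
#'
#' Runs \code{\link{greedyMetricLearning}} to learn the feature coefficient
#' vector alpha, induces per-SNP weights, then selects k by leave-one-out
#' exactly as \code{\link{fitSimpleKnn}} does, under the learned weighted
#' metric. The k selection is deliberately detached from the metric learning
#' (the MRC objective does not involve k). If the learned alpha induces
#' all-zero SNP weights (completely uninformative annotations), the metric
#' falls back to the unweighted one with a warning.
#'
#' @param task a \linkS4class{GeneTask} restricted to training individuals
#' @param config a \code{\link{metricLearningConfig}}
#' @return a \linkS4class{KnnModel} whose \code{alpha} slot holds the learned
#'   feature coefficients
#' @export
fitKnnIgf <- function(task, config = metricLearningConfig()) {
  fit <- greedyMetricLearning(task, config)
  w <- inducedSnpWeights(fit$alpha, task@F)
  if (all(w == 0)) {
    warning("learned metric induces all-zero SNP weights; falling back to unweighted metric")
    w <- rep(1, ncol(task@X))
  }
  fitSimpleKnn(task, kGrid = config$kGrid, snpWeights = w, alpha = fit$alpha)
}
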