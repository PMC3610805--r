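## Cross-validation fold construction for the three population-aware schemes,
## the gene x model x fold evaluation loop, and the robustness statistics.

#' Build cross-validation folds under a population-aware scheme
#'
#' Three schemes: \describe{
#'   \item{cross_pop}{one fold per population; the test set is that entire
#'     population and the training set is the union of all the others.}
#'   \item{mixed_pop}{individuals are partitioned into \code{nFolds}
#'     near-equal test sets, stratified by population so each fold's
#'     population composition matches the global one to within one
#'     individual; each fold trains on the other nFolds-1 sets.}
#'   \item{intra_pop}{a separate \code{nFolds}-fold partition within each
#'     population; training individuals always come from the test
#'     individuals' own population.}}
#'
#' @param populations named factor of population labels
#' @param scheme "cross_pop", "mixed_pop" or "intra_pop"
#' @param nFolds folds per partition for mixed_pop / intra_pop (default 5)
#' @param seed integer seed; fold assignment is deterministic given it
#' @param stratified for mixed_pop: stratify by population (default TRUE);
#'   FALSE gives a fully random partition
#' @return a \linkS4class{FoldAssignment}
#' @export
makeCvFolds <- function(populations, scheme = c("cross_pop", "mixed_pop",
                        "intra_pop"), nFolds = 5L, seed = 1L,
                        stratified = TRUE) {
  scheme <- match.arg(scheme)
  ids <- names(populations)
  if (is.null(ids)) stop("populations must be a named factor")
  pops <- droplevels(as.factor(populations))
  folds <- list()
  if (scheme == "cross_pop") {
    if (nlevels(pops) < 2) stop("cross_pop needs at least 2 populations")
    for (p in levels(pops))
      folds[[p]] <- list(train = ids[pops != p], test = ids[pops == p])
  } else if (scheme == "mixed_pop") {
    lab <- withSeed(seed, {
      lab <- integer(length(ids)); names(lab) <- ids
      if (stratified) {
        offset <- 0L
        for (p in levels(pops)) {
          members <- sample(ids[pops == p])
          # cycle fold labels with a rotating offset so global sizes even out
          lab[members] <- ((seq_along(members) - 1L + offset) %% nFolds) + 1L
          offset <- (offset + length(members)) %% nFolds
        }
      } else {
        lab[sample(ids)] <- ((seq_along(ids) - 1L) %% nFolds) + 1L
      }
      lab
    })
    for (f in seq_len(nFolds))
      folds[[sprintf("fold%d", f)]] <-
        list(train = ids[lab != f], test = ids[lab == f])
  } else {
    counts <- table(pops)
    if (any(counts < nFolds))
      stop("population '", names(counts)[which.min(counts)],
        "' has fewer individuals than folds")
    lab <- withSeed(seed, {
      lab <- integer(length(ids)); names(lab) <- ids
      for (p in levels(pops)) {
        members <- sample(ids[pops == p])
        lab[members] <- ((seq_along(members) - 1L) %% nFolds) + 1L
      }
      lab
    })
    for (p in levels(pops)) for (f in seq_len(nFolds)) {
      inPop <- ids[pops == p]
      test <- inPop[lab[inPop] == f]
      folds[[sprintf("%s_fold%d", p, f)]] <-
        list(train = setdiff(inPop, test), test = test)
    }
  }
  new("FoldAssignment", scheme = scheme, folds = folds, seed = as.integer(seed))
}

#' Run the per-gene cross-validated model comparison
#'
#' For every requested gene, fold and model: fit on the training individuals,
#' predict the held-out individuals, and record training and test R-squared.
#' The training R-squared follows each model's own definition — in-sample for
#' the single-SNP model, mean internal-CV validation R-squared for the
#' elastic net, leave-one-out for the KNN models; the combined model's
#' training R-squared is the mean of its two components'. Test R-squared is
#' always computed against the test set's own variance. Genes with no
#' cis-SNPs are skipped with a message; per-gene errors mark the gene failed
#' without aborting the run.
#'
#' @param dataset a \linkS4class{CisDataset}
#' @param geneIds genes to evaluate (default: all genes with expression)
#' @param models subset of c("single", "enet", "knn", "knn_igf", "combined")
#' @param scheme cross-validation scheme (see \code{\link{makeCvFolds}})
#' @param config list of tuning parameters; recognized keys: windowBp
#'   (default 1e5), nFolds (5), centerScope ("global" or "train_only"),
#'   impute, pcaComponents, kMax (50), internalFolds (5), l1Ratio (0.5),
#'   metric (a \code{\link{metricLearningConfig}})
#' @param seed integer seed controlling fold assignment and internal CV
#' @return list with \code{summary} (data.frame: gene_id, model, scheme,
#'   fold, train_r2, test_r2, params) and \code{predictions} (long
#'   data.frame of per-individual test predictions)
#' @export
runGeneCv <- function(dataset, geneIds = NULL,
                      models = c("single", "enet", "knn"),
                      scheme = "cross_pop", config = list(), seed = 1L) {
  cfg <- modifyList(list(windowBp = 100000L, nFolds = 5L,
    centerScope = "global", impute = "mode", pcaComponents = 0L,
    kMax = 50L, internalFolds = 5L, l1Ratio = 0.5,
    metric = metricLearningConfig()), config)
  known <- c("single", "enet", "knn", "knn_igf", "combined")
  if (!all(models %in% known)) stop("unknown model name")
  if (is.null(geneIds))
    geneIds <- intersect(rownames(expressionValues(dataset)),
      geneTable(dataset)$gene_id)
  pops <- populationLabels(dataset)
  assign <- makeCvFolds(pops, scheme, nFolds = cfg$nFolds, seed = seed)
  needKnn <- any(c("knn", "combined") %in% models)
  needEnet <- any(c("enet", "combined") %in% models)
  smry <- list(); preds <- list()
  for (gid in geneIds) {
    task <- tryCatch(
      makeGeneTask(dataset, gid, windowBp = cfg$windowBp,
        centerScope = if (cfg$centerScope == "global") "global" else "none",
        impute = cfg$impute, pcaComponents = cfg$pcaComponents),
      error = function(e) e)
    if (is.null(task)) next
    if (inherits(task, "error")) {
      smry[[length(smry) + 1L]] <- data.frame(gene_id = gid, model = "all",
        scheme = scheme, fold = NA_character_, train_r2 = NA_real_,
        test_r2 = NA_real_, params = paste("failed:", conditionMessage(task)),
        stringsAsFactors = FALSE)
      next
    }
    for (fname in names(assign@folds)) {
      fold <- assign@folds[[fname]]
      res <- tryCatch(
        evalGeneFold(task, fold, models, cfg, pops, seed, needKnn, needEnet),
        error = function(e) e)
      if (inherits(res, "error")) {
        smry[[length(smry) + 1L]] <- data.frame(gene_id = gid, model = "all",
          scheme = scheme, fold = fname, train_r2 = NA_real_,
          test_r2 = NA_real_, params = paste("failed:", conditionMessage(res)),
          stringsAsFactors = FALSE)
        next
      }
      for (m in names(res)) {
        smry[[length(smry) + 1L]] <- data.frame(gene_id = gid, model = m,
          scheme = scheme, fold = fname, train_r2 = res[[m]]$trainR2,
          test_r2 = res[[m]]$testR2, params = res[[m]]$params,
          stringsAsFactors = FALSE)
        preds[[length(preds) + 1L]] <- data.frame(gene_id = gid, model = m,
          scheme = scheme, fold = fname,
          individual_id = names(res[[m]]$pred),
          prediction = unname(res[[m]]$pred),
          observed = unname(res[[m]]$obs), stringsAsFactors = FALSE)
      }
    }
  }
  list(summary = do.call(rbind, smry), predictions = do.call(rbind, preds),
    folds = assign)
}

evalGeneFold <- function(task, fold, models, cfg, pops, seed,
                         needKnn, needEnet) {
  trainTask <- subsetTask(task, fold$train)
  testTask <- subsetTask(task, fold$test)
  if (cfg$centerScope == "train_only") {
    yAll <- centerExpressionByPopulation(task@y, pops, "train_only",
      trainIds = fold$train)
    trainTask@y <- yAll[fold$train]
    testTask@y <- yAll[fold$test]
  }
  yTest <- testTask@y
  out <- list()
  knnPred <- enetPred <- NULL
  knnTrainR2 <- enetTrainR2 <- NA_real_
  if (needKnn) {
    m <- fitSimpleKnn(trainTask, kGrid = seq_len(min(cfg$kMax,
      length(trainTask@y) - 1L)))
    knnPred <- predictKnn(m, testTask@X)
    knnTrainR2 <- m@looR2
    if ("knn" %in% models)
      out$knn <- list(trainR2 = m@looR2, testR2 = rSquared(yTest, knnPred),
        pred = setNames(knnPred, names(yTest)), obs = yTest,
        params = sprintf("k=%d", m@k))
  }
  if (needEnet) {
    m <- fitElasticNet(trainTask, internalFolds = cfg$internalFolds,
      l1Ratio = cfg$l1Ratio, seed = seed)
    enetPred <- predict(m, testTask@X)
    enetTrainR2 <- m@trainR2Cv
    if ("enet" %in% models)
      out$enet <- list(trainR2 = m@trainR2Cv,
        testR2 = rSquared(yTest, enetPred),
        pred = setNames(enetPred, names(yTest)), obs = yTest,
        params = sprintf("lambda=%.4g;nonzero=%d", m@lambda,
          sum(abs(m@snpWeights) > 1e-8)))
  }
  if ("single" %in% models) {
    m <- fitSingleBestSnp(trainTask)
    p <- predict(m, testTask@X)
    out$single <- list(
      trainR2 = rSquared(trainTask@y, predict(m, trainTask@X)),
      testR2 = rSquared(yTest, p), pred = setNames(p, names(yTest)),
      obs = yTest, params = sprintf("snp=%s", m@snpId))
  }
  if ("knn_igf" %in% models) {
    m <- fitKnnIgf(trainTask, cfg$metric)
    p <- predictKnn(m, testTask@X)
    out$knn_igf <- list(trainR2 = m@looR2, testR2 = rSquared(yTest, p),
      pred = setNames(p, names(yTest)), obs = yTest,
      params = sprintf("k=%d;alphaMax=%s", m@k,
        colnames(task@F)[which.max(m@alpha)]))
  }
  if ("combined" %in% models) {
    p <- combinePredictions(knnPred, enetPred)
    out$combined <- list(trainR2 = mean(c(knnTrainR2, enetTrainR2)),
      testR2 = rSquared(yTest, p), pred = setNames(p, names(yTest)),
      obs = yTest, params = "mean(knn,enet)")
  }
  out
}

#' Average per-gene R-squared across folds
#'
#' Cross-fold aggregation of a \code{\link{runGeneCv}} summary: per gene and
#' model, the mean training and test R-squared over folds.
#'
#' @param summary the \code{summary} data.frame from \code{\link{runGeneCv}}
#' @return data.frame gene_id, model, train_r2, test_r2
#' @export
aggregateGeneR2 <- function(summary) {
  ok <- summary$model != "all" & !is.na(summary$train_r2)
  s <- summary[ok, , drop = FALSE]
  agg <- aggregate(cbind(train_r2, test_r2) ~ gene_id + model, data = s, FUN = mean)
  agg[order(agg$model, agg$gene_id), , drop = FALSE]
}

#' Fraction of robustly predicted genes
#'
#' A gene is robustly predicted when its test R-squared is at least
#' \code{threshold} times its training R-squared. Only genes with training
#' R-squared above \code{minTrain} enter the denominator.
#'
#' @param trainR2s,testR2s aligned per-gene R-squared vectors
#' @param threshold robustness threshold in [0, 1]
#' @param minTrain training R-squared floor for inclusion (default 0.05)
#' @return fraction in [0, 1]
#' @export
robustnessFraction <- function(trainR2s, testR2s, threshold, minTrain = 0.05) {
  if (length(trainR2s) != length(testR2s)) stop("length mismatch")
  keep <- !is.na(trainR2s) & trainR2s > minTrain
  if (!any(keep)) stop("empty gene set: no genes with training R2 above ", minTrain)
  mean(testR2s[keep] >= threshold * trainR2s[keep])
}

#' Train/test R-squared concordance and binned means
#'
#' Pearson and Spearman correlations between per-gene training and test
#' R-squared, plus mean training and test R-squared within training-R-squared
#' bins. Empty bins are reported with NA means.
#'
#' @param trainR2s,testR2s aligned per-gene vectors (length >= 3)
#' @param binEdges bin boundaries for training R-squared (left-closed,
#'   right-open; last bin right-closed)
#' @return list with \code{pearson}, \code{spearman} and \code{bins} (a
#'   data.frame: bin, n, mean_train_r2, mean_test_r2)
#' @export
concordanceAndBins <- function(trainR2s, testR2s,
                               binEdges = seq(0, 1, by = 0.1)) {
  if (length(trainR2s) != length(testR2s)) stop("length mismatch")
  if (length(trainR2s) < 3) stop("need at least 3 genes")
  bins <- cut(trainR2s, binEdges, right = FALSE, include.lowest = TRUE)
  lev <- levels(bins)
  binDf <- data.frame(bin = lev,
    n = as.integer(table(bins)[lev]),
    mean_train_r2 = vapply(lev, function(b)
      if (any(bins == b, na.rm = TRUE)) mean(trainR2s[which(bins == b)]) else NA_real_,
      numeric(1)),
    mean_test_r2 = vapply(lev, function(b)
      if (any(bins == b, na.rm = TRUE)) mean(testR2s[which(bins == b)]) else NA_real_,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(pearson = cor(trainR2s, testR2s, method = "pearson"),
    spearman = cor(trainR2s, testR2s, method = "spearman"),
    bins = binDf)
}

#' Overlap of top-predicted genes between models
#'
#' Given per-model gene lists ranked by test R-squared (descending, ties
#' broken lexicographically by gene id), counts the intersection of the
#' top-n prefixes for every model pair and across all models.
#'
#' @param topGeneLists named list of ranked gene-id vectors
#' @param nTop prefix size
#' @return list with \code{pairwise} (data.frame model_a, model_b, overlap)
#'   and \code{all} (count common to every model)
#' @export
modelOverlap <- function(topGeneLists, nTop) {
  if (length(topGeneLists) < 2) stop("need at least two models")
  if (any(vapply(topGeneLists, length, integer(1)) < nTop))
    stop("nTop exceeds a gene list length")
  tops <- lapply(topGeneLists, function(v) v[seq_len(nTop)])
  pairs <- combn(names(tops), 2)
  pw <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
    overlap = apply(pairs, 2, function(p)
      length(intersect(tops[[p[1]]], tops[[p[2]]]))),
    stringsAsFactors = FALSE)
  list(pairwise = pw, all = length(Reduce(intersect, tops)))
}

#' Rank genes by aggregated test R-squared
#'
#' @param aggregated output of \code{\link{aggregateGeneR2}}
#' @param model model name to rank
#' @return character vector of gene ids, best first (ties by gene id)
#' @export
rankGenesByTestR2 <- function(aggregated, model) {
  sub <- aggregated[aggregated$model == model, , drop = FALSE]
  sub$gene_id[order(-sub$test_r2, sub$gene_id)]
}

#' Compare gene properties between predictable and unpredictable genes
#'
#' For each per-gene scalar (e.g. selected K, absolute expression,
#' coefficient of variation, cis-SNP count, mean SNP entropy): group means
#' and a two-sample t-test p-value. Welch's correction is the default; set
#' \code{pooled = TRUE} for the classic equal-variance Student test. A scalar
#' constant within both groups gets p = 1.
#'
#' @param geneFeatures data.frame of per-gene scalars (one row per gene)
#' @param groupMask logical: TRUE = predictable group
#' @param pooled use the pooled-variance test (default FALSE = Welch)
#' @return data.frame feature, mean_predictable, mean_unpredictable, p_value
#' @export
characterizeGenes <- function(geneFeatures, groupMask, pooled = FALSE) {
  if (nrow(geneFeatures) != length(groupMask)) stop("length mismatch")
  if (!any(groupMask) || all(groupMask)) stop("both groups must be non-empty")
  res <- lapply(names(geneFeatures), function(f) {
    a <- geneFeatures[[f]][groupMask]
    b <- geneFeatures[[f]][!groupMask]
    p <- if (sd(a) == 0 && sd(b) == 0) 1 else
      tryCatch(t.test(a, b, var.equal = pooled)$p.value, error = function(e) 1)
    data.frame(feature = f, mean_predictable = mean(a),
      mean_unpredictable = mean(b), p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Coefficient of variation
#'
#' Standard deviation divided by the mean — the expression-variability
#' summary used when characterizing predictable genes.
#'
#' @param x numeric vector with non-zero mean
#' @return sd(x)/mean(x)
#' @export
coefficientOfVariation <- function(x) {
  m <- mean(x)
  if (m == 0) stop("zero mean")
  sd(x) / m
}
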