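#' @import methods
#' @importFrom stats cor cov sd var phyper p.adjust t.test rbinom rnorm runif
#'   predict coef setNames aggregate
#' @importFrom utils read.delim write.table combn modifyList
#' @importFrom glmnet glmnet
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits
NULL

## ---------------------------------------------------------------------------
## Input containers
## ---------------------------------------------------------------------------

#' GenotypeMatrix: minor-allele counts with SNP coordinates
#'
#' Holds an individuals x SNPs matrix of minor-allele counts (0, 1 or 2 copies
#' of the less frequent allele; \code{NA} for missing calls) together with the
#' chromosome and 1-based position of every SNP.
#'
#' @slot counts integer matrix, individuals in rows (rownames = individual
#'   ids), SNPs in columns (colnames = SNP ids); entries in \{0,1,2\} or NA.
#' @slot snpMeta data.frame with columns \code{chromosome} (character) and
#'   \code{position} (positive integer, 1-based), one row per SNP in column
#'   order of \code{counts}.
#' @export
setClass("GenotypeMatrix",
  representation(counts = "matrix", snpMeta = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  cnt <- object@counts
  meta <- object@snpMeta
  msg <- character()
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    msg <- c(msg, "counts must have individual ids as rownames and SNP ids as colnames")
  else {
    if (anyDuplicated(rownames(cnt)))
      msg <- c(msg, "duplicate individual ids")
    if (anyDuplicated(colnames(cnt)))
      msg <- c(msg, "duplicate SNP ids")
  }
  bad <- !is.na(cnt) & !(cnt %in% c(0L, 1L, 2L))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf(
      "genotype value outside {0,1,2} at individual '%s', SNP '%s'",
      rownames(cnt)[idx[1]], colnames(cnt)[idx[2]]))
  }
  if (!all(c("chromosome", "position") %in% names(meta)))
    msg <- c(msg, "snpMeta needs 'chromosome' and 'position' columns")
  else {
    if (nrow(meta) != ncol(cnt))
      msg <- c(msg, "snpMeta row count must equal number of SNPs")
    if (any(is.na(meta$position)) || any(meta$position < 1))
      msg <- c(msg, "SNP positions must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' ExpressionPanel: genes x individuals expression values
#'
#' @slot values numeric matrix, genes in rows (rownames = gene ids),
#'   individuals in columns (colnames = individual ids).
#' @export
setClass("ExpressionPanel", representation(values = "matrix"))

setValidity("ExpressionPanel", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have gene ids as rownames and individual ids as colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate individual ids")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: SNPs x genomic features
#'
#' Per-SNP genomic annotations (indicator bins or continuous scores) used by
#' the metric-learning KNN and by the enrichment analyses.
#'
#' @slot values numeric matrix, SNPs in rows (rownames = SNP ids), features in
#'   columns (colnames = feature names).
#' @export
setClass("FeatureMatrix", representation(values = "matrix"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have SNP ids as rownames and feature names as colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate SNP ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate feature names")
  }
  if (any(!is.finite(v))) msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

#' CisDataset: the five linked input tables
#'
#' Bundles genotypes, expression, SNP genomic features, gene coordinates and
#' population labels, and validates all cross-references among them: every
#' expression/population individual must be a genotyped individual, every
#' feature-matrix SNP must be a genotyped SNP, gene ids must be unique with
#' start <= end.
#'
#' @slot genotypes GenotypeMatrix
#' @slot expression ExpressionPanel
#' @slot features FeatureMatrix
#' @slot genes data.frame with columns gene_id, chromosome, start, end
#'   (1-based inclusive)
#' @slot populations named factor, one population label per individual
#' @export
setClass("CisDataset",
  representation(genotypes = "GenotypeMatrix", expression = "ExpressionPanel",
    features = "FeatureMatrix", genes = "data.frame", populations = "factor"))

setValidity("CisDataset", function(object) {
  msg <- character()
  ind <- rownames(object@genotypes@counts)
  snp <- colnames(object@genotypes@counts)
  expInd <- colnames(object@expression@values)
  unknown <- setdiff(expInd, ind)
  if (length(unknown))
    msg <- c(msg, sprintf("expression individual '%s' absent from genotypes", unknown[1]))
  if (!setequal(expInd, ind))
    msg <- c(msg, "expression individuals must match genotype individuals as a set")
  fsnp <- rownames(object@features@values)
  if (!all(fsnp %in% snp))
    msg <- c(msg, sprintf("feature-matrix SNP '%s' absent from genotypes",
      setdiff(fsnp, snp)[1]))
  g <- object@genes
  if (!all(c("gene_id", "chromosome", "start", "end") %in% names(g)))
    msg <- c(msg, "genes needs gene_id, chromosome, start, end columns")
  else {
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicate gene ids in gene table")
    if (any(g$start > g$end)) msg <- c(msg, "gene start must be <= end")
    if (!all(rownames(object@expression@values) %in% g$gene_id))
      msg <- c(msg, sprintf("expression gene '%s' absent from gene table",
        setdiff(rownames(object@expression@values), g$gene_id)[1]))
  }
  pop <- object@populations
  if (is.null(names(pop)) || !setequal(names(pop), ind))
    msg <- c(msg, "every genotyped individual needs exactly one population label")
  if (anyDuplicated(names(pop)))
    msg <- c(msg, "duplicate individual in population labels")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Per-gene task and fitted models
## ---------------------------------------------------------------------------

#' GeneTask: one gene's prediction problem
#'
#' The per-gene restriction of the dataset: centered expression response,
#' imputed cis-genotype submatrix, genomic-feature submatrix and population
#' labels, all over the same individuals.
#'
#' @slot geneId character gene id
#' @slot y numeric response vector (centered expression), named by individual
#' @slot X numeric matrix individuals x cis-SNPs, no missing values
#' @slot F numeric matrix cis-SNPs x features
#' @slot populations named factor over the same individuals
#' @slot constantSnps logical vector flagging zero-variance SNP columns
#' @export
setClass("GeneTask",
  representation(geneId = "character", y = "numeric", X = "matrix",
    F = "matrix", populations = "factor", constantSnps = "logical"))

setValidity("GeneTask", function(object) {
  msg <- character()
  if (ncol(object@X) < 1) msg <- c(msg, "task needs at least one cis-SNP")
  if (anyNA(object@X)) msg <- c(msg, "X must be imputed (no missing values)")
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "y length must equal number of individuals in X")
  if (nrow(object@F) > 0 && nrow(object@F) != ncol(object@X))
    msg <- c(msg, "feature submatrix rows must match cis-SNP count")
  if (length(msg)) msg else TRUE
})

#' SingleSnpModel: best-correlated-SNP linear predictor
#'
#' @slot snpId id of the selected SNP (argmax |Pearson r| with the response
#'   among non-constant cis-SNPs; ties broken by lowest column index)
#' @slot snpIndex its column index in the task's X
#' @slot slope,intercept OLS coefficients of y on the SNP's allele counts
#' @slot trainCorr training-set Pearson correlation of the selected SNP
#' @export
setClass("SingleSnpModel",
  representation(snpId = "character", snpIndex = "integer", slope = "numeric",
    intercept = "numeric", trainCorr = "numeric"))

#' ElasticNetModel: penalized multi-SNP linear predictor
#'
#' @slot snpWeights per-SNP regression weights (length = cis-SNP count)
#' @slot intercept numeric
#' @slot lambda penalty selected by internal cross-validation
#' @slot l1Ratio elastic-net mixing parameter
#' @slot trainR2Cv mean validation R-squared over the internal folds at the
#'   selected lambda (not the in-sample R-squared)
#' @export
setClass("ElasticNetModel",
  representation(snpWeights = "numeric", intercept = "numeric",
    lambda = "numeric", l1Ratio = "numeric", trainR2Cv = "numeric"))

#' KnnModel: K-nearest-neighbor predictor under a weighted L1 metric
#'
#' Prediction for an individual is the unweighted mean response of its k
#' nearest training individuals under the distance
#' d(a,b) = sum_i w_i |X_ai - X_bi|. Simple KNN uses all-ones weights; the
#' metric-learning extension uses genomic-feature-induced weights.
#'
#' @slot k number of neighbors (selected by leave-one-out on the training set)
#' @slot snpWeights nonnegative per-SNP weights of the L1 metric
#' @slot trainX,trainY stored training data
#' @slot looR2 leave-one-out training R-squared at the selected k
#' @slot alpha genomic-feature coefficients (length 0 for simple KNN)
#' @export
setClass("KnnModel",
  representation(k = "integer", snpWeights = "numeric", trainX = "matrix",
    trainY = "numeric", looR2 = "numeric", alpha = "numeric"))

setValidity("KnnModel", function(object) {
  msg <- character()
  if (object@k < 1 || object@k > nrow(object@trainX))
    msg <- c(msg, "k must be in 1..N_train")
  if (any(object@snpWeights < 0)) msg <- c(msg, "snpWeights must be nonnegative")
  if (length(object@snpWeights) != ncol(object@trainX))
    msg <- c(msg, "snpWeights length must equal SNP count")
  if (length(msg)) msg else TRUE
})

#' Predictor: one member of the metric-learning search pool
#'
#' A genomic-feature coefficient vector together with its metric-to-response
#' correlation (MRC) objective on training data (NA until evaluated).
#'
#' @slot alpha feature coefficient vector, not all zero
#' @slot objective MRC value in [-1, 1], or NA before evaluation
#' @export
setClass("Predictor",
  representation(alpha = "numeric", objective = "numeric"))

setValidity("Predictor", function(object) {
  msg <- character()
  if (all(object@alpha == 0)) msg <- c(msg, "alpha must not be all zero")
  if (!is.na(object@objective) &&
      (object@objective < -1 - 1e-12 || object@objective > 1 + 1e-12))
    msg <- c(msg, "objective must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' FoldAssignment: train/test splits of one cross-validation scheme
#'
#' @slot scheme one of "cross_pop", "mixed_pop", "intra_pop"
#' @slot folds named list; each element is a list with character vectors
#'   \code{train} and \code{test} of individual ids (disjoint)
#' @slot seed integer seed the assignment was generated with
#' @export
setClass("FoldAssignment",
  representation(scheme = "character", folds = "list", seed = "integer"))

setValidity("FoldAssignment", function(object) {
  if (!object@scheme %in% c("cross_pop", "mixed_pop", "intra_pop"))
    return("scheme must be cross_pop, mixed_pop or intra_pop")
  for (f in object@folds)
    if (length(intersect(f$train, f$test)))
      return("train and test sets must be disjoint within each fold")
  TRUE
})
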