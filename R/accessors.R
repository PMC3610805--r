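## Constructors, accessors and show methods for the data containers.

#' Construct a GenotypeMatrix
#'
#' @param counts individuals x SNPs matrix of minor-allele counts in
#'   \{0,1,2\} (NA = missing call), with individual ids as rownames and SNP
#'   ids as colnames.
#' @param chromosome character vector, one per SNP.
#' @param position 1-based integer positions, one per SNP.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' cnt <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'   dimnames = list(c("i1", "i2"), c("s1", "s2")))
#' GenotypeMatrix(cnt, chromosome = c("1", "1"), position = c(100L, 200L))
#' @export
GenotypeMatrix <- function(counts, chromosome, position) {
  storage.mode(counts) <- "integer"
  new("GenotypeMatrix", counts = counts,
    snpMeta = data.frame(chromosome = as.character(chromosome),
      position = as.integer(position), row.names = colnames(counts)))
}

#' Construct an ExpressionPanel
#' @param values genes x individuals numeric matrix with dimnames.
#' @export
ExpressionPanel <- function(values) {
  storage.mode(values) <- "double"
  new("ExpressionPanel", values = values)
}

#' Construct a FeatureMatrix
#' @param values SNPs x features numeric matrix with dimnames.
#' @export
FeatureMatrix <- function(values) {
  storage.mode(values) <- "double"
  new("FeatureMatrix", values = values)
}

#' Construct a CisDataset
#'
#' @param genotypes GenotypeMatrix
#' @param expression ExpressionPanel
#' @param features FeatureMatrix
#' @param genes data.frame with gene_id, chromosome, start, end (1-based
#'   inclusive coordinates)
#' @param populations named character/factor of population labels, one per
#'   genotyped individual
#' @export
CisDataset <- function(genotypes, expression, features, genes, populations) {
  pops <- as.factor(setNames(as.character(populations), names(populations)))
  new("CisDataset", genotypes = genotypes, expression = expression,
    features = features, genes = as.data.frame(genes), populations = pops)
}

#' @rdname accessors
#' @param x a package object
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))
#' @rdname accessors
#' @export
setGeneric("snpMeta", function(x) standardGeneric("snpMeta"))
#' @rdname accessors
#' @export
setGeneric("expressionValues", function(x) standardGeneric("expressionValues"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))

#' Accessors for the data containers
#' @name accessors
#' @return the requested component
NULL

#' @rdname accessors
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@counts))
#' @rdname accessors
#' @export
setMethod("individualIds", "CisDataset",
  function(x) individualIds(x@genotypes))
#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@counts))
#' @rdname accessors
#' @export
setMethod("snpIds", "CisDataset", function(x) snpIds(x@genotypes))
#' @rdname accessors
#' @export
setMethod("geneIds", "CisDataset", function(x) x@genes$gene_id)
#' @rdname accessors
#' @export
setMethod("genotypeCounts", "GenotypeMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("genotypeCounts", "CisDataset", function(x) x@genotypes@counts)
#' @rdname accessors
#' @export
setMethod("snpMeta", "GenotypeMatrix", function(x) x@snpMeta)
#' @rdname accessors
#' @export
setMethod("snpMeta", "CisDataset", function(x) x@genotypes@snpMeta)
#' @rdname accessors
#' @export
setMethod("expressionValues", "ExpressionPanel", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("expressionValues", "CisDataset", function(x) x@expression@values)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureValues", "CisDataset", function(x) x@features@values)
#' @rdname accessors
#' @export
setMethod("geneTable", "CisDataset", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("populationLabels", "CisDataset", function(x) x@populations)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs (%d missing calls)\n",
    nrow(object@counts), ncol(object@counts), sum(is.na(object@counts))))
})

setMethod("show", "ExpressionPanel", function(object) {
  cat(sprintf("ExpressionPanel: %d genes x %d individuals\n",
    nrow(object@values), ncol(object@values)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d SNPs x %d genomic features\n",
    nrow(object@values), ncol(object@values)))
})

setMethod("show", "CisDataset", function(object) {
  pops <- table(object@populations)
  cat(sprintf(
    "CisDataset: %d individuals (%s), %d SNPs, %d genes, %d genomic features\n",
    nrow(object@genotypes@counts),
    paste(sprintf("%s=%d", names(pops), pops), collapse = ", "),
    ncol(object@genotypes@counts), nrow(object@genes),
    ncol(object@features@values)))
})

setMethod("show", "GeneTask", function(object) {
  cat(sprintf("GeneTask '%s': %d individuals, %d cis-SNPs, %d features\n",
    object@geneId, nrow(object@X), ncol(object@X), ncol(object@F)))
})

setMethod("show", "SingleSnpModel", function(object) {
  cat(sprintf("SingleSnpModel: SNP %s, slope %.4g, intercept %.4g (train r = %.3f)\n",
    object@snpId, object@slope, object@intercept, object@trainCorr))
})

setMethod("show", "ElasticNetModel", function(object) {
  cat(sprintf("ElasticNetModel: %d/%d non-zero SNP weights, lambda %.4g, internal-CV R2 %.3f\n",
    sum(abs(object@snpWeights) > 1e-8), length(object@snpWeights),
    object@lambda, object@trainR2Cv))
})

setMethod("show", "KnnModel", function(object) {
  cat(sprintf("KnnModel: k = %d, %s metric over %d SNPs, LOO R2 %.3f\n",
    object@k,
    if (length(object@alpha)) "feature-weighted" else "unweighted",
    ncol(object@trainX), object@looR2))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: scheme %s, %d folds (seed %d)\n",
    object@scheme, length(object@folds), object@seed))
})
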