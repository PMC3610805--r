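## Per-gene task construction: cis-window SNP extraction, imputation,
## population-wise expression centering, SNP entropy, PCA correction.

#' Extract the cis-SNPs of a gene
#'
#' A cis-SNP lies on the gene's chromosome with position inside
#' \code{[start - windowBp, end + windowBp]}, 1-based inclusive on both ends
#' (gene body plus flanking windows). Interval arithmetic is delegated to
#' IRanges.
#'
#' @param gene one row of the gene table (list or data.frame row with
#'   gene_id, chromosome, start, end)
#' @param genotypes a \linkS4class{GenotypeMatrix}
#' @param windowBp flanking window in bp on each side (default 100000)
#' @return character vector of SNP ids (possibly empty)
#' @export
extractCisSnps <- function(gene, genotypes, windowBp = 100000L) {
  meta <- snpMeta(genotypes)
  sameChrom <- which(meta$chromosome == gene$chromosome)
  if (!length(sameChrom)) return(character(0))
  snps <- IRanges::IRanges(meta$position[sameChrom], width = 1L)
  lo <- max(1L, gene$start - as.integer(windowBp))
  win <- IRanges::IRanges(lo, gene$end + as.integer(windowBp))
  hits <- IRanges::findOverlaps(snps, win)
  snpIds(genotypes)[sameChrom[S4Vectors::queryHits(hits)]]
}

#' Impute missing genotype calls
#'
#' Missing entries are replaced per SNP by the mode of the non-missing calls
#' (ties broken toward the smaller count), which keeps the \{0,1,2\} support so
#' L1 KNN distances remain integral. Mean imputation (rounded to the nearest
#' integer in \{0,1,2\}) is available as an alternative.
#'
#' @param X individuals x SNPs count matrix, possibly with NAs
#' @param method "mode" (default) or "mean"
#' @return list with \code{X} (no missing values) and \code{constant}
#'   (logical: SNP columns with zero variance after imputation)
#' @export
imputeGenotypes <- function(X, method = c("mode", "mean")) {
  method <- match.arg(method)
  allMiss <- colSums(!is.na(X)) == 0
  if (any(allMiss))
    stop("all-missing genotype column for SNP '", colnames(X)[allMiss][1], "'")
  miss <- which(colSums(is.na(X)) > 0)
  for (j in miss) {
    v <- X[, j]
    fill <- if (method == "mode") {
      tb <- tabulate(v[!is.na(v)] + 1L, nbins = 3L)
      which.max(tb) - 1L   # which.max takes the first max: ties -> smaller count
    } else {
      max(0L, min(2L, as.integer(round(mean(v, na.rm = TRUE)))))
    }
    X[is.na(v), j] <- fill
  }
  list(X = X, constant = apply(X, 2, function(v) all(v == v[1])))
}

#' Center expression within populations
#'
#' Subtracts the population mean from each individual's expression so that
#' population-specific expression offsets do not masquerade as genotype
#' signal. With \code{scope = "global"} the means are computed over all
#' individuals (centering done once, before cross-validation); with
#' \code{scope = "train_only"} they are computed on \code{trainIds} only and
#' applied to everyone, the leakage-free fold-aware variant.
#'
#' @param y named numeric vector of raw expression (names = individual ids)
#' @param populations named factor of population labels
#' @param scope "global" or "train_only"
#' @param trainIds individual ids defining the means when scope="train_only"
#' @return centered numeric vector, same names and order as \code{y}
#' @export
centerExpressionByPopulation <- function(y, populations,
                                         scope = c("global", "train_only"),
                                         trainIds = NULL) {
  scope <- match.arg(scope)
  if (is.null(names(y))) stop("y must be named by individual id")
  pop <- populations[names(y)]
  if (anyNA(pop)) stop("unlabeled individual: ",
    names(y)[is.na(pop)][1])
  refIds <- if (scope == "global") names(y) else trainIds
  if (scope == "train_only" && is.null(refIds))
    stop("trainIds required when scope is 'train_only'")
  for (p in levels(droplevels(pop))) {
    members <- names(y)[pop == p]
    ref <- intersect(refIds, members)
    if (!length(ref))
      stop("population '", p, "' has no individuals in the mean-defining subset")
    y[members] <- y[members] - mean(y[ref])
  }
  y
}

#' Shannon entropy of a SNP's allele counts
#'
#' Minor-allele counts are decomposed into two binary alleles: count 0 ->
#' (A=0,B=0), 1 -> (A=0,B=1), 2 -> (A=1,B=1). The SNP entropy is the mean of
#' the two binary Shannon entropies in bits (log base 2), so it lies in
#' [0, 1] and reaches 1 only when both derived alleles have frequency 1/2.
#'
#' @param counts vector of minor-allele counts in \{0,1,2\}, no missing
#' @return entropy in bits
#' @export
snpEntropy <- function(counts) {
  if (!length(counts)) stop("empty genotype column")
  if (anyNA(counts) || !all(counts %in% c(0, 1, 2)))
    stop("counts must be in {0,1,2} with no missing values")
  h <- function(p) {
    if (p <= 0 || p >= 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  pA <- mean(counts == 2)     # allele A present only in homozygotes
  pB <- mean(counts >= 1)     # allele B present in het and hom
  (h(pA) + h(pB)) / 2
}

#' Mean SNP entropy over a gene's cis-SNPs
#'
#' @param X individuals x cis-SNPs count matrix, no missing values
#' @return mean of \code{\link{snpEntropy}} over columns
#' @export
geneAverageEntropy <- function(X) {
  if (ncol(X) < 1) stop("no cis-SNPs")
  mean(apply(X, 2, snpEntropy))
}

#' Remove leading principal components from a genotype matrix
#'
#' Projects the column-centered genotype matrix onto its top
#' \code{nComponents} principal axes and regresses those projections out of
#' every SNP column, removing broad (population-scale) structure. With fewer
#' informative components available than requested, only the available ones
#' are removed (with a warning). \code{nComponents = 0} is the identity.
#'
#' @param X individuals x SNPs numeric matrix, imputed
#' @param nComponents number of leading components to remove (default 2)
#' @return corrected matrix, same dimensions; column means are preserved
#' @export
pcaCorrectGenotypes <- function(X, nComponents = 2L) {
  nComponents <- as.integer(nComponents)
  if (nComponents == 0L) return(X)
  if (nrow(X) < 3) stop("need at least 3 individuals for PCA correction")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  keep <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * max(sv$d, 1))
  ncomp <- min(nComponents, keep)
  if (ncomp < nComponents)
    warning(sprintf("only %d informative component(s) available; removing %d",
      keep, ncomp))
  if (ncomp == 0L) return(X)
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  # residual of each column after projecting out span(U)
  Xres <- Xc - U %*% (t(U) %*% Xc)
  sweep(Xres, 2, mu, "+")
}

#' Build a gene's prediction task
#'
#' Extracts the gene's cis-SNPs, imputes missing calls, centers expression
#' within populations and subsets the feature matrix, returning a
#' \linkS4class{GeneTask} ready for model fitting. Returns NULL (with a
#' message) when the gene has no cis-SNPs.
#'
#' @param dataset a \linkS4class{CisDataset}
#' @param geneId gene to build the task for
#' @param windowBp cis-window half-width in bp
#' @param centerScope "global" (center once over everyone) or "none" (leave
#'   raw; fold-aware centering is then done inside \code{\link{runGeneCv}})
#' @param impute "mode" or "mean"
#' @param pcaComponents leading genotype PCs to remove (0 = off; applied to
#'   the cis submatrix)
#' @return a \linkS4class{GeneTask} or NULL
#' @export
makeGeneTask <- function(dataset, geneId, windowBp = 100000L,
                         centerScope = c("global", "none"),
                         impute = "mode", pcaComponents = 0L) {
  centerScope <- match.arg(centerScope)
  g <- dataset@genes[dataset@genes$gene_id == geneId, ]
  if (nrow(g) != 1) stop("unknown gene: ", geneId)
  cis <- extractCisSnps(g, dataset@genotypes, windowBp)
  if (!length(cis)) {
    message("gene ", geneId, " has no cis-SNPs in a ", windowBp, " bp window; skipped")
    return(NULL)
  }
  ind <- individualIds(dataset)
  Xraw <- genotypeCounts(dataset)[, cis, drop = FALSE]
  imp <- imputeGenotypes(Xraw, impute)
  X <- imp$X
  storage.mode(X) <- "double"
  if (pcaComponents > 0) X <- pcaCorrectGenotypes(X, pcaComponents)
  yRaw <- expressionValues(dataset)[geneId, ind]
  y <- if (centerScope == "global")
    centerExpressionByPopulation(yRaw, populationLabels(dataset), "global")
  else yRaw
  fv <- featureValues(dataset)
  Fgene <- fv[intersect(cis, rownames(fv)), , drop = FALSE]
  if (nrow(Fgene) != length(cis)) {
    # SNPs absent from the feature matrix get all-zero annotation rows
    full <- matrix(0, length(cis), ncol(fv), dimnames = list(cis, colnames(fv)))
    full[rownames(Fgene), ] <- Fgene
    Fgene <- full
  } else {
    Fgene <- fv[cis, , drop = FALSE]
  }
  new("GeneTask", geneId = geneId, y = y, X = X, F = Fgene,
    populations = populationLabels(dataset)[ind], constantSnps = imp$constant)
}

#' Restrict a GeneTask to a subset of individuals
#'
#' @param task a \linkS4class{GeneTask}
#' @param ids individual ids to keep
#' @return the restricted \linkS4class{GeneTask}
#' @export
subsetTask <- function(task, ids) {
  keep <- match(ids, names(task@y))
  if (anyNA(keep)) stop("unknown individual in subset")
  new("GeneTask", geneId = task@geneId, y = task@y[keep],
    X = task@X[keep, , drop = FALSE], F = task@F,
    populations = task@populations[keep], constantSnps = task@constantSnps)
}
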