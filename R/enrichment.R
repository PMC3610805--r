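## Hypergeometric enrichment/depletion of genomic features among selected
## SNPs or feature weights, with Benjamini-Hochberg FDR control.

#' Hypergeometric enrichment and depletion tails
#'
#' For an urn of N entities of which K carry the feature, and n draws of
#' which k carry it: \code{pEnriched = P(X >= k)} and
#' \code{pDepleted = P(X <= k)} for X ~ Hypergeometric(N, K, n). The two
#' tails overlap at k, so they sum to 1 + P(X = k).
#'
#' @param N population size
#' @param K feature carriers in the population
#' @param n number of draws
#' @param k observed carriers among the draws
#' @return list with \code{pEnriched} and \code{pDepleted}
#' @export
hypergeometricTest <- function(N, K, n, k) {
  if (any(c(N, K, n, k) != round(c(N, K, n, k)))) stop("arguments must be integers")
  if (K < 0 || K > N || n < 0 || n > N) stop("out-of-range arguments")
  if (k < max(0, n + K - N) || k > min(K, n)) stop("k outside attainable range")
  list(pEnriched = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    pDepleted = phyper(k, K, N - K, n, lower.tail = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (with monotonicity enforcement), preserving input
#' order. Inputs must lie in (0, 1].
#'
#' @param pValues raw p-values in (0, 1]
#' @return adjusted q-values, same order
#' @export
bhFdr <- function(pValues) {
  if (!length(pValues)) stop("no p-values")
  if (any(is.na(pValues)) || any(pValues <= 0) || any(pValues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pValues, method = "BH")
}

#' Feature enrichment/depletion across genes
#'
#' Tests, for every genomic feature, whether selected entities carry it more
#' (enrichment) or less (depletion) often than chance, per CV partition, and
#' calls a feature only when its BH-adjusted tail p-value is below
#' \code{alpha} in \emph{every} partition supplied.
#'
#' Two entity conventions: \describe{
#'   \item{KNN-IGF mode}{entities are (gene, feature) pairs; a pair is a
#'     carrier of feature m when it is that feature's pair, and is drawn when
#'     the gene's learned alpha gives the feature a non-zero coefficient.
#'     Supply \code{partitions} as lists of per-gene selected feature-name
#'     sets and \code{background} as per-gene candidate feature-name sets.}
#'   \item{elastic-net mode}{entities are (gene, SNP) pairs; a pair carries
#'     feature m when the SNP's annotation value is non-zero (indicator
#'     semantics, threshold configurable), and is drawn when its regression
#'     weight is non-zero. Supply per-gene selected/background SNP-id sets
#'     and \code{featureMatrix} mapping SNPs to features.}}
#'
#' @param partitions list (one element per CV partition) of named lists: per
#'   gene, the character vector of selected entities (features or SNPs)
#' @param background named list: per gene, the candidate entity set
#' @param featureMatrix a \linkS4class{FeatureMatrix} (required in
#'   elastic-net mode; NULL for KNN-IGF mode, where entities ARE features)
#' @param alpha per-partition significance level on adjusted p (default 0.01)
#' @param carrierThreshold annotation values with absolute value above this
#'   count as carrying the feature (default 0)
#' @return data.frame: feature, and per-partition q-values summarised as
#'   \code{max_q_enriched}/\code{max_q_depleted} (the worst partition),
#'   logical \code{enriched}/\code{depleted} calls, and the pooled counts
#'   N, K, n, k of the first partition for reference
#' @export
featureEnrichmentAcrossGenes <- function(partitions, background,
                                         featureMatrix = NULL, alpha = 0.01,
                                         carrierThreshold = 0) {
  if (!length(partitions)) stop("no partitions")
  if (!length(background) || !all(lengths(background) > 0))
    stop("empty background")
  snpMode <- !is.null(featureMatrix)
  featNames <- if (snpMode) colnames(featureValues(featureMatrix))
    else sort(unique(unlist(background)))
  perPart <- lapply(partitions, function(sel) {
    univCarrier <- drawn <- character(0)
    # build the entity table once per partition
    ent <- list()
    for (g in names(background)) {
      bg <- background[[g]]
      sl <- sel[[g]]
      if (is.null(sl)) sl <- character(0)
      if (!all(sl %in% bg))
        stop("selected entity outside background for gene ", g)
      ent[[g]] <- list(bg = bg, sel = sl)
    }
    N <- sum(vapply(ent, function(e) length(e$bg), integer(1)))
    n <- sum(vapply(ent, function(e) length(e$sel), integer(1)))
    res <- lapply(featNames, function(fm) {
      if (snpMode) {
        fv <- featureValues(featureMatrix)[, fm]
        carries <- function(x) abs(fv[x]) > carrierThreshold
        K <- sum(vapply(ent, function(e) sum(carries(e$bg)), numeric(1)))
        k <- sum(vapply(ent, function(e) sum(carries(e$sel)), numeric(1)))
      } else {
        K <- sum(vapply(ent, function(e) sum(e$bg == fm), numeric(1)))
        k <- sum(vapply(ent, function(e) sum(e$sel == fm), numeric(1)))
      }
      ht <- hypergeometricTest(N, K, n, k)
      data.frame(feature = fm, N = N, K = K, n = n, k = k,
        p_enriched = ht$pEnriched, p_depleted = ht$pDepleted,
        stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q_enriched <- bhFdr(res$p_enriched)
    res$q_depleted <- bhFdr(res$p_depleted)
    res
  })
  qe <- sapply(perPart, function(r) r$q_enriched)
  qd <- sapply(perPart, function(r) r$q_depleted)
  qe <- matrix(qe, nrow = length(featNames))
  qd <- matrix(qd, nrow = length(featNames))
  first <- perPart[[1]]
  data.frame(feature = featNames,
    N = first$N, K = first$K, n = first$n, k = first$k,
    max_q_enriched = apply(qe, 1, max),
    max_q_depleted = apply(qd, 1, max),
    enriched = apply(qe, 1, max) < alpha,
    depleted = apply(qd, 1, max) < alpha,
    stringsAsFactors = FALSE)
}

#' Extract non-zero selections from fitted models
#'
#' Helpers turning fitted models into the selection sets that
#' \code{\link{featureEnrichmentAcrossGenes}} consumes: for a
#' \linkS4class{KnnModel} (KNN-IGF), the features with non-zero alpha (exact
#' zero comparison — the greedy search produces exact zeros only from
#' unselected initializations); for an \linkS4class{ElasticNetModel}, the
#' SNPs with |weight| above \code{tol} (default 1e-8).
#'
#' @param model a fitted \linkS4class{KnnModel} or
#'   \linkS4class{ElasticNetModel}
#' @param names feature names (KNN-IGF) or SNP ids (elastic net)
#' @param tol numeric tolerance for elastic-net weights
#' @return character vector of selected names
#' @export
selectedEntities <- function(model, names, tol = 1e-8) {
  if (is(model, "KnnModel")) {
    if (!length(model@alpha)) stop("model has no feature coefficients")
    names[model@alpha != 0]
  } else if (is(model, "ElasticNetModel")) {
    names[abs(model@snpWeights) > tol]
  } else stop("unsupported model class")
}

#' Gene-set (annotation term) enrichment
#'
#' Generic hypergeometric + BH machinery for user-supplied annotations: for
#' each term, tests whether the selected genes carry it more often than
#' expected among the universe.
#'
#' @param selectedGenes character vector of selected gene ids
#' @param universe character vector of all candidate gene ids
#' @param annotation data.frame with columns \code{entity} (gene id) and
#'   \code{term}
#' @param alpha FDR threshold for the \code{significant} flag (default 0.05)
#' @return data.frame term, N, K, n, k, p_enriched, q_enriched, significant
#' @export
geneSetEnrichment <- function(selectedGenes, universe, annotation,
                              alpha = 0.05) {
  if (!all(selectedGenes %in% universe)) stop("selected gene outside universe")
  if (!all(c("entity", "term") %in% names(annotation)))
    stop("annotation needs 'entity' and 'term' columns")
  ann <- annotation[annotation$entity %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term))
  N <- length(universe); n <- length(selectedGenes)
  res <- lapply(terms, function(tm) {
    carriers <- unique(ann$entity[ann$term == tm])
    K <- length(carriers)
    k <- length(intersect(selectedGenes, carriers))
    data.frame(term = tm, N = N, K = K, n = n, k = k,
      p_enriched = hypergeometricTest(N, K, n, k)$pEnriched,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_enriched <- bhFdr(res$p_enriched)
  res$significant <- res$q_enriched < alpha
  res[order(res$p_enriched, res$term), , drop = FALSE]
}
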