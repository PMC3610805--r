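## Reading and writing the five linked input tables plus result tables.
##
## Dialect: tab-separated UTF-8, header row, first column is the row id.
## Missing genotype calls are written as "NA". Genotypes are stored SNPs-as-rows
## (snp_id, chromosome, position, then one column per individual), the dosage
## file convention, so the per-SNP coordinates travel with the counts; the
## loader transposes to the internal individuals x SNPs orientation.

fmtNum <- function(x) {
  # %.17g survives a write/read round trip exactly for doubles
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = NULL, colClasses = "character")
}

#' Load a genotype table
#'
#' Expects columns \code{snp_id}, \code{chromosome}, \code{position}, then one
#' column per individual holding minor-allele counts 0/1/2 or NA.
#'
#' @param path TSV file path
#' @return A \linkS4class{GenotypeMatrix}
#' @export
readGenotypes <- function(path) {
  tab <- readTsv(path)
  need <- c("snp_id", "chromosome", "position")
  if (!all(need %in% names(tab)))
    stop("genotype table must have columns snp_id, chromosome, position")
  indCols <- setdiff(names(tab), need)
  if (!length(indCols)) stop("genotype table has no individual columns")
  raw <- as.matrix(tab[, indCols, drop = FALSE])
  ok <- raw %in% c("0", "1", "2", "NA")
  if (!all(ok)) {
    idx <- which(!ok)[1]
    rc <- arrayInd(idx, dim(raw))
    stop(sprintf(
      "genotype parse error: value '%s' at SNP '%s', individual '%s' (expected 0/1/2/NA)",
      raw[idx], tab$snp_id[rc[1]], indCols[rc[2]]))
  }
  cnt <- matrix(suppressWarnings(as.integer(raw)), nrow = nrow(raw),
    dimnames = list(tab$snp_id, indCols))
  GenotypeMatrix(t(cnt), chromosome = tab$chromosome,
    position = as.integer(tab$position))
}

#' Load an expression table (genes as rows, individuals as columns)
#' @param path TSV file path with first column \code{gene_id}
#' @return An \linkS4class{ExpressionPanel}
#' @export
readExpression <- function(path) {
  tab <- readTsv(path)
  if (names(tab)[1] != "gene_id") stop("expression table must start with gene_id")
  v <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- tab$gene_id
  if (anyNA(v)) stop("expression values must be numeric and non-missing")
  ExpressionPanel(v)
}

#' Load a SNP genomic-feature table (SNPs as rows, features as columns)
#' @param path TSV file path with first column \code{snp_id}
#' @return A \linkS4class{FeatureMatrix}
#' @export
readFeatures <- function(path) {
  tab <- readTsv(path)
  if (names(tab)[1] != "snp_id") stop("feature table must start with snp_id")
  v <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- tab$snp_id
  if (anyNA(v)) stop("feature values must be numeric and non-missing")
  FeatureMatrix(v)
}

#' Load a gene annotation table
#' @param path TSV with columns gene_id, chromosome, start, end
#' @return data.frame
#' @export
readGenes <- function(path) {
  tab <- readTsv(path)
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns gene_id, chromosome, start, end")
  data.frame(gene_id = tab$gene_id, chromosome = tab$chromosome,
    start = as.integer(tab$start), end = as.integer(tab$end),
    stringsAsFactors = FALSE)
}

#' Load population labels
#' @param path TSV with columns individual_id, population
#' @return named factor
#' @export
readPopulations <- function(path) {
  tab <- readTsv(path)
  need <- c("individual_id", "population")
  if (!all(need %in% names(tab)))
    stop("population table must have columns individual_id, population")
  as.factor(setNames(tab$population, tab$individual_id))
}

#' Load and cross-validate the five input tables
#'
#' Reads genotype, expression, feature, gene and population tables and returns
#' a validated \linkS4class{CisDataset}. All cross-reference invariants are
#' checked (unknown individuals or SNPs raise errors naming the offending id);
#' missing genotype calls are preserved as NA — imputation is a preprocessing
#' step, not a loading step.
#'
#' @param genotypePath,expressionPath,featurePath,genePath,populationPath
#'   paths to the five TSV tables
#' @return A \linkS4class{CisDataset}
#' @export
loadDataset <- function(genotypePath, expressionPath, featurePath, genePath,
                        populationPath) {
  CisDataset(
    genotypes = readGenotypes(genotypePath),
    expression = readExpression(expressionPath),
    features = readFeatures(featurePath),
    genes = readGenes(genePath),
    populations = readPopulations(populationPath))
}

#' Write a CisDataset as the five TSV tables
#'
#' Inverse of \code{\link{loadDataset}}: writes genotype.tsv, expression.tsv,
#' features.tsv, genes.tsv and populations.tsv under \code{dir}. Numeric
#' values are written with enough digits for an exact round trip.
#'
#' @param dataset a \linkS4class{CisDataset}
#' @param dir output directory (created if absent)
#' @return invisibly, the five file paths
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genotype.tsv", "expression.tsv", "features.tsv",
    "genes.tsv", "populations.tsv"))
  cnt <- t(dataset@genotypes@counts)   # SNPs as rows on disk
  gt <- data.frame(snp_id = rownames(cnt),
    chromosome = dataset@genotypes@snpMeta$chromosome,
    position = dataset@genotypes@snpMeta$position,
    ifelse(is.na(cnt), "NA", as.character(cnt)),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(gt)[-(1:3)] <- colnames(cnt)
  writeTsv(gt, paths[1])
  ev <- dataset@expression@values
  ex <- data.frame(gene_id = rownames(ev),
    apply(ev, 2, fmtNum), check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(ex, paths[2])
  fv <- dataset@features@values
  ft <- data.frame(snp_id = rownames(fv),
    apply(fv, 2, fmtNum), check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(ft, paths[3])
  writeTsv(dataset@genes, paths[4])
  writeTsv(data.frame(individual_id = names(dataset@populations),
    population = as.character(dataset@populations)), paths[5])
  invisible(setNames(paths,
    c("genotype", "expression", "features", "genes", "populations")))
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
}

#' Write cross-validation result tables
#'
#' Writes one summary table per (model, scheme) combination present in the
#' results, with columns gene_id, fold, train_r2, test_r2 and a parameter
#' summary, plus a long predictions table (gene, model, fold, individual,
#' prediction, observed). Row order is deterministic: gene_id, then fold.
#'
#' @param results the list returned by \code{\link{runGeneCv}} (elements
#'   \code{summary} and \code{predictions})
#' @param outDir output directory
#' @return invisibly, the written file paths
#' @export
writeResults <- function(results, outDir) {
  smry <- results$summary
  if (is.null(smry) || nrow(smry) == 0) stop("no results")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (model in sort(unique(smry$model))) {
    for (scheme in sort(unique(smry$scheme))) {
      sub <- smry[smry$model == model & smry$scheme == scheme, , drop = FALSE]
      if (!nrow(sub)) next
      sub <- sub[order(sub$gene_id, sub$fold), , drop = FALSE]
      sub$train_r2 <- fmtNum(sub$train_r2)
      sub$test_r2 <- fmtNum(sub$test_r2)
      p <- file.path(outDir, sprintf("summary_%s_%s.tsv", model, scheme))
      writeTsv(sub, p)
      paths <- c(paths, p)
    }
  }
  pred <- results$predictions
  if (!is.null(pred) && nrow(pred)) {
    pred <- pred[order(pred$gene_id, pred$model, pred$fold, pred$individual_id), ,
      drop = FALSE]
    pred$prediction <- fmtNum(pred$prediction)
    pred$observed <- fmtNum(pred$observed)
    p <- file.path(outDir, "predictions.tsv")
    writeTsv(pred, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
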