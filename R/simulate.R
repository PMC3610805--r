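## Synthetic multi-population genotype/expression/feature panels with
## planted, tunable cis effects. The generator emulates the statistical
## structure the prediction task assumes: population-specific allele
## frequencies, cis windows holding a known number of SNPs, linear or
## non-linear genotype effects of tunable heritability with controllable
## cross-population sharing, and genomic-feature annotations that
## preferentially tag causal SNPs.

#' Simulation specification
#'
#' @param nPerPop individuals per population (default 50)
#' @param nPopulations number of populations (default 4, labelled pop1..)
#' @param nGenes number of genes (default 10)
#' @param snpsPerGene cis-SNPs per gene (default 30)
#' @param mafRange minor-allele frequency range; per SNP and population the
#'   frequency is drawn uniformly from it (default c(0.1, 0.5)). Minor-allele
#'   orientation is fixed globally by keeping the range at or below 0.5.
#' @param h2 fraction of expression variance from the planted genotype
#'   effects, in [0, 1] (default 0.4)
#' @param nCausal causal SNPs per gene (default 5)
#' @param effectModel "linear", "dominant" or "epistatic"
#' @param shareAcrossPops probability a causal SNP has the same effect in all
#'   populations (default 1; non-shared SNPs get independent per-population
#'   effects)
#' @param noiseSd expression noise scale used when h2 = 0 (otherwise the
#'   noise is scaled from the realized genetic variance; default 1)
#' @param featureSpec list(M, nInformative, pTagCausal, pTagNull, pNoise):
#'   number of genomic features, how many are informative, the probabilities
#'   that an informative feature tags a causal / non-causal SNP, and the
#'   tagging rate of pure-noise features
#' @param windowBp cis-window half-width the layout must respect
#' @param seed integer seed; all draws are deterministic given it
#' @return a list of class "SimulationSpec"
#' @export
simulationSpec <- function(nPerPop = 50L, nPopulations = 4L, nGenes = 10L,
                           snpsPerGene = 30L, mafRange = c(0.1, 0.5),
                           h2 = 0.4, nCausal = min(5L, snpsPerGene),
                           effectModel = c("linear", "dominant", "epistatic"),
                           shareAcrossPops = 1, noiseSd = 1,
                           featureSpec = list(M = 5L, nInformative = 1L,
                             pTagCausal = 1, pTagNull = 0, pNoise = 0.2),
                           windowBp = 100000L, seed = 1L) {
  effectModel <- match.arg(effectModel)
  stopifnot(h2 >= 0, h2 <= 1, nCausal <= snpsPerGene,
    shareAcrossPops >= 0, shareAcrossPops <= 1,
    mafRange[1] >= 0, mafRange[2] <= 0.5)
  structure(list(nPerPop = as.integer(nPerPop),
    nPopulations = as.integer(nPopulations), nGenes = as.integer(nGenes),
    snpsPerGene = as.integer(snpsPerGene), mafRange = mafRange, h2 = h2,
    nCausal = as.integer(nCausal), effectModel = effectModel,
    shareAcrossPops = shareAcrossPops, noiseSd = noiseSd,
    featureSpec = featureSpec, windowBp = as.integer(windowBp),
    seed = as.integer(seed)), class = "SimulationSpec")
}

#' Simulate genotypes, population labels and gene coordinates
#'
#' Genes are laid out along one chromosome with enough spacing that their cis
#' windows never overlap, and each gene's window contains exactly
#' \code{snpsPerGene} SNPs. Per population and SNP, allele counts are drawn
#' binomially with two trials at a frequency drawn from \code{mafRange}, so
#' populations differ in allele frequency but share the minor-allele
#' orientation. SNPs are independent (no linkage disequilibrium).
#'
#' @param spec a \code{\link{simulationSpec}}
#' @return list with \code{genotypes} (\linkS4class{GenotypeMatrix}),
#'   \code{populations} (named factor) and \code{genes} (data.frame)
#' @export
simulateGenotypes <- function(spec) {
  withSeed(spec$seed, {
    geneLen <- 10000L
    spacing <- 2L * spec$windowBp + geneLen + 100000L
    genes <- data.frame(
      gene_id = sprintf("gene%03d", seq_len(spec$nGenes)),
      chromosome = "1",
      start = spec$windowBp + 1L + (seq_len(spec$nGenes) - 1L) * spacing,
      stringsAsFactors = FALSE)
    genes$end <- genes$start + geneLen - 1L
    nInd <- spec$nPerPop * spec$nPopulations
    ind <- sprintf("ind%04d", seq_len(nInd))
    popLab <- factor(rep(sprintf("pop%d", seq_len(spec$nPopulations)),
      each = spec$nPerPop))
    names(popLab) <- ind
    D <- spec$nGenes * spec$snpsPerGene
    snpId <- character(D); snpPos <- integer(D)
    counts <- matrix(0L, nInd, D)
    col <- 0L
    for (g in seq_len(spec$nGenes)) {
      lo <- genes$start[g] - spec$windowBp
      hi <- genes$end[g] + spec$windowBp
      pos <- sort(sample(seq(lo, hi), spec$snpsPerGene))
      for (s in seq_len(spec$snpsPerGene)) {
        col <- col + 1L
        snpId[col] <- sprintf("snp_%s_%03d", genes$gene_id[g], s)
        snpPos[col] <- pos[s]
        for (p in seq_len(spec$nPopulations)) {
          maf <- runif(1, spec$mafRange[1], spec$mafRange[2])
          rows <- which(popLab == sprintf("pop%d", p))
          counts[rows, col] <- rbinom(length(rows), 2L, maf)
        }
      }
    }
    dimnames(counts) <- list(ind, snpId)
    list(genotypes = GenotypeMatrix(counts, chromosome = rep("1", D),
        position = snpPos),
      populations = popLab, genes = genes)
  })
}

geneticValue <- function(X, causal, effects, effectModel) {
  if (effectModel == "linear") {
    drop(X[, causal, drop = FALSE] %*% effects)
  } else if (effectModel == "dominant") {
    drop((X[, causal, drop = FALSE] >= 1) %*% effects)
  } else {
    # epistatic: products of consecutive causal pairs (cyclic when odd)
    idx <- causal
    if (length(idx) == 1) return(X[, idx] * effects[1])
    g <- numeric(nrow(X))
    for (i in seq_along(idx)) {
      j <- if (i < length(idx)) i + 1L else 1L
      g <- g + effects[i] * X[, idx[i]] * X[, idx[j]]
    }
    g
  }
}

#' Simulate expression with planted cis effects
#'
#' For each gene, \code{nCausal} causal SNPs are drawn from its cis window
#' and given standard-normal effect sizes; with probability
#' \code{1 - shareAcrossPops} a causal SNP instead receives independent
#' per-population effects. The genetic value follows the chosen effect model
#' and Gaussian noise is scaled so that the genetic share of the total
#' variance equals \code{h2} in expectation (\code{h2 = 0} plants no effect
#' at all; \code{h2 = 1} adds no noise and requires a non-degenerate genetic
#' value).
#'
#' @param spec a \code{\link{simulationSpec}}
#' @param sim output of \code{\link{simulateGenotypes}}
#' @return list with \code{expression} (\linkS4class{ExpressionPanel}) and
#'   \code{truth} (data.frame: gene_id, snp_id, shared, effect, realized_h2)
#' @export
simulateExpression <- function(spec, sim) {
  withSeed(spec$seed + 1000L, {
    cnt <- genotypeCounts(sim$genotypes)
    pops <- sim$populations
    vals <- matrix(NA_real_, spec$nGenes, nrow(cnt),
      dimnames = list(sim$genes$gene_id, rownames(cnt)))
    truth <- list()
    for (g in seq_len(spec$nGenes)) {
      gid <- sim$genes$gene_id[g]
      cis <- grep(sprintf("^snp_%s_", gid), colnames(cnt), value = TRUE)
      causal <- sort(sample(cis, spec$nCausal))
      shared <- runif(spec$nCausal) < spec$shareAcrossPops
      baseEff <- rnorm(spec$nCausal)
      gval <- numeric(nrow(cnt))
      if (spec$h2 > 0) {
        if (all(shared)) {
          gval <- geneticValue(cnt, causal, baseEff, spec$effectModel)
        } else {
          for (p in levels(pops)) {
            rows <- which(pops == p)
            eff <- ifelse(shared, baseEff, rnorm(spec$nCausal))
            gval[rows] <- geneticValue(cnt[rows, , drop = FALSE], causal, eff,
              spec$effectModel)
          }
        }
      }
      varG <- var(gval)
      if (spec$h2 == 0) {
        y <- rnorm(nrow(cnt), sd = spec$noiseSd)
      } else if (spec$h2 == 1) {
        if (varG == 0) stop("h2 = 1 but the genetic value has zero variance")
        y <- gval
      } else {
        if (varG == 0) stop("planted genetic value has zero variance for ", gid)
        y <- gval + rnorm(nrow(cnt), sd = sqrt(varG * (1 - spec$h2) / spec$h2))
      }
      vals[g, ] <- y
      truth[[g]] <- data.frame(gene_id = gid, snp_id = causal,
        shared = shared, effect = ifelse(rep(spec$h2 > 0, spec$nCausal),
          baseEff, 0),
        realized_h2 = if (var(y) > 0) varG / var(y) else NA_real_,
        stringsAsFactors = FALSE)
    }
    list(expression = ExpressionPanel(vals), truth = do.call(rbind, truth))
  })
}

#' Simulate SNP genomic features
#'
#' The first \code{nInformative} features tag causal SNPs with probability
#' \code{pTagCausal} and non-causal SNPs with \code{pTagNull}; the remaining
#' features are pure-noise indicators with rate \code{pNoise}.
#'
#' @param spec a \code{\link{simulationSpec}}
#' @param sim output of \code{\link{simulateGenotypes}}
#' @param truth truth record from \code{\link{simulateExpression}}
#' @return a \linkS4class{FeatureMatrix}
#' @export
simulateFeatures <- function(spec, sim, truth) {
  withSeed(spec$seed + 2000L, {
    fs <- spec$featureSpec
    snps <- snpIds(sim$genotypes)
    isCausal <- snps %in% truth$snp_id
    vals <- matrix(0, length(snps), fs$M,
      dimnames = list(snps, sprintf("feat%02d", seq_len(fs$M))))
    for (m in seq_len(fs$M)) {
      vals[, m] <- if (m <= fs$nInformative)
        rbinom(length(snps), 1L, ifelse(isCausal, fs$pTagCausal, fs$pTagNull))
      else rbinom(length(snps), 1L, fs$pNoise)
    }
    FeatureMatrix(vals)
  })
}

#' Simulate a complete dataset
#'
#' Runs \code{\link{simulateGenotypes}}, \code{\link{simulateExpression}} and
#' \code{\link{simulateFeatures}} and assembles a validated
#' \linkS4class{CisDataset} plus the ground-truth record.
#'
#' @param spec a \code{\link{simulationSpec}}
#' @return list with \code{dataset} (\linkS4class{CisDataset}) and
#'   \code{truth} (data.frame of causal SNPs, effects and realized h2)
#' @export
simulateDataset <- function(spec) {
  sim <- simulateGenotypes(spec)
  expr <- simulateExpression(spec, sim)
  feats <- simulateFeatures(spec, sim, expr$truth)
  ds <- CisDataset(genotypes = sim$genotypes, expression = expr$expression,
    features = feats, genes = sim$genes, populations = sim$populations)
  list(dataset = ds, truth = expr$truth)
}

#' Write the ground-truth record alongside a dataset
#'
#' @param truth truth data.frame from \code{\link{simulateDataset}}
#' @param dir output directory
#' @return invisibly, the file path
#' @export
writeTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "truth.tsv")
  out <- truth
  out$effect <- fmtNum(out$effect)
  out$realized_h2 <- fmtNum(out$realized_h2)
  writeTsv(out, p)
  invisible(p)
}
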