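---
title: "Predicting expression differences from cis-genotypes: models, metric learning and evaluation"
author: "cisxpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting expression differences from cis-genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisxpred)
```

## The problem

Expression of a gene varies among individuals, and part of that variation is
driven by nearby sequence variation: SNPs inside the gene body or its
flanking regulatory regions (*cis*-SNPs, here within 100 kb of the gene).
`cisxpred` asks how well the expression level of an *unseen* individual can
be predicted from genotype alone, using only a gene's cis-SNPs, and — just as
importantly — whether a model can know *in advance*, from training data only,
which genes it will predict well. That second property, robustness, is what
distinguishes a usable genotype-to-expression predictor from one that merely
fits.

Because trans-acting variation and environment dominate most genes'
expression variance, even an optimal cis-only predictor explains a minority
of variance for most genes. The package therefore treats the per-gene
training-vs-test R² relationship, not the absolute R², as the primary object
of study.

## The four models

Each gene defines an independent task: a response vector $y$ (expression over
$N$ individuals, centered within each population) and a design matrix $X$
($N \times D$ minor-allele counts in $\{0,1,2\}$ over the gene's $D$
cis-SNPs).

**Single best-SNP.** The cis-SNP with the highest absolute Pearson
correlation to $y$ on the training set, used in a two-parameter OLS
regression. Absolute rather than signed correlation is used because a
strongly negative SNP is equally predictive under OLS; ties go to the lower
SNP index so runs are reproducible.

**Elastic net.** A linear model over all $D$ SNPs with the glmnet penalty
$\lambda\,(\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2/2)$, mixing parameter
$\alpha = 0.5$ by default. $\lambda$ is selected by internal cross-validation
*within the training set* (5 folds, glmnet's 50-value log-spaced path down to
$10^{-3}$ of the maximal $\lambda$), maximizing mean validation R², each fold
scored against its own variance. The reported training R² is that internal-CV
mean, not the in-sample value, so the training score is itself an honest
forecast of held-out performance.

**Simple KNN.** A test individual is predicted as the unweighted mean
expression of its $k$ nearest training individuals, distance being the L1
metric $d(a,b) = \sum_i |X_{a,i} - X_{b,i}|$. The single parameter $k$ is
selected by leave-one-out within the training set: each training individual
is predicted from its $k$ nearest *other* training individuals and the $k$
maximizing this LOO R² wins (ties to the smallest $k$). LOO is used because a
naive in-sample KNN score would let every individual be its own nearest
neighbor. Neighbor ties at the $k$-th rank are broken by ascending training
index. The grid is capped at $k \le 50$ by default.

**Combined.** The element-wise mean of the KNN and elastic-net predictions —
the two multi-SNP models make different assumptions (non-parametric local
averaging vs. global linear), so their average tends to be more robust than
either. Raw predictions are averaged, not standardized ones. The combined
model's training R² is not uniquely defined by the procedure; this package
reports the mean of the two components' training R² values.

## Metric learning (KNN-IGF)

In the simple KNN metric every SNP counts equally, but SNPs differ greatly in
regulatory relevance. The extended model (KNN *Integrating Genomic Features*)
weighs each SNP by a learned combination of its genomic annotations. Given a
SNP-by-feature matrix $F$ ($D \times M$: promoter proximity bins,
conservation, GC content, binding sites, chromatin marks, ...), a feature
coefficient vector $\alpha$ induces per-SNP weights
$w_i = \sum_m \alpha_m f_{i,m}$ (clamped at zero: an L1 metric needs
nonnegative weights) and the metric becomes
$d(a,b) = \sum_i w_i |X_{a,i} - X_{b,i}|$. Because each coefficient is shared
by all SNPs carrying the feature, the parameter count is $M$, not $D$, which
is the model's defense against overfitting.

**Objective.** $\alpha$ is scored by the *metric-to-response correlation*
(MRC): the Pearson correlation, over all unordered training pairs, between
$d(a,b)$ and $|y_a - y_b|$. A good metric places individuals with similar
expression close together, giving MRC near $+1$. The MRC involves no $k$;
detaching metric learning from the choice of $k$ reduces overfitting.
Degenerate metrics (constant pairwise distances) are assigned objective 0.

**Search.** The objective is not differentiable, so a greedy pool search is
used. The pool starts with $M$ one-hot predictors ($\alpha = e_m$). Each
iteration keeps the $R_{\max}$ best by MRC (default 5) and replaces the pool
with all $R_{\max}^2$ pairwise combinations
$\alpha_{ij} = (g_i \alpha_i + g_j \alpha_j)/(g_i + g_j)$, where
$g = \max(f, 10^{-6})$ floors non-positive objectives so the weighting never
flips sign. Self-pairs are included, so the incumbent survives every
iteration and the best objective is non-decreasing — an invariant asserted on
every run. Iteration stops when the improvement falls below $10^{-6}$ or
after 50 iterations. After the search, SNP weights are induced from the best
$\alpha$ and $k$ is selected exactly as in simple KNN, under the learned
metric. With a single all-ones feature, the learned metric is a positive
rescaling of the unweighted one, and KNN-IGF reproduces simple KNN
prediction-for-prediction — a useful exact reduction that the test suite
checks.

The pairwise-combination equation and the distance/prediction formulas are
implemented from their prose descriptions; the objective-weighted convex
combination is the unique reading that reproduces the stated
"cannot decrease" self-combination property.

## Cross-validation schemes

Three schemes probe where predictive power comes from:

* **Cross-Pop** — each fold holds out one entire population; training uses
  only the other populations. Success requires effects shared across
  populations. This is the hardest and most interesting scheme.
* **Mixed-Pop** — five near-equal folds stratified by population (each
  fold's population composition matches the global one within one
  individual). A non-stratified variant is available behind a flag.
* **Intra-Pop** — five-fold CV run separately inside each population;
  training and test individuals always share a population.

Expression is centered per population (subtracting the population mean)
before modeling, so population-level expression offsets cannot leak into the
genotype signal. The default centers once, globally, before CV — matching
the usual practice of preprocessing the panel as a whole; because global
centering technically uses test individuals' values, a strictly leakage-free
`train_only` scope (means from training individuals applied to everyone) is
also provided.

R² is always $1 - \mathrm{SS_{res}}/\mathrm{SS_{tot}}$ with the mean and
variance taken on the evaluated set itself, so test R² can be negative.

## Robustness statistics

Per gene, fold-level R² values are averaged across folds first. Then:
per-gene train/test concordance (Pearson and Spearman across genes), binned
mean test R² by training-R² bin, the fraction of *robustly predicted* genes
(test R² at least a threshold fraction of training R², among genes with
training R² above 0.05), overlap counts of top-predicted genes between
models, and predictable-vs-unpredictable comparisons of gene properties
(selected $k$, expression level, coefficient of variation, cis-SNP count,
mean SNP entropy) by two-sample t-tests. Welch's correction is the default
because the two groups are typically very unbalanced; the pooled-variance
test is a flag. SNP entropy decomposes each count into two binary alleles
(0 → 00, 1 → 01, 2 → 11) and averages the two binary Shannon entropies in
bits, so it lies in $[0,1]$ and is comparable across SNPs with different
count supports.

## Enrichment analysis

Which annotations matter? For the elastic net, entities are (gene, SNP)
pairs: for each feature, a hypergeometric test asks whether SNPs carrying the
feature receive non-zero regression weights more (enrichment) or less
(depletion) often than chance. For KNN-IGF, entities are (gene, feature)
pairs and the draw is a non-zero learned $\alpha_m$. Both tails are computed,
BH-adjusted across features within each CV partition, and a feature is called
only when it clears the threshold (default adjusted $p < 0.01$) in *every*
partition — a deliberately conservative all-partitions rule. Continuous
annotation values are binarized at non-zero for carrier status (the threshold
is configurable); elastic-net weights use a $10^{-8}$ tolerance while KNN-IGF
alphas use exact zero, because the greedy search produces exact zeros only
for never-selected initializations. The same hypergeometric+BH machinery is
exposed generically for gene-set (e.g. GO term) enrichment at a 5% FDR
default. The default background for KNN-IGF is all $M$ features per gene; a
flagged alternative restricts to features present among the gene's SNPs.

## The synthetic-data generator

Real genotype-expression panels cannot ship with a package, so every claim
the test suite makes is grounded in simulated panels with known truth.
`simulationSpec()` controls: populations and individuals per population
(default 4 × 50, close to classic multi-population reference panels), genes
and cis-SNPs per gene, per-population allele frequencies drawn uniformly
from a range (default 0.1–0.5, keeping minor-allele orientation global),
heritability $h^2$ (the fraction of expression variance from planted
genotype effects; noise is scaled from the realized genetic variance so the
sample $h^2$ matches in expectation), the number of causal SNPs, the effect
model (linear, dominant, or epistatic pairwise products), the fraction of
causal SNPs whose effects are shared across populations, and an annotation
model in which designated informative features tag causal SNPs with one
probability and background SNPs with another, alongside pure-noise features.

What the generator does *not* emulate: linkage disequilibrium (SNPs are
independent; an LD-aware extension would change KNN's neighbor structure),
trans effects, expression measurement error structure beyond Gaussian noise,
and realistic allele-frequency spectra. Passing tests therefore demonstrate
correctness of the algorithms and their contracts under the stated
generative model, not performance claims about any real cohort.

Genes are laid out on one chromosome with cis windows spaced so they never
overlap and each window contains exactly the requested number of SNPs; the
ground truth (causal SNPs, effects, realized $h^2$) is written alongside the
dataset as `truth.tsv` so downstream checks can join predictions to truth.

## Numerical and design choices

* **Coordinates** are 1-based inclusive on both ends; the cis window is
  $[\mathrm{start} - W, \mathrm{end} + W]$ with $W = 100$ kb by default.
  Overlap arithmetic is delegated to IRanges.
* **Missing genotypes** are imputed per SNP by the mode of observed calls
  (ties toward the smaller count), preserving the $\{0,1,2\}$ support so
  unweighted distances stay integral; mean imputation is a flag. All-missing
  columns are an error naming the SNP.
* **Genotype file orientation** on disk is SNPs-as-rows
  (`snp_id, chromosome, position`, then individuals), the dosage-file
  convention, because per-SNP coordinates then travel with the counts; the
  loader transposes to individuals × SNPs internally. Numeric values are
  written with 17 significant digits so a write/read round trip is exact.
* **PCA correction** (optional, default off) removes the projections onto
  the top-2 principal axes of the column-centered cis-genotype submatrix,
  per gene. Computing components genome-wide instead is one flag away; the
  per-gene reading keeps tasks independent.
* **Degenerate inputs**: constant response or all-constant SNPs are errors;
  rank-deficient PCA removes only the available components with a warning;
  zero-variance pair vectors give MRC 0.
* **Problem sizes** in the tests and acceptance script (panels of 120–200
  individuals, 20–50 SNPs per gene, 20–200 genes, 20-seed replicates) are
  chosen to estimate each property with comfortable margins while keeping
  the full suite around a minute of CPU.

## Worked example

```{r example, eval = FALSE}
spec <- simulationSpec(nPerPop = 50, nPopulations = 4, nGenes = 10,
  snpsPerGene = 20, h2 = 0.4, seed = 1)
sim <- simulateDataset(spec)
res <- runGeneCv(sim$dataset, models = c("single", "enet", "knn", "combined"),
  scheme = "cross_pop", seed = 2)
agg <- aggregateGeneR2(res$summary)
aggregate(test_r2 ~ model, agg, mean)
robustnessFraction(agg$train_r2[agg$model == "combined"],
  agg$test_r2[agg$model == "combined"], threshold = 0.5)
```

## Known limitations

The greedy pool search finds a local MRC maximum; no global-optimality claim
is made. The MRC surrogate can disagree with the final R² objective for
pathological annotation matrices. Heavily correlated SNPs (absent from the
generator's default) would make the elastic net's selected-SNP identities
unstable even when predictions are stable, which matters for the enrichment
analysis's selection sets. Enrichment p-values treat (gene, SNP) entities as
exchangeable draws, ignoring within-gene correlation of selections; the
all-partitions rule partly compensates by demanding replication.
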