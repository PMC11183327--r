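# scIFS

Marker-gene selection and cell-state classification for single-cell
RNA-seq, built around information-based gene ranking and incremental
feature selection.

## The problem

Annotating cell subpopulations in scRNA-seq data — and finding the small
set of genes that characterizes each subpopulation — is usually done by
manual marker curation. scIFS automates both steps for any labelled
cells × genes count matrix: it ranks every gene by how informative it is
about the cell classes, then searches the ranking for the smallest gene
subset that supports accurate supervised classification of cell state.
It is aimed at computational biologists who have a reference atlas (or
any labelled matrix) and want a compact, validated marker panel plus a
reusable classifier.

## Method

**Gene ranking.** Four scorers are provided:

- `mic` (default) — a grid-partition mutual information coefficient. For a
  gene with expression vector *x* and cell labels *Y*, every partition of
  *x* into *k* intervals (cut points between sorted distinct values) is
  considered for *k* = 2…16; for each *k* the partition maximizing the
  plug-in mutual information *I(X;Y)* is found exactly by dynamic
  programming over candidate cuts, *I* is normalized by
  log₂ min(*k*, *k_Y*) so grids of different resolution are comparable,
  and the best normalized value in [0, 1] is the score.
- `mi` — plain plug-in mutual information
  *I(X;Y) = Σ p(x,y) log₂ p(x,y)/(p(x)p(y))* (bits) after equal-frequency
  binning of expression.
- `cv2` — squared coefficient of variation (population variance / mean²),
  the classic unsupervised dispersion score.
- `pca` — explained-variance-weighted squared PCA loadings.

Genes with scores ≤ 0 are excluded; the rest are ranked descending.

**Incremental feature selection (IFS).** Nested prefixes of the ranking
(sizes stepping by 10 to 1,000, by 200 to 5,000, by 1,000 beyond) are each
scored by stratified five-fold cross-validated accuracy with a pluggable
classifier (k-NN, SVM, random forest or XGBoost), using one fixed fold
assignment so curve differences reflect gene subsets only. The optimal
subset size is the smallest one attaining the maximum mean accuracy.

**Evaluation.** Accuracy, per-class and macro precision / recall /
F1 (= 2PR/(P+R)), the confusion matrix, and one-vs-rest ROC AUC computed
with the rank statistic (midranks on ties).

**Synthetic data.** A negative-binomial (Gamma–Poisson) simulator plants
disjoint marker genes per cell type at a configurable log2 fold change
over a flat baseline, with lognormal library-size variation, so the whole
pipeline can be exercised and validated without any external dataset.

## Worked example

```r
library(scIFS)

sim   <- simulateCells(syntheticConfig())        # 1,200 cells x 2,000 genes
sce   <- normalizeCounts(filterGenes(sim))
split <- stratifiedSplit(sce, 0.7, seed = 1)

ranking <- rankGenes(sce, "mic", cells = split$train)
ranking@entries <- ranking@entries[1:200, ]      # sweep the leading prefix

spec  <- classifierSpec("xgboost", seed = 1)
curve <- runIFS(sce[, split$train], ranking, spec, nFolds = 5, seed = 1)
show(curve)
#> IFSCurve: 20 subset sizes (mic ranking, xgboost)
#>   optimal k = 60, mean CV accuracy = 0.9869

model  <- fitFinal(sce[, split$train],
                   head(rankedGenes(ranking), optimalK(curve)), spec)
report <- evaluateModel(model, sce[, split$test])
show(report)
#> EvaluationReport: accuracy 0.9806 | macro P 0.9810 R 0.9804 F1 0.9807 | macro AUC 0.9996
```

So on the bundled synthetic benchmark the `mic` + XGBoost combination
selects a 60-gene panel (the simulation plants exactly 60 markers) and
classifies held-out cells with 98% accuracy; the per-class block of the
report shows no class falling behind.

The same pipeline is available from the shell via `exec/scifs`
(`simulate`, `rank`, `ifs`, `train`, `evaluate` subcommands), each stage
writing its artifact plus a JSON provenance block.

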