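# Shared fixtures and independent oracles used across the test files.

# Tiny labelled experiment built by hand (genes x cells).
toySCE <- function(counts = NULL, labels = NULL) {
  if (is.null(counts))
    counts <- matrix(c(1, 0, 2, 5,
                       0, 0, 0, 0,
                       3, 1, 0, 2), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  if (!is.null(labels))
    SummarizedExperiment::colData(sce)$label <- factor(labels)
  sce
}

# Small well-separated two-class dataset: class means shifted far apart on a
# handful of informative genes, pure noise elsewhere.
separableSCE <- function(nPerClass = 30, nGenes = 20, nInformative = 5,
                         shift = 10, seed = 11) {
  set.seed(seed)
  n <- 2 * nPerClass
  x <- matrix(rnorm(n * nGenes), nGenes, n)
  lab <- rep(c("a", "b"), each = nPerClass)
  x[seq_len(nInformative), lab == "b"] <-
    x[seq_len(nInformative), lab == "b"] + shift
  dimnames(x) <- list(sprintf("g%02d", seq_len(nGenes)),
                      sprintf("c%03d", seq_len(n)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = abs(x), logcounts = x))
  SummarizedExperiment::colData(sce)$label <- factor(lab)
  sce
}

# A small simulated dataset reused by several files (cheap: 200 x 300).
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCells(syntheticConfig(
        nCells = 200, nGenes = 300, nTypes = 3, markersPerType = 8,
        log2FoldChange = 2, seed = 13))
    cache
  }
})

# Brute-force plug-in mutual information straight from the definition:
# sum over the joint table of p(x,y) log2 [ p(x,y) / (p(x) p(y)) ].
bruteMI <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pxy <- tab[i, j] / n
    if (pxy > 0)
      s <- s + pxy * log2(pxy / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
  }
  s
}

# Shannon entropy in bits.
entropyBits <- function(x) {
  p <- table(x) / length(x)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

# Exhaustive normalized-MI maximization over every interval partition of x
# into 2..maxXBins pieces (cuts between sorted distinct values only).
exhaustiveMic <- function(x, y, maxXBins = 4) {
  ord <- order(x)
  xs <- x[ord]
  ys <- droplevels(factor(y))[ord]
  ky <- nlevels(ys)
  bounds <- which(diff(xs) > 0)
  if (length(bounds) < 1) return(0)
  best <- 0
  for (nCuts in seq_len(min(maxXBins - 1, length(bounds)))) {
    # combn over indices: combn(x, m) misreads a length-1 x as seq_len(x)
    for (ci in utils::combn(length(bounds), nCuts, simplify = FALSE)) {
      cuts <- bounds[ci]
      seg <- rep(seq_len(nCuts + 1), times = diff(c(0, cuts, length(xs))))
      best <- max(best, mutualInformation(seg, ys) /
                          log2(min(nCuts + 1, ky)))
    }
  }
  min(best, 1)
}

# AUC by exhaustive concordant/discordant pair counting (ties count 1/2).
pairCountAuc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
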