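#' Plug-in mutual information between two discrete sequences
#'
#' Computes the plug-in estimate
#' \deqn{I(X;Y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)\,p(y)}}
#' from the joint count table of the two sequences, in bits. Non-negative and
#' symmetric in its arguments; equals \eqn{H(X) - H(X\mid Y)}.
#'
#' @param x,y discrete value sequences of equal length (>= 2); any atomic or
#'   factor type.
#' @return mutual information in bits.
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1))  # H(X) = 1 bit
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2)
    stop("at least two observations are required", call. = FALSE)
  n <- length(x)
  joint <- table(x, y)
  # I = [ sum n_xy log2 n_xy - sum n_x log2 n_x - sum n_y log2 n_y ] / n
  #     + log2 n
  (sum(xlog2x(joint)) - sum(xlog2x(rowSums(joint))) -
     sum(xlog2x(colSums(joint)))) / n + log2(n)
}

#' Discretize a continuous sequence into bins
#'
#' `equal_frequency` cuts at empirical quantile positions so that bin
#' occupancies differ by at most one when all values are distinct (tied values
#' always share a bin); `equal_width` cuts the observed range into intervals
#' of equal length. A constant sequence collapses to a single bin.
#'
#' @param x numeric sequence.
#' @param nBins number of bins (>= 1).
#' @param strategy `"equal_frequency"` or `"equal_width"`.
#' @return integer bin codes in `1:nBins`, aligned with `x`.
#' @export
discretize <- function(x, nBins,
                       strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  if (nBins < 1) stop("nBins must be >= 1", call. = FALSE)
  n <- length(x)
  if (n == 0) return(integer(0))
  if (min(x) == max(x)) return(rep(1L, n))
  if (strategy == "equal_frequency") {
    ord <- order(x)
    prov <- as.integer(floor((seq_len(n) - 1) * nBins / n)) + 1L
    xs <- x[ord]
    prov <- prov[match(xs, xs)]  # tied values take the bin of the first
    bins <- integer(n)
    bins[ord] <- prov
    bins
  } else {
    edges <- seq(min(x), max(x), length.out = nBins + 1L)
    pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
         as.integer(nBins))
  }
}

#' Mutual information of expression with labels after binning
#'
#' Equal-frequency bins the expression values into at most `nBins` bins
#' (capped at the number of distinct values) and returns the plug-in mutual
#' information with the class labels, in bits.
#'
#' @param x numeric expression values.
#' @param y class labels.
#' @param nBins maximum number of expression bins.
#' @return mutual information in bits.
#' @export
miScore <- function(x, y, nBins = 16L) {
  b <- min(nBins, length(unique(x)))
  mutualInformation(discretize(x, b, "equal_frequency"), y)
}

#' Squared coefficient of variation
#'
#' Population variance (1/n denominator) divided by the squared mean — the
#' classic unsupervised dispersion score for highly variable genes. A gene
#' with zero mean has no defined CV2 and is returned as `NA` so the
#' positive-score filter excludes it.
#'
#' @param x numeric sequence of length >= 2.
#' @return CV2, `0` for a constant positive sequence, `NA` for zero mean.
#' @export
cv2Score <- function(x) {
  if (length(x) < 2) stop("at least two observations required", call. = FALSE)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  v <- mean((x - m)^2)
  v / m^2
}

#' PCA loading importance per gene
#'
#' Scores each gene by its explained-variance-weighted squared loading:
#' \deqn{s_g = \sum_c \mathrm{EVR}_c \, w_{gc}^2} where \eqn{w_{gc}} is the
#' loading of gene g on component c and EVR its explained-variance ratio.
#' Scores are non-negative, zero for zero-variance genes, and sum across genes
#' to the total explained-variance ratio of the retained components.
#'
#' @param sce a normalized `SingleCellExperiment`, or a cells-by-genes matrix.
#' @param nComponents number of principal components to retain (capped at the
#'   matrix rank).
#' @return named numeric vector of per-gene scores.
#' @export
pcaGeneScores <- function(sce, nComponents = 50L) {
  x <- if (methods::is(sce, "SummarizedExperiment"))
    cellsByGenes(sce, rownames(sce)) else as.matrix(sce)
  if (nComponents < 1) stop("nComponents must be >= 1", call. = FALSE)
  nComponents <- min(nComponents, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  totVar <- sum(pc$sdev^2)
  if (totVar == 0) return(stats::setNames(numeric(ncol(x)), colnames(x)))
  cc <- seq_len(min(nComponents, ncol(pc$rotation)))
  evr <- pc$sdev[cc]^2 / totVar
  scores <- as.numeric(pc$rotation[, cc, drop = FALSE]^2 %*% evr)
  stats::setNames(scores, colnames(x))
}

#' Rank genes by an importance score
#'
#' Applies one of the four scorers gene by gene — `mic` (grid-partition
#' normalized mutual information, see [micScore()]), `mi` (binned mutual
#' information), `cv2` (dispersion) or `pca` (loading importance) — drops
#' genes with scores at or below zero, and sorts the rest by score descending
#' with ties broken by gene identifier.
#'
#' @param sce a `SingleCellExperiment`; `logcounts` are used when present.
#' @param method scoring method.
#' @param y class labels; required for `mic`/`mi`, taken from
#'   `colData(sce)$label` when omitted, and ignored for `cv2`/`pca`.
#' @param maxXBins maximum expression bins for `mic`/`mi`.
#' @param nComponents retained components for `pca`.
#' @param cells optional cell indices to restrict scoring to (e.g. a training
#'   split).
#' @return a [GeneRanking-class].
#' @export
rankGenes <- function(sce, method = c("mic", "mi", "cv2", "pca"), y = NULL,
                      maxXBins = 16L, nComponents = 50L, cells = NULL) {
  method <- match.arg(method)
  if (!is.null(cells)) sce <- sce[, cells]
  x <- cellsByGenes(sce, rownames(sce))
  params <- list(assay = modelAssay(sce), n_cells = ncol(sce))
  if (method %in% c("mic", "mi")) {
    if (is.null(y)) y <- cellLabels(sce)
    y <- droplevels(factor(y))
    if (length(y) != nrow(x))
      stop("labels are not aligned with the matrix", call. = FALSE)
    if (nlevels(y) < 2)
      stop("at least two classes are required for ", method, call. = FALSE)
    scores <- if (method == "mic")
      apply(x, 2, micScore, y = y, maxXBins = maxXBins)
    else apply(x, 2, miScore, y = y, nBins = maxXBins)
    params$max_x_bins <- as.integer(maxXBins)
  } else if (method == "cv2") {
    scores <- apply(x, 2, cv2Score)
  } else {
    scores <- pcaGeneScores(x, nComponents = nComponents)
    params$n_components <- as.integer(nComponents)
  }
  keep <- !is.na(scores) & scores > 0
  if (!any(keep))
    stop("no gene obtained a positive ", method, " score", call. = FALSE)
  entries <- data.frame(gene_id = names(scores)[keep],
                        score = unname(scores[keep]),
                        stringsAsFactors = FALSE)
  entries <- entries[order(-entries$score, entries$gene_id), , drop = FALSE]
  rownames(entries) <- NULL
  methods::new("GeneRanking", method = method, entries = entries,
               params = params)
}

#' @rdname scIFS-accessors
#' @export
setMethod("rankedGenes", "GeneRanking", function(x, ...) x@entries$gene_id)

#' @rdname scIFS-accessors
#' @export
setMethod("geneScores", "GeneRanking", function(x, ...)
  stats::setNames(x@entries$score, x@entries$gene_id))

setMethod("show", "GeneRanking", function(object) {
  cat("GeneRanking (", object@method, "): ", nrow(object@entries),
      " genes with positive scores\n", sep = "")
  print(utils::head(object@entries, 5))
  if (nrow(object@entries) > 5) cat("...\n")
})

#' Length of a gene ranking
#' @param x a [GeneRanking-class].
#' @export
setMethod("length", "GeneRanking", function(x) nrow(x@entries))

#' Write / read a gene ranking
#'
#' The on-disk form is a CSV `rank,gene_id,score,method` (rank 1-based) with a
#' JSON provenance sidecar (`<file>.provenance.json`) recording the scoring
#' parameters.
#'
#' @param ranking a [GeneRanking-class].
#' @param file CSV path.
#' @export
writeRanking <- function(ranking, file) {
  df <- data.frame(rank = seq_len(length(ranking)),
                   gene_id = ranking@entries$gene_id,
                   score = ranking@entries$score,
                   method = ranking@method)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  writeJson(c(list(method = ranking@method), ranking@params),
            paste0(file, ".provenance.json"))
  invisible(file)
}

#' @rdname writeRanking
#' @export
readRanking <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  prov <- paste0(file, ".provenance.json")
  params <- if (file.exists(prov)) jsonlite::read_json(prov) else list()
  params$method <- NULL
  methods::new("GeneRanking", method = df$method[1],
               entries = data.frame(gene_id = df$gene_id, score = df$score,
                                    stringsAsFactors = FALSE),
               params = params)
}
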