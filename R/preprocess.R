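#' Drop genes never observed in any cell
#'
#' Retains exactly the genes with a total raw count greater than zero across
#' all cells, preserving gene order — the standard benchmark filter that keeps
#' every gene expressed in at least one cell. Idempotent.
#'
#' @param sce a `SingleCellExperiment` with raw counts.
#' @return the filtered `SingleCellExperiment`.
#' @export
filterGenes <- function(sce) {
  tot <- Matrix::rowSums(SummarizedExperiment::assay(sce, "counts"))
  keep <- tot > 0
  if (!any(keep))
    stop("all genes have zero total count; nothing left after filtering",
         call. = FALSE)
  sce[keep, ]
}

#' Library-size normalization with log transform
#'
#' Scales each cell's counts to a common total (`scale`, default 10,000) and
#' applies `log(1 + x)` — the de facto scRNA-seq normalization. The result is
#' stored as the `logcounts` assay and the object is flagged as normalized in
#' its metadata. Within-cell expression rank order is preserved.
#'
#' @param sce a `SingleCellExperiment` with raw counts; every cell must have a
#'   positive total count.
#' @param scale per-cell target total before the log transform.
#' @return the `SingleCellExperiment` with a `logcounts` assay added.
#' @export
normalizeCounts <- function(sce, scale = 1e4) {
  m <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(m)
  if (any(tot <= 0))
    stop("cell(s) with zero total count cannot be normalized: ",
         paste(utils::head(colnames(sce)[tot <= 0], 5), collapse = ", "),
         call. = FALSE)
  lc <- log1p(as.matrix(m) %*% Matrix::Diagonal(x = scale / tot))
  lc <- as.matrix(lc)
  dimnames(lc) <- dimnames(m)
  SummarizedExperiment::assay(sce, "logcounts") <- lc
  S4Vectors::metadata(sce)$normalized <- TRUE
  S4Vectors::metadata(sce)$normalizationScale <- scale
  sce
}

#' Stratified train/test split
#'
#' Splits cells into disjoint train and test sets, drawing
#' `round(trainFraction * class size)` training cells per class (clamped so
#' both sides of every class are non-empty), reproducibly from `seed`.
#'
#' @param y a factor of cell labels, or a `SingleCellExperiment` carrying a
#'   `label` column in its `colData`.
#' @param trainFraction fraction of each class assigned to training,
#'   in (0, 1).
#' @param seed integer seed; the same seed yields the identical split.
#' @return a list with integer index vectors `train` and `test` (ascending),
#'   plus `perClass`, a `data.frame` of realized per-class counts.
#' @export
stratifiedSplit <- function(y, trainFraction = 0.7, seed = 1L) {
  if (methods::is(y, "SummarizedExperiment")) y <- cellLabels(y)
  y <- droplevels(factor(y))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1", call. = FALSE)
  sizes <- table(y)
  if (any(sizes < 2))
    stop("cannot stratify: class(es) with fewer than 2 cells: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  train <- integer(0)
  withSeed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      nTrain <- min(max(round(trainFraction * length(idx)), 1L),
                    length(idx) - 1L)
      train <- c(train, sample(idx)[seq_len(nTrain)])
    }
  })
  train <- sort(train)
  test <- setdiff(seq_along(y), train)
  perClass <- data.frame(class = levels(y),
                         n = as.integer(sizes),
                         n_train = as.integer(table(y[train])),
                         n_test = as.integer(table(y[test])))
  list(train = train, test = test, perClass = perClass,
       trainFraction = trainFraction, seed = as.integer(seed))
}

#' Write a split manifest
#'
#' Records a [stratifiedSplit()] result as JSON: seed, fraction, realized
#' per-class counts and the cell-id lists (ids, never positions, on disk).
#'
#' @param split a [stratifiedSplit()] result.
#' @param sce the `SingleCellExperiment` the split indexes into.
#' @param file output JSON path.
#' @export
writeSplitManifest <- function(split, sce, file) {
  writeJson(list(
    seed = split$seed, train_fraction = split$trainFraction,
    per_class = split$perClass,
    train_cells = colnames(sce)[split$train],
    test_cells = colnames(sce)[split$test]), file)
  invisible(file)
}
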