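#' Read a single-cell expression matrix
#'
#' Reads either a CellRanger-style Matrix Market triple (`matrix.mtx` plus
#' gene-id and cell-id sidecar files, genes as rows on disk) or a dense CSV
#' (header row = gene ids, first column = cell ids, cells as rows on disk).
#' Whatever the on-disk orientation, the returned `SingleCellExperiment`
#' follows the Bioconductor convention: genes as rows, cells as columns, with
#' the counts in `assay(x, "counts")`.
#'
#' @param path for `mtx_triple`, the fixture directory; for `dense_csv`, the
#'   CSV file.
#' @param format `"mtx_triple"` or `"dense_csv"`.
#' @param matrixFile,genesFile,cellsFile file names inside `path` for the
#'   triple layout.
#' @return a `SingleCellExperiment` with unique gene and cell identifiers.
#' @examples
#' dir <- tempfile(); sim <- simulateCells(syntheticConfig(
#'   nCells = 30, nGenes = 40, nTypes = 2, markersPerType = 3, seed = 1))
#' writeFixture(sim, dir)
#' sce <- readExpression(dir)
#' dim(sce)
#' @export
readExpression <- function(path, format = c("mtx_triple", "dense_csv"),
                           matrixFile = "matrix.mtx", genesFile = "genes.tsv",
                           cellsFile = "barcodes.tsv") {
  format <- match.arg(format)
  if (format == "mtx_triple") {
    paths <- file.path(path, c(matrixFile, genesFile, cellsFile))
    miss <- paths[!file.exists(paths)]
    if (length(miss))
      stop("missing input file(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
    genes <- utils::read.delim(paths[2], header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(paths[3], header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m))
      stop("gene sidecar lists ", length(genes), " ids but matrix has ",
           nrow(m), " gene rows", call. = FALSE)
    if (length(cells) != ncol(m))
      stop("cell sidecar lists ", length(cells), " ids but matrix has ",
           ncol(m), " cell columns", call. = FALSE)
    dimnames(m) <- list(genes, cells)
  } else {
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    # on disk cells are rows; transpose into genes-by-cells
    m <- t(as.matrix(df))
  }
  if (any(m < 0))
    stop("expression matrix contains negative entries", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell identifiers", call. = FALSE)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a single-cell expression matrix
#'
#' Inverse of [readExpression()]: emits either the Matrix Market triple or the
#' dense CSV layout. `readExpression` round-trips both exactly.
#'
#' @param sce a `SingleCellExperiment`; the `counts` assay is written.
#' @inheritParams readExpression
#' @return invisibly, the path(s) written.
#' @export
writeExpression <- function(sce, path, format = c("mtx_triple", "dense_csv"),
                            matrixFile = "matrix.mtx",
                            genesFile = "genes.tsv",
                            cellsFile = "barcodes.tsv") {
  format <- match.arg(format)
  m <- SummarizedExperiment::assay(sce, "counts")
  if (format == "mtx_triple") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"),
                                "generalMatrix"),
                    file.path(path, matrixFile))
    writeLines(rownames(m), file.path(path, genesFile))
    writeLines(colnames(m), file.path(path, cellsFile))
    invisible(file.path(path, c(matrixFile, genesFile, cellsFile)))
  } else {
    df <- as.data.frame(t(as.matrix(m)), check.names = FALSE)
    utils::write.csv(cbind(cell_id = rownames(df), df), path,
                     row.names = FALSE, quote = FALSE)
    invisible(path)
  }
}

#' Read and attach per-cell labels
#'
#' `readLabels` parses a `cell_id,label` CSV; `attachLabels` aligns labels to
#' the cells of a `SingleCellExperiment` and stores them as a factor in
#' `colData(sce)$label`.
#'
#' @param file labels CSV with columns `cell_id` and `label`.
#' @return `readLabels`: a `data.frame`; `attachLabels`: the annotated
#'   `SingleCellExperiment`.
#' @export
readLabels <- function(file) {
  if (!file.exists(file)) stop("missing labels file: ", file, call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "label") %in% names(df)))
    stop("labels CSV must have columns 'cell_id' and 'label'", call. = FALSE)
  df
}

#' @rdname readLabels
#' @param sce a `SingleCellExperiment`.
#' @param labels a `data.frame` from [readLabels()].
#' @export
attachLabels <- function(sce, labels) {
  idx <- match(colnames(sce), labels$cell_id)
  if (anyNA(idx))
    stop("cells without a label: ",
         paste(utils::head(colnames(sce)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  SummarizedExperiment::colData(sce)$label <-
    factor(labels$label[idx], levels = sort(unique(labels$label)))
  sce
}

#' @rdname readLabels
#' @export
writeLabels <- function(sce, file) {
  utils::write.csv(data.frame(cell_id = colnames(sce),
                              label = as.character(cellLabels(sce))),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
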