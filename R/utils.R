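# Evaluate expr under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# x * log2(x) with the 0 log 0 = 0 convention; keeps dim attributes.
xlog2x <- function(x) {
  out <- x
  out[] <- 0
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

#' Cell labels of a labelled experiment
#'
#' Returns the per-cell class labels stored in `colData(sce)` as a factor.
#'
#' @param sce a `SingleCellExperiment` (or any `SummarizedExperiment`).
#' @param labelCol name of the `colData` column holding the labels.
#' @return factor of cell labels, aligned with `colnames(sce)`.
#' @export
cellLabels <- function(sce, labelCol = "label") {
  cd <- SummarizedExperiment::colData(sce)
  if (!labelCol %in% names(cd))
    stop("no '", labelCol, "' column in colData; attach labels first",
         call. = FALSE)
  y <- cd[[labelCol]]
  factor(y, levels = if (is.factor(y)) levels(y) else sort(unique(y)))
}

# Expression assay used for modelling: logcounts when present, else counts.
modelAssay <- function(sce) {
  nm <- SummarizedExperiment::assayNames(sce)
  if ("logcounts" %in% nm) "logcounts" else "counts"
}

# Dense cells-by-genes matrix for a gene subset, in the given gene order.
cellsByGenes <- function(sce, genes, assay = modelAssay(sce)) {
  missing <- setdiff(genes, rownames(sce))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  t(as.matrix(SummarizedExperiment::assay(sce, assay)[genes, , drop = FALSE]))
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
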