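#' Accessors for scIFS result objects
#'
#' @param x a result object.
#' @param ... further arguments (unused).
#' @return `rankedGenes` returns the ordered gene identifiers; `geneScores`
#'   the named score vector; `curvePoints` a `data.frame` of IFS points;
#'   `optimalK`/`optimalAccuracy` the selected subset size and its mean
#'   accuracy; `accuracy` the overall accuracy; `perClassMetrics` the
#'   per-class metric table; `confusion` the confusion count matrix.
#' @name scIFS-accessors
NULL

#' @rdname scIFS-accessors
#' @export
setGeneric("rankedGenes", function(x, ...) standardGeneric("rankedGenes"))

#' @rdname scIFS-accessors
#' @export
setGeneric("geneScores", function(x, ...) standardGeneric("geneScores"))

#' @rdname scIFS-accessors
#' @export
setGeneric("curvePoints", function(x, ...) standardGeneric("curvePoints"))

#' @rdname scIFS-accessors
#' @export
setGeneric("optimalK", function(x, ...) standardGeneric("optimalK"))

#' @rdname scIFS-accessors
#' @export
setGeneric("optimalAccuracy",
           function(x, ...) standardGeneric("optimalAccuracy"))

#' @rdname scIFS-accessors
#' @export
setGeneric("accuracy", function(x, ...) standardGeneric("accuracy"))

#' @rdname scIFS-accessors
#' @export
setGeneric("perClassMetrics",
           function(x, ...) standardGeneric("perClassMetrics"))

#' @rdname scIFS-accessors
#' @export
setGeneric("confusion", function(x, ...) standardGeneric("confusion"))

#' Predict cell states with a fitted model
#'
#' @param object a [FittedModel-class].
#' @param newdata a `SingleCellExperiment` (or genes-by-cells matrix) sharing
#'   the model's gene vocabulary.
#' @param ... further arguments passed to methods.
#' @return a list with elements `class` (factor of hard predictions) and
#'   `prob` (cells-by-classes probability matrix, rows summing to 1).
#' @export
setGeneric("predictCells",
           function(object, newdata, ...) standardGeneric("predictCells"))
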