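#' @import methods
NULL

#' Gene ranking produced by a scoring method
#'
#' Ordered genes with strictly positive importance scores from one ranking
#' method (`mic`, `mi`, `cv2` or `pca`). Genes scoring zero or less are
#' excluded at construction; entries are sorted by score descending with ties
#' broken by gene identifier.
#'
#' @slot method single string, the scoring method.
#' @slot entries `data.frame` with columns `gene_id` and `score`.
#' @slot params named list of the parameters the scorer was run with.
#'
#' @seealso [rankGenes()]
#' @export
setClass("GeneRanking",
  representation(method = "character", entries = "data.frame",
                 params = "list"),
  prototype(method = NA_character_,
            entries = data.frame(gene_id = character(), score = numeric()),
            params = list()))

setValidity("GeneRanking", function(object) {
  e <- object@entries
  if (!all(c("gene_id", "score") %in% names(e)))
    return("entries must have columns 'gene_id' and 'score'")
  if (length(object@method) != 1L)
    return("method must be a single string")
  if (anyDuplicated(e$gene_id))
    return("duplicate gene ids in ranking")
  if (nrow(e) && any(e$score <= 0))
    return("all ranking scores must be strictly positive")
  if (nrow(e) > 1L) {
    o <- order(-e$score, e$gene_id)
    if (!identical(o, seq_len(nrow(e))))
      return("entries must be sorted by score desc, gene_id asc on ties")
  }
  TRUE
})

#' Classifier specification
#'
#' Names one of the four supported learners together with its hyperparameters
#' and the seed used for any stochastic part of training. Build with
#' [classifierSpec()] so that library defaults are filled in.
#'
#' @slot name one of `"knn"`, `"svm"`, `"rf"`, `"xgboost"`.
#' @slot params named list of hyperparameters.
#' @slot seed integer seed fixed for stochastic learners.
#'
#' @export
setClass("ClassifierSpec",
  representation(name = "character", params = "list", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
  if (!object@name %in% c("knn", "svm", "rf", "xgboost"))
    return("classifier name must be one of knn, svm, rf, xgboost")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' Incremental feature selection curve
#'
#' Cross-validated accuracy over nested prefixes of a gene ranking, together
#' with the selected optimal subset size. The optimal size attains the maximum
#' mean accuracy; on ties the smallest size wins (parsimony).
#'
#' @slot method ranking method the prefixes were drawn from.
#' @slot classifier the [ClassifierSpec-class] used at every point.
#' @slot k integer vector of evaluated subset sizes, strictly increasing.
#' @slot foldAccuracies matrix, one row per subset size, one column per fold.
#' @slot meanAccuracy numeric vector of per-size mean fold accuracies.
#' @slot optimalK selected subset size.
#' @slot optimalAccuracy mean accuracy at `optimalK`.
#' @slot seed cross-validation fold seed.
#'
#' @seealso [runIFS()]
#' @export
setClass("IFSCurve",
  representation(method = "character", classifier = "ClassifierSpec",
                 k = "integer", foldAccuracies = "matrix",
                 meanAccuracy = "numeric", optimalK = "integer",
                 optimalAccuracy = "numeric", seed = "integer"))

setValidity("IFSCurve", function(object) {
  if (length(object@k) && any(diff(object@k) <= 0))
    return("subset sizes k must be strictly increasing")
  if (nrow(object@foldAccuracies) != length(object@k))
    return("one row of fold accuracies per subset size required")
  if (length(object@meanAccuracy) != length(object@k))
    return("one mean accuracy per subset size required")
  mu <- rowMeans(object@foldAccuracies)
  if (length(mu) && max(abs(mu - object@meanAccuracy)) > 1e-12)
    return("meanAccuracy must be the arithmetic mean of the folds")
  if (!object@optimalK %in% object@k)
    return("optimalK must be one of the evaluated sizes")
  best <- max(object@meanAccuracy)
  if (abs(object@meanAccuracy[match(object@optimalK, object@k)] - best) > 1e-12)
    return("optimalK must attain the maximum mean accuracy")
  if (object@optimalK != min(object@k[object@meanAccuracy >= best - 1e-12]))
    return("ties in mean accuracy must resolve to the smallest k")
  TRUE
})

#' Fitted cell-state classifier
#'
#' Opaque trained-model handle produced by [fitFinal()]: a learner trained on
#' a fixed marker-gene subset, exposing hard class predictions and per-class
#' probabilities for any expression object sharing the gene vocabulary.
#'
#' @slot spec the [ClassifierSpec-class] used for training.
#' @slot genes character vector of gene identifiers the model consumes.
#' @slot classes ordered class labels.
#' @slot fit internal learner object.
#' @slot assayName assay the model expects at prediction time.
#'
#' @seealso [predictCells()], [saveModel()]
#' @export
setClass("FittedModel",
  representation(spec = "ClassifierSpec", genes = "character",
                 classes = "character", fit = "ANY", assayName = "character"))

#' Multiclass confusion matrix
#'
#' Square count matrix over an ordered class set; rows are true classes,
#' columns predicted classes.
#'
#' @slot classes ordered label set.
#' @slot counts square non-negative integer matrix, rows = true classes.
#'
#' @seealso [confusionCounts()]
#' @export
setClass("ConfusionMatrix",
  representation(classes = "character", counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  k <- length(object@classes)
  if (!all(dim(object@counts) == c(k, k)))
    return("counts must be square with one row/column per class")
  if (any(object@counts < 0))
    return("confusion counts must be non-negative")
  TRUE
})

#' Multiclass evaluation report
#'
#' Accuracy, macro- and micro-averaged precision/recall/F1, per-class metrics
#' (optionally with one-vs-rest AUC) and the underlying confusion matrix.
#'
#' @slot accuracy overall accuracy (diagonal mass of the confusion matrix).
#' @slot precisionMacro,recallMacro,f1Macro unweighted class means.
#' @slot precisionMicro,recallMicro,f1Micro globally pooled values.
#' @slot perClass `data.frame` with columns `class`, `precision`, `recall`,
#'   `f1` and `auc` (`NA` when probabilities were not supplied).
#' @slot aucMacro unweighted mean of the per-class one-vs-rest AUCs, `NA`
#'   when not computed.
#' @slot confusion the [ConfusionMatrix-class].
#'
#' @seealso [metricsFromConfusion()], [evaluateModel()]
#' @export
setClass("EvaluationReport",
  representation(accuracy = "numeric",
                 precisionMacro = "numeric", recallMacro = "numeric",
                 f1Macro = "numeric",
                 precisionMicro = "numeric", recallMicro = "numeric",
                 f1Micro = "numeric",
                 perClass = "data.frame", aucMacro = "numeric",
                 confusion = "ConfusionMatrix"))

setValidity("EvaluationReport", function(object) {
  sc <- c(object@accuracy, object@precisionMacro, object@recallMacro,
          object@f1Macro)
  if (any(!is.na(sc) & (sc < 0 | sc > 1)))
    return("all scalar metrics must lie in [0, 1]")
  TRUE
})

#' Synthetic dataset configuration
#'
#' Parameters of the negative-binomial single-cell count generator. Defaults
#' describe the standard fixture used throughout the package tests: 1,200
#' cells, 2,000 genes, 6 cell types with 10 disjoint marker genes each at a
#' log2 fold change of 2 over a flat baseline.
#'
#' @slot nCells,nGenes,nTypes,markersPerType integer dimensions.
#' @slot log2FoldChange marker elevation in the marker's own type (log2).
#' @slot baselineMean negative-binomial mean of a non-marker gene.
#' @slot dispersion shared NB dispersion (variance = mu + dispersion * mu^2).
#' @slot librarySizeMean target mean library size; `NA` means the natural
#'   baseline total `nGenes * baselineMean`.
#' @slot libraryCV coefficient of variation of the lognormal per-cell
#'   library-size multiplier.
#' @slot classProportions simplex vector of length `nTypes`.
#' @slot seed integer seed; the whole draw is reproducible from it.
#'
#' @seealso [syntheticConfig()], [simulateCells()]
#' @export
setClass("SyntheticConfig",
  representation(nCells = "integer", nGenes = "integer", nTypes = "integer",
                 markersPerType = "integer", log2FoldChange = "numeric",
                 baselineMean = "numeric", dispersion = "numeric",
                 librarySizeMean = "numeric", libraryCV = "numeric",
                 classProportions = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nTypes * object@markersPerType > object@nGenes)
    return("nTypes * markersPerType must not exceed nGenes")
  if (length(object@classProportions) != object@nTypes)
    return("classProportions must have one entry per type")
  if (any(object@classProportions < 0) ||
      abs(sum(object@classProportions) - 1) > 1e-8)
    return("classProportions must be non-negative and sum to 1")
  if (object@log2FoldChange < 0) return("log2FoldChange must be >= 0")
  if (object@baselineMean <= 0) return("baselineMean must be > 0")
  if (object@dispersion <= 0) return("dispersion must be > 0")
  if (object@nTypes < 2) return("at least two cell types are required")
  TRUE
})
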