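#' Subset-size schedule for incremental feature selection
#'
#' Sizes step by 10 up to 1,000, by 200 up to 5,000 and by 1,000 thereafter,
#' truncated at and always ending with `nRanked`.
#'
#' @param nRanked number of ranked genes available (>= 1).
#' @return strictly increasing integer vector ending at `nRanked`.
#' @examples
#' stepSchedule(25)    # 10 20 25
#' @export
stepSchedule <- function(nRanked) {
  nRanked <- as.integer(nRanked)
  if (nRanked < 1) stop("nRanked must be >= 1", call. = FALSE)
  s <- c(seq.int(10L, 1000L, 10L),
         seq.int(1200L, 5000L, 200L),
         seq.int(6000L, max(6000L, nRanked), 1000L))
  s <- s[s < nRanked]
  c(s, nRanked)
}

#' Cross-validated accuracy of a classifier on a gene subset
#'
#' Stratified, seeded k-fold cross-validation: the classifier is trained on
#' the named gene subset only and each fold's held-out accuracy is returned.
#' Fold assignment depends only on `(y, nFolds, seed)`, so different gene
#' subsets evaluated under the same seed share identical folds.
#'
#' @param sce a `SingleCellExperiment` with labels in `colData(sce)$label`
#'   (the `logcounts` assay is used when present).
#' @param genes gene identifiers to train on; must exist in `sce`.
#' @param spec a [ClassifierSpec-class].
#' @param nFolds number of folds (every class needs at least `nFolds` cells).
#' @param seed fold-assignment seed.
#' @param folds optional precomputed fold vector (overrides `nFolds`/`seed`).
#' @return numeric vector of per-fold held-out accuracies.
#' @export
crossValidatedAccuracy <- function(sce, genes, spec, nFolds = 5L, seed = 1L,
                                   folds = NULL) {
  y <- cellLabels(sce)
  x <- cellsByGenes(sce, genes)
  if (is.null(folds)) folds <- stratifiedFolds(y, nFolds, seed)
  vapply(sort(unique(folds)), function(f) {
    hold <- folds == f
    clf <- trainClf(spec, x[!hold, , drop = FALSE], droplevels(y[!hold]))
    pred <- predictClf(clf, x[hold, , drop = FALSE])$class
    mean(as.character(pred) == as.character(y[hold]))
  }, numeric(1))
}

#' Incremental feature selection over a gene ranking
#'
#' Sweeps nested prefixes of the ranking at the [stepSchedule()] sizes,
#' scoring each prefix by stratified cross-validated accuracy with a fixed
#' fold assignment, and selects the optimal subset size: the smallest size
#' attaining the maximum mean accuracy.
#'
#' @inheritParams crossValidatedAccuracy
#' @param ranking a [GeneRanking-class] (non-empty).
#' @param schedule optional vector of subset sizes to evaluate; defaults to
#'   `stepSchedule(length(ranking))`.
#' @return an [IFSCurve-class].
#' @export
runIFS <- function(sce, ranking, spec, nFolds = 5L, seed = 1L,
                   schedule = NULL) {
  nRanked <- length(ranking)
  if (nRanked < 1) stop("ranking is empty", call. = FALSE)
  if (is.null(schedule)) schedule <- stepSchedule(nRanked)
  schedule <- as.integer(schedule)
  if (any(schedule > nRanked))
    stop("schedule exceeds the number of ranked genes", call. = FALSE)
  y <- cellLabels(sce)
  folds <- stratifiedFolds(y, nFolds, seed)
  genes <- rankedGenes(ranking)
  acc <- t(vapply(schedule, function(k)
    crossValidatedAccuracy(sce, genes[seq_len(k)], spec, folds = folds),
    numeric(length(unique(folds)))))
  mu <- rowMeans(acc)
  bestIdx <- which(mu >= max(mu) - 1e-12)[1L]   # smallest k on ties
  methods::new("IFSCurve", method = ranking@method, classifier = spec,
               k = schedule, foldAccuracies = acc, meanAccuracy = mu,
               optimalK = schedule[bestIdx], optimalAccuracy = mu[bestIdx],
               seed = as.integer(seed))
}

#' @rdname scIFS-accessors
#' @export
setMethod("curvePoints", "IFSCurve", function(x, ...) {
  df <- data.frame(k = x@k, x@foldAccuracies, mean_accuracy = x@meanAccuracy)
  names(df)[seq_len(ncol(x@foldAccuracies)) + 1L] <-
    paste0("fold_", seq_len(ncol(x@foldAccuracies)))
  df
})

#' @rdname scIFS-accessors
#' @export
setMethod("optimalK", "IFSCurve", function(x, ...) x@optimalK)

#' @rdname scIFS-accessors
#' @export
setMethod("optimalAccuracy", "IFSCurve", function(x, ...) x@optimalAccuracy)

setMethod("show", "IFSCurve", function(object) {
  cat("IFSCurve: ", length(object@k), " subset sizes (", object@method,
      " ranking, ", object@classifier@name, ")\n", sep = "")
  cat("  optimal k = ", object@optimalK, ", mean CV accuracy = ",
      sprintf("%.4f", object@optimalAccuracy), "\n", sep = "")
})

#' Write an IFS curve and its summary
#'
#' Emits `<prefix>.csv` (`k,fold_1..fold_n,mean_accuracy`) and
#' `<prefix>.json` (method, classifier, optimal size/accuracy, seeds).
#'
#' @param curve an [IFSCurve-class].
#' @param prefix output path prefix.
#' @export
writeIFSCurve <- function(curve, prefix) {
  utils::write.csv(curvePoints(curve), paste0(prefix, ".csv"),
                   row.names = FALSE, quote = FALSE)
  writeJson(list(method = curve@method,
                 classifier = list(name = curve@classifier@name,
                                   params = curve@classifier@params,
                                   seed = curve@classifier@seed),
                 n_folds = ncol(curve@foldAccuracies),
                 cv_seed = curve@seed,
                 optimal_k = curve@optimalK,
                 optimal_accuracy = curve@optimalAccuracy),
            paste0(prefix, ".json"))
  invisible(prefix)
}

#' Train the final model on a fixed gene subset
#'
#' Fits the specified classifier on all supplied cells using the given genes
#' only, returning a serializable [FittedModel-class] handle that predicts
#' hard classes and per-class probabilities for any expression object sharing
#' the gene vocabulary.
#'
#' @inheritParams crossValidatedAccuracy
#' @param genes non-empty character vector of gene identifiers.
#' @return a [FittedModel-class].
#' @export
fitFinal <- function(sce, genes, spec) {
  if (length(genes) < 1) stop("gene list is empty", call. = FALSE)
  y <- cellLabels(sce)
  x <- cellsByGenes(sce, genes)
  clf <- trainClf(spec, x, y)
  methods::new("FittedModel", spec = spec, genes = as.character(genes),
               classes = clf$classes, fit = clf, assayName = modelAssay(sce))
}

#' @rdname predictCells
#' @export
setMethod("predictCells", "FittedModel", function(object, newdata, ...) {
  x <- if (methods::is(newdata, "SummarizedExperiment"))
    cellsByGenes(newdata, object@genes, assay = object@assayName)
  else as.matrix(newdata)[, object@genes, drop = FALSE]
  predictClf(object@fit, x)
})

setMethod("show", "FittedModel", function(object) {
  cat("FittedModel:", object@spec@name, "on", length(object@genes),
      "genes,", length(object@classes), "classes\n")
})

#' Persist and restore a fitted model
#'
#' The learner is stored in its native serialization (XGBoost boosters via
#' their raw byte form) inside an RDS file, with a JSON sidecar naming the
#' classifier, gene list and expected preprocessing. Reloaded models give
#' identical predictions.
#'
#' @param model a [FittedModel-class].
#' @param file output RDS path; the sidecar is `<file>.json`.
#' @export
saveModel <- function(model, file) {
  fit <- model@fit
  if (fit$type == "xgboost")
    fit$model <- xgboost::xgb.save.raw(fit$model)
  saveRDS(list(spec = list(name = model@spec@name, params = model@spec@params,
                           seed = model@spec@seed),
               genes = model@genes, classes = model@classes,
               assayName = model@assayName, fit = fit),
          file)
  writeJson(list(classifier = model@spec@name,
                 hyperparameters = model@spec@params,
                 seed = model@spec@seed, n_genes = length(model@genes),
                 genes = model@genes, classes = model@classes,
                 expects_assay = model@assayName), paste0(file, ".json"))
  invisible(file)
}

#' @rdname saveModel
#' @export
loadModel <- function(file) {
  obj <- readRDS(file)
  if (obj$fit$type == "xgboost")
    obj$fit$model <- xgboost::xgb.load.raw(obj$fit$model)
  methods::new("FittedModel",
               spec = classifierSpec(obj$spec$name, obj$spec$params,
                                     obj$spec$seed),
               genes = obj$genes, classes = obj$classes, fit = obj$fit,
               assayName = obj$assayName)
}
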