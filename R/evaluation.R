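#' Confusion matrix over an ordered class set
#'
#' `counts[i, j]` is the number of cells whose true class is `classes[i]` and
#' predicted class `classes[j]`; row sums equal the per-class true counts.
#'
#' @param yTrue,yPred label vectors of equal length; all values must appear
#'   in `classes`.
#' @param classes ordered label set; defaults to the sorted union of the
#'   observed labels.
#' @return a [ConfusionMatrix-class].
#' @export
confusionCounts <- function(yTrue, yPred,
                            classes = sort(unique(c(as.character(yTrue),
                                                    as.character(yPred))))) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(yTrue, yPred)), classes)
  if (length(bad))
    stop("label(s) not in the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(yTrue, levels = classes),
                  factor(yPred, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))
  methods::new("ConfusionMatrix", classes = classes, counts = counts)
}

#' @rdname scIFS-accessors
#' @export
setMethod("confusion", "ConfusionMatrix", function(x, ...) x@counts)

#' @rdname scIFS-accessors
#' @export
setMethod("confusion", "EvaluationReport", function(x, ...)
  x@confusion@counts)

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (", length(object@classes), " classes, ",
      sum(object@counts), " cells)\n", sep = "")
  print(object@counts)
})

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest TP/FP/FN/TN are read off the matrix per class, giving
#' precision TP/(TP+FP), recall TP/(TP+FN) and F1 = 2PR/(P+R); macro values
#' are unweighted class means and micro values pool the counts globally.
#' Overall accuracy is the diagonal mass. When a class has no predicted
#' (or no true) positives its precision (recall) is defined as 0 and a
#' warning is issued.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return an [EvaluationReport-class] with AUC fields `NA`.
#' @examples
#' cm <- confusionCounts(rep(c("a","b"), c(60, 40)),
#'                       rep(c("a","b","a","b"), c(50, 10, 5, 35)))
#' accuracy(metricsFromConfusion(cm))  # 0.85
#' @export
metricsFromConfusion <- function(cm) {
  m <- cm@counts
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safeDiv <- function(num, den, what) {
    zero <- den == 0
    if (any(zero))
      warning("class(es) with zero denominator for ", what, ": ",
              paste(cm@classes[zero], collapse = ", "),
              "; defining the value as 0", call. = FALSE)
    out <- numeric(length(num))
    out[!zero] <- num[!zero] / den[!zero]
    out
  }
  precision <- safeDiv(tp, tp + fp, "precision")
  recall <- safeDiv(tp, tp + fn, "recall")
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  perClass <- data.frame(class = cm@classes, precision = precision,
                         recall = recall, f1 = f1, auc = NA_real_,
                         row.names = NULL, stringsAsFactors = FALSE)
  micro <- sum(tp) / n   # single-label multiclass: micro P = R = F1 = accuracy
  methods::new("EvaluationReport",
               accuracy = sum(tp) / n,
               precisionMacro = mean(precision), recallMacro = mean(recall),
               f1Macro = mean(f1),
               precisionMicro = micro, recallMicro = micro, f1Micro = micro,
               perClass = perClass, aucMacro = NA_real_, confusion = cm)
}

#' One-vs-rest ROC AUC from class probabilities
#'
#' For each class, the AUC of its probability column against the binary
#' "is this class" indicator, computed with the rank statistic (midranks for
#' ties — equivalent to trapezoidal integration of the ROC curve). The macro
#' AUC is the unweighted mean over classes present in `yTrue`; classes absent
#' from `yTrue` get `NA` and are excluded with a warning.
#'
#' @param yTrue true labels.
#' @param prob cells-by-classes probability matrix; rows sum to ~1.
#' @param classes ordered class set, defaulting to `colnames(prob)`.
#' @return list with `perClass` (named AUC vector) and `macro`.
#' @export
rocAuc <- function(yTrue, prob, classes = colnames(prob)) {
  prob <- as.matrix(prob)
  if (is.null(classes))
    stop("class names are required (colnames(prob) or classes=)",
         call. = FALSE)
  if (length(yTrue) != nrow(prob))
    stop("probability rows are not aligned with the labels", call. = FALSE)
  yTrue <- as.character(yTrue)
  auc <- vapply(seq_along(classes), function(j) {
    pos <- yTrue == classes[j]
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0 || nNeg == 0) return(NA_real_)
    r <- rank(prob[, j])                       # midranks on ties
    (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  }, numeric(1))
  names(auc) <- classes
  if (anyNA(auc))
    warning("class(es) absent from yTrue, AUC undefined: ",
            paste(classes[is.na(auc)], collapse = ", "), call. = FALSE)
  list(perClass = auc, macro = mean(auc, na.rm = TRUE))
}

#' ROC curve points for each class
#'
#' One-vs-rest ROC coordinates per class, one row per distinct threshold,
#' suitable for plotting tools (`class,fpr,tpr,threshold`).
#'
#' @inheritParams rocAuc
#' @return a `data.frame` with columns `class`, `fpr`, `tpr`, `threshold`.
#' @export
rocPoints <- function(yTrue, prob, classes = colnames(prob)) {
  yTrue <- as.character(yTrue)
  out <- lapply(classes, function(cl) {
    s <- prob[, cl]
    pos <- yTrue == cl
    th <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(s[pos] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(s[!pos] >= t), numeric(1))
    data.frame(class = cl, fpr = c(0, fpr), tpr = c(0, tpr),
               threshold = c(Inf, th))
  })
  do.call(rbind, out)
}

#' Evaluate a fitted model on labelled cells
#'
#' Predicts the supplied cells and assembles the full report: accuracy,
#' macro/micro precision, recall and F1, the confusion matrix, and per-class
#' plus macro one-vs-rest AUC from the predicted probabilities.
#'
#' @param model a [FittedModel-class].
#' @param sce a labelled `SingleCellExperiment`.
#' @return an [EvaluationReport-class].
#' @export
evaluateModel <- function(model, sce) {
  y <- cellLabels(sce)
  pred <- predictCells(model, sce)
  cls <- model@classes
  cm <- confusionCounts(as.character(y), as.character(pred$class),
                        classes = cls)
  rep <- metricsFromConfusion(cm)
  a <- rocAuc(as.character(y), pred$prob, classes = cls)
  rep@perClass$auc <- unname(a$perClass)
  rep@aucMacro <- a$macro
  rep
}

#' @rdname scIFS-accessors
#' @export
setMethod("accuracy", "EvaluationReport", function(x, ...) x@accuracy)

#' @rdname scIFS-accessors
#' @export
setMethod("perClassMetrics", "EvaluationReport", function(x, ...) x@perClass)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(paste0("EvaluationReport: accuracy %.4f | macro P %.4f",
                     " R %.4f F1 %.4f"),
              object@accuracy, object@precisionMacro, object@recallMacro,
              object@f1Macro))
  if (!is.na(object@aucMacro))
    cat(sprintf(" | macro AUC %.4f", object@aucMacro))
  cat("\n")
  print(object@perClass, digits = 4)
})

#' Write an evaluation report
#'
#' Emits the report as JSON (`<prefix>.json`, noting the macro averaging
#' convention), the confusion matrix as labelled CSV
#' (`<prefix>_confusion.csv`) and optionally ROC curve points
#' (`<prefix>_roc.csv`).
#'
#' @param report an [EvaluationReport-class].
#' @param prefix output path prefix.
#' @param roc optional `data.frame` from [rocPoints()].
#' @export
writeReport <- function(report, prefix, roc = NULL) {
  writeJson(list(
    accuracy = report@accuracy,
    precision_macro = report@precisionMacro,
    recall_macro = report@recallMacro,
    f1_macro = report@f1Macro,
    precision_micro = report@precisionMicro,
    recall_micro = report@recallMicro,
    f1_micro = report@f1Micro,
    auc_macro = report@aucMacro,
    averaging = "macro (unweighted class mean); AUC is one-vs-rest macro",
    per_class = report@perClass), paste0(prefix, ".json"))
  cm <- report@confusion@counts
  utils::write.csv(data.frame(true_class = rownames(cm), cm,
                              check.names = FALSE),
                   paste0(prefix, "_confusion.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(roc))
    utils::write.csv(roc, paste0(prefix, "_roc.csv"), row.names = FALSE,
                     quote = FALSE)
  invisible(prefix)
}
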