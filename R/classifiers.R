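#' Build a classifier specification
#'
#' Fills in library defaults for the four supported learners. Hyperparameters
#' given in `params` override the defaults; everything, including the training
#' seed, is recorded so runs are reproducible.
#'
#' Defaults: knn `k = 5`; svm radial kernel, `cost = 1`; rf `ntree = 300`;
#' xgboost `nrounds = 80`, `max_depth = 6`, `eta = 0.3`, single thread.
#'
#' @param name `"knn"`, `"svm"`, `"rf"` or `"xgboost"`.
#' @param params named list of hyperparameter overrides.
#' @param seed integer seed for stochastic learners.
#' @return a [ClassifierSpec-class].
#' @export
classifierSpec <- function(name = c("xgboost", "knn", "svm", "rf"),
                           params = list(), seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
    knn = list(k = 5L),
    svm = list(kernel = "radial", cost = 1),
    rf = list(ntree = 300L),
    xgboost = list(nrounds = 80L, max_depth = 6L, eta = 0.3, nthread = 1L))
  defaults[names(params)] <- params
  methods::new("ClassifierSpec", name = name, params = defaults,
               seed = as.integer(seed))
}

setMethod("show", "ClassifierSpec", function(object) {
  p <- paste(names(object@params), unlist(object@params),
             sep = "=", collapse = ", ")
  cat("ClassifierSpec:", object@name, "(", p, ") seed", object@seed, "\n")
})

# Train one learner on a dense cells-by-genes matrix. Returns an internal
# handle list(type, model, classes, ...) consumed by predictClf().
trainClf <- function(spec, x, y) {
  y <- droplevels(factor(y))
  p <- spec@params
  model <- switch(spec@name,
    knn = list(train = x, y = y, k = as.integer(p$k)),
    svm = withSeed(spec@seed,
      e1071::svm(x, y, kernel = p$kernel, cost = p$cost,
                 probability = TRUE)),
    rf = withSeed(spec@seed,
      randomForest::randomForest(x, y, ntree = p$ntree)),
    xgboost = {
      d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      withSeed(spec@seed,
        xgboost::xgb.train(
          params = list(objective = "multi:softprob",
                        num_class = nlevels(y),
                        max_depth = p$max_depth, eta = p$eta,
                        nthread = p$nthread, seed = spec@seed),
          data = d, nrounds = p$nrounds, verbose = 0))
    })
  list(type = spec@name, model = model, classes = levels(y))
}

# Deterministic k-NN with full per-class vote fractions. Ties in distance are
# broken by training index; ties in votes by class order.
knnProb <- function(handle, x) {
  tr <- handle$train
  d2 <- outer(rowSums(x^2), rowSums(tr^2), "+") - 2 * tcrossprod(x, tr)
  k <- min(handle$k, nrow(tr))
  cls <- levels(handle$y)
  prob <- matrix(0, nrow(x), length(cls), dimnames = list(NULL, cls))
  yInt <- as.integer(handle$y)
  for (i in seq_len(nrow(x))) {
    nb <- order(d2[i, ])[seq_len(k)]
    prob[i, ] <- tabulate(yInt[nb], nbins = length(cls)) / k
  }
  prob
}

# Per-class probabilities and argmax predictions from a trained handle.
predictClf <- function(clf, x) {
  cls <- clf$classes
  prob <- switch(clf$type,
    knn = knnProb(clf$model, x),
    svm = {
      p <- stats::predict(clf$model, x, probability = TRUE)
      attr(p, "probabilities")[, cls, drop = FALSE]
    },
    rf = stats::predict(clf$model, x, type = "prob")[, cls, drop = FALSE],
    xgboost = {
      p <- stats::predict(clf$model, xgboost::xgb.DMatrix(x))
      colnames(p) <- cls
      p
    })
  prob <- prob / rowSums(prob)
  hard <- factor(cls[max.col(prob, ties.method = "first")], levels = cls)
  list(class = hard, prob = prob)
}

# Seeded stratified fold assignment: within each class, cells are shuffled
# and folds dealt round-robin. Errors when a class is smaller than nFolds.
stratifiedFolds <- function(y, nFolds, seed) {
  y <- droplevels(factor(y))
  sizes <- table(y)
  if (any(sizes < nFolds))
    stop("class(es) smaller than the number of folds: ",
         paste(names(sizes)[sizes < nFolds], collapse = ", "), call. = FALSE)
  folds <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[sample(idx)] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}
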