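test_that("confusion counts are tabulated true-by-predicted", {
  cm <- confusionCounts(c("a", "b", "a"), c("a", "b", "a"),
                        classes = c("a", "b"))
  expect_equal(unname(confusion(cm)), matrix(c(2, 0, 0, 1), 2))
  one <- confusionCounts("a", "b", classes = c("a", "b"))
  expect_equal(unname(confusion(one)), matrix(c(0, 0, 1, 0), 2))
  # row sums conserve the per-class true counts
  set.seed(4)
  yt <- sample(letters[1:4], 60, replace = TRUE)
  yp <- sample(letters[1:4], 60, replace = TRUE)
  cm4 <- confusionCounts(yt, yp, classes = letters[1:4])
  expect_equal(unname(rowSums(confusion(cm4))),
               unname(as.integer(table(factor(yt, levels = letters[1:4])))))
  expect_error(confusionCounts("a", "z", classes = c("a", "b")), "class set")
})

test_that("metrics on the fixed binary matrix match hand arithmetic", {
  yt <- rep(c("neg", "pos"), c(60, 40))
  yp <- rep(c("neg", "pos", "neg", "pos"), c(50, 10, 5, 35))
  rep <- metricsFromConfusion(confusionCounts(yt, yp,
                                              classes = c("neg", "pos")))
  expect_equal(accuracy(rep), 0.85)
  pc <- perClassMetrics(rep)
  expect_equal(pc$precision, c(50 / 55, 35 / 45))
  expect_equal(pc$recall, c(50 / 60, 35 / 40))
  expect_equal(pc$f1, 2 * pc$precision * pc$recall /
                       (pc$precision + pc$recall))
  expect_equal(rep@precisionMacro, mean(c(50 / 55, 35 / 45)))
  expect_equal(rep@recallMacro, mean(c(50 / 60, 35 / 40)))
  # a perfect diagonal gives all ones
  perf <- metricsFromConfusion(confusionCounts(yt, yt,
                                               classes = c("neg", "pos")))
  expect_equal(accuracy(perf), 1)
  expect_equal(perf@f1Macro, 1)
})

test_that("per-class metrics agree with a one-vs-rest recount on random
          matrices", {
  set.seed(99)
  for (i in 1:50) {
    k <- sample(3:6, 1)
    cls <- letters[seq_len(k)]
    m <- matrix(rpois(k * k, 4), k, k)
    diag(m) <- diag(m) + rpois(k, 6)   # keep denominators mostly nonzero
    yt <- rep(cls, times = rowSums(m))
    yp <- unlist(lapply(seq_len(k), function(r) rep(cls, times = m[r, ])))
    rep <- suppressWarnings(
      metricsFromConfusion(confusionCounts(yt, yp, classes = cls)))
    pc <- perClassMetrics(rep)
    for (j in seq_len(k)) {
      tp <- sum(yt == cls[j] & yp == cls[j])
      fp <- sum(yt != cls[j] & yp == cls[j])
      fn <- sum(yt == cls[j] & yp != cls[j])
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      expect_equal(pc$precision[j], p, tolerance = 1e-12)
      expect_equal(pc$recall[j], r, tolerance = 1e-12)
      expect_equal(pc$f1[j], if (p + r > 0) 2 * p * r / (p + r) else 0,
                   tolerance = 1e-12)
    }
    expect_equal(accuracy(rep), mean(yt == yp), tolerance = 1e-12)
    # macro F1 is invariant to a permutation of the class order
    perm <- sample(cls)
    repP <- suppressWarnings(
      metricsFromConfusion(confusionCounts(yt, yp, classes = perm)))
    expect_equal(repP@f1Macro, rep@f1Macro, tolerance = 1e-12)
  }
})

test_that("zero predicted positives yield precision 0 with a warning", {
  yt <- c("a", "a", "b", "b")
  yp <- c("a", "a", "a", "a")
  expect_warning(rep <- metricsFromConfusion(
    confusionCounts(yt, yp, classes = c("a", "b"))), "precision")
  expect_equal(perClassMetrics(rep)$precision[2], 0)
})

test_that("roc auc matches direct pair counting on worked examples", {
  # probability column (.9,.8,.7,.4,.3,.2), positives at ranks 1,2,4 -> 8/9
  p <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  yt <- c("pos", "pos", "neg", "pos", "neg", "neg")
  prob <- cbind(pos = p, neg = 1 - p)
  a <- rocAuc(yt, prob)
  expect_equal(unname(a$perClass["pos"]), 8 / 9)
  # perfect ordering gives 1; an uninformative constant scorer gives 0.5
  perfect <- cbind(pos = c(.9, .8, .7, .3, .2, .1),
                   neg = 1 - c(.9, .8, .7, .3, .2, .1))
  expect_equal(unname(rocAuc(yt[c(1, 2, 4, 3, 5, 6)],
                             perfect)$perClass["pos"]), 1)
  flat <- matrix(0.5, 6, 2, dimnames = list(NULL, c("pos", "neg")))
  expect_equal(unname(rocAuc(yt, flat)$perClass), c(0.5, 0.5))
})

test_that("roc auc equals exhaustive concordant-pair counting", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    k <- sample(2:4, 1)
    cls <- letters[seq_len(k)]
    yt <- sample(cls, n, replace = TRUE)
    if (length(unique(yt)) < 2) next
    prob <- matrix(runif(n * k), n, k, dimnames = list(NULL, cls))
    # occasional ties to exercise the midrank handling
    if (i %% 3 == 0) prob <- round(prob, 1)
    prob <- prob / rowSums(prob)
    a <- suppressWarnings(rocAuc(yt, prob))
    for (j in seq_len(k)) {
      expected <- pairCountAuc(prob[, j], yt == cls[j])
      if (is.na(expected)) expect_true(is.na(a$perClass[j]))
      else expect_equal(unname(a$perClass[j]), expected, tolerance = 1e-12)
    }
    present <- !is.na(a$perClass)
    expect_equal(a$macro, mean(a$perClass[present]), tolerance = 1e-12)
  }
})

test_that("roc auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  y <- sample(c("a", "b"), 40, replace = TRUE)
  p <- runif(40)
  prob <- cbind(a = p, b = 1 - p)
  ours <- rocAuc(y, prob)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = p, levels = c("b", "a"), direction = "<",
    quiet = TRUE)))
  expect_equal(unname(ours$perClass["a"]), ref, tolerance = 1e-12)
})

test_that("a class absent from the truth is excluded from the macro AUC", {
  prob <- matrix(c(.7, .6, .3, .2, .1, .2, .1, .3,
                   .2, .2, .6, .5), 4, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(a <- rocAuc(c("a", "a", "c", "c"), prob), "absent")
  expect_true(is.na(a$perClass["b"]))
  expect_equal(a$macro, mean(a$perClass[c("a", "c")]))
})

test_that("evaluateModel assembles report, confusion and roc artifacts", {
  sce <- separableSCE(nPerClass = 25, nGenes = 15)
  model <- fitFinal(sce, rownames(sce)[1:8], classifierSpec("rf", seed = 2))
  rep <- evaluateModel(model, sce)
  expect_gte(accuracy(rep), 0.95)
  expect_false(anyNA(perClassMetrics(rep)$auc))
  prefix <- tempfile()
  pred <- predictCells(model, sce)
  writeReport(rep, prefix, roc = rocPoints(cellLabels(sce), pred$prob))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$accuracy, accuracy(rep))
  expect_true(grepl("macro", js$averaging))
  cmcsv <- read.csv(paste0(prefix, "_confusion.csv"))
  expect_equal(nrow(cmcsv), 2)
  roc <- read.csv(paste0(prefix, "_roc.csv"))
  expect_identical(names(roc), c("class", "fpr", "tpr", "threshold"))
})
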