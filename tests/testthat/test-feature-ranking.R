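test_that("mutual information reproduces textbook identities", {
  x <- c(0, 0, 1, 1)
  expect_equal(mutualInformation(x, x), 1)          # I(X;X) = H(X) = 1 bit
  expect_equal(mutualInformation(rep(7, 6), c(1, 2, 1, 2, 1, 2)), 0)
  # joint counts [[2,1],[1,2]] over n = 6, against direct summation
  a <- c(0, 0, 0, 1, 1, 1); b <- c(0, 0, 1, 0, 1, 1)
  expect_equal(mutualInformation(a, b), bruteMI(a, b), tolerance = 1e-12)
  expect_error(mutualInformation(1:3, 1:4), "equal length")
})

test_that("mutual information equals the brute-force plug-in formula", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    x <- sample(seq_len(sample(2:4, 1)), n, replace = TRUE)
    y <- sample(seq_len(sample(2:4, 1)), n, replace = TRUE)
    expect_equal(mutualInformation(x, y), bruteMI(x, y), tolerance = 1e-12)
    # symmetry and entropy bounds
    expect_equal(mutualInformation(x, y), mutualInformation(y, x),
                 tolerance = 1e-12)
    mi <- mutualInformation(x, y)
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(entropyBits(x), entropyBits(y)) + 1e-12)
  }
})

test_that("discretize bins as specified in both strategies", {
  expect_equal(discretize(c(1, 2, 3, 4), 2), c(1, 1, 2, 2))
  expect_equal(discretize(rep(3.5, 6), 4), rep(1, 6))
  expect_equal(discretize(c(0, 0, 0, 5, 9, 9), 3, "equal_width"),
               c(1, 1, 1, 2, 3, 3))
  # equal-frequency occupancies differ by <= 1 on distinct values
  set.seed(2)
  x <- sample(seq_len(100))
  for (nb in c(2, 3, 7, 16)) {
    occ <- table(discretize(x, nb))
    expect_lte(diff(range(occ)), 1)
  }
  # tied values always share a bin
  b <- discretize(c(1, 1, 1, 1, 2, 3), 3)
  expect_length(unique(b[1:4]), 1)
})

test_that("micScore attains 1 on perfect threshold separation and matches
          exhaustive partition search", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- rep(c("a", "b"), each = 3)
  expect_equal(micScore(x, y), 1)
  # two classes: the normalizer is log2(2) = 1 for every k_x >= 2, so the
  # score is exactly the best achievable plug-in MI
  expect_equal(micScore(x, y, maxXBins = 8), 1)
  # degenerate x collapses to 0
  expect_equal(micScore(rep(1, 6), y), 0)

  set.seed(303)
  for (i in 1:60) {
    n <- sample(6:12, 1)
    x <- sample(1:6, n, replace = TRUE)
    ky <- sample(2:3, 1)
    y <- sample(letters[seq_len(ky)], n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(micScore(x, y, maxXBins = 4), exhaustiveMic(x, y, 4),
                 tolerance = 1e-12)
  }
})

test_that("micScore is invariant to strictly monotone transforms of x", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(40)
    y <- sample(c("a", "b", "c"), 40, replace = TRUE)
    s <- micScore(x, y)
    expect_equal(micScore(exp(x), y), s, tolerance = 1e-12)
    expect_equal(micScore(rank(x), y), s, tolerance = 1e-12)
  }
})

test_that("cv2 is population variance over squared mean", {
  expect_equal(cv2Score(c(1, 2, 3, 4)), 0.2)     # 1.25 / 6.25
  expect_equal(cv2Score(c(5, 5, 5)), 0)
  set.seed(5)
  x <- rgamma(30, 2)
  expect_equal(cv2Score(2 * x), cv2Score(x), tolerance = 1e-12)
  expect_true(is.na(cv2Score(rep(0, 5))))
})

test_that("pca gene scores follow the explained-variance-weighted loadings", {
  # two perfectly correlated genes: single nontrivial component with
  # loadings proportional to (1, 2)/sqrt(5) -> squared loadings 0.2, 0.8
  set.seed(8)
  b <- rnorm(40)
  x <- cbind(gA = b, gB = 2 * b)
  s <- pcaGeneScores(x, nComponents = 2)
  expect_equal(unname(s["gB"] / s["gA"]), 4, tolerance = 1e-8)
  expect_equal(sum(s), 1, tolerance = 1e-8)  # all variance on one component
  # zero-variance gene scores 0; scores sum to the retained EVR
  x3 <- cbind(x, gC = rep(1, 40), gD = rnorm(40))
  s3 <- pcaGeneScores(x3, nComponents = 3)
  expect_equal(unname(s3["gC"]), 0, tolerance = 1e-10)
  pc <- prcomp(x3, center = TRUE)
  expect_equal(sum(s3), sum(pc$sdev[1:3]^2) / sum(pc$sdev^2),
               tolerance = 1e-8)
})

test_that("rankGenes filters non-positive scores and breaks ties by id", {
  # three genes engineered so one has zero cv2 (constant)
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 2, 2, 2), g3 = c(1, 1, 1, 9))
  colnames(m) <- paste0("c", 1:4)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m))
  rk <- rankGenes(sce, "cv2")
  expect_false("g2" %in% rankedGenes(rk))
  expect_equal(length(rk), 2)
  expect_true(all(geneScores(rk) > 0))
  # identical scores order by gene id ascending
  m2 <- rbind(gB = c(1, 2, 3, 4), gA = c(1, 2, 3, 4))
  colnames(m2) <- paste0("c", 1:4)
  rk2 <- rankGenes(SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m2)), "cv2")
  expect_identical(rankedGenes(rk2), c("gA", "gB"))
})

test_that("rankings are deterministic and recover planted markers", {
  sim <- simulateCells(syntheticConfig(
    nCells = 300, nGenes = 500, nTypes = 3, markersPerType = 10,
    log2FoldChange = 2, seed = 21))
  sce <- normalizeCounts(filterGenes(sim))
  markers <- unlist(S4Vectors::metadata(sim)$markers)
  rk <- rankGenes(sce, "mic")
  rk2 <- rankGenes(sce, "mic")
  expect_identical(rk@entries, rk2@entries)
  # 30 planted markers among 500 genes: at least 8 of any type's 10 in the
  # top 20 of the mic ranking; pool over types via the top-30 here
  top <- head(rankedGenes(rk), 30)
  expect_gte(sum(markers %in% top), 24)
})

test_that("ranking files round-trip through CSV with provenance", {
  sce <- separableSCE()
  rk <- rankGenes(sce, "mi")
  f <- tempfile(fileext = ".csv")
  writeRanking(rk, f)
  back <- readRanking(f)
  expect_identical(rankedGenes(back), rankedGenes(rk))
  expect_equal(geneScores(back), geneScores(rk))
  expect_identical(back@method, "mi")
  df <- read.csv(f)
  expect_identical(names(df), c("rank", "gene_id", "score", "method"))
  expect_identical(df$rank, seq_len(length(rk)))
  expect_true(file.exists(paste0(f, ".provenance.json")))
})
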