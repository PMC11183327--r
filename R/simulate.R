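#' Configure the synthetic single-cell dataset generator
#'
#' Builds a validated [SyntheticConfig-class]. Defaults are the package's
#' standard fixture — 1,200 cells, 2,000 genes, 6 equally likely cell types
#' with 10 disjoint marker genes per type elevated 4-fold (log2FC 2) above a
#' flat baseline of 2 counts, shared negative-binomial dispersion 0.5 and a
#' lognormal library-size multiplier with 25% coefficient of variation.
#'
#' @param nCells,nGenes,nTypes,markersPerType dataset dimensions;
#'   `nTypes * markersPerType` must not exceed `nGenes`.
#' @param log2FoldChange marker elevation (log2) in the marker's own type.
#' @param baselineMean NB mean of every non-marker gene.
#' @param dispersion shared NB dispersion (variance = mu + dispersion * mu^2).
#' @param librarySizeMean target mean library size; `NA` (default) keeps the
#'   natural baseline total `nGenes * baselineMean`, so marker means are not
#'   distorted by rescaling.
#' @param libraryCV coefficient of variation of the per-cell library-size
#'   multiplier.
#' @param classProportions class mixing proportions (default: equal).
#' @param seed integer seed; the entire draw is a pure function of the config.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nCells = 1200L, nGenes = 2000L, nTypes = 6L,
                            markersPerType = 10L, log2FoldChange = 2,
                            baselineMean = 2, dispersion = 0.5,
                            librarySizeMean = NA_real_, libraryCV = 0.25,
                            classProportions = NULL, seed = 7L) {
  if (is.null(classProportions))
    classProportions <- rep(1 / nTypes, nTypes)
  methods::new("SyntheticConfig",
               nCells = as.integer(nCells), nGenes = as.integer(nGenes),
               nTypes = as.integer(nTypes),
               markersPerType = as.integer(markersPerType),
               log2FoldChange = as.numeric(log2FoldChange),
               baselineMean = as.numeric(baselineMean),
               dispersion = as.numeric(dispersion),
               librarySizeMean = as.numeric(librarySizeMean),
               libraryCV = as.numeric(libraryCV),
               classProportions = as.numeric(classProportions),
               seed = as.integer(seed))
}

configAsList <- function(config) {
  list(n_cells = config@nCells, n_genes = config@nGenes,
       n_types = config@nTypes, markers_per_type = config@markersPerType,
       log2_fold_change = config@log2FoldChange,
       baseline_mean = config@baselineMean, dispersion = config@dispersion,
       library_size_mean = config@librarySizeMean,
       library_cv = config@libraryCV,
       class_proportions = config@classProportions, seed = config@seed)
}

#' Simulate a labelled single-cell count matrix with planted markers
#'
#' Draws overdispersed counts from a Gamma–Poisson (negative binomial) model:
#' every gene has mean `baselineMean`, except each type's marker genes, whose
#' mean is multiplied by `2^log2FoldChange` in cells of that type. Cell
#' labels are multinomial in `classProportions`; markers are disjoint across
#' types so recovery can be scored unambiguously. Per-cell expected totals
#' are scaled toward `librarySizeMean` times a lognormal multiplier (mean 1,
#' CV `libraryCV`). Fully reproducible from `config@seed`.
#'
#' @param config a [SyntheticConfig-class].
#' @return a `SingleCellExperiment` with a `counts` assay, `colData$label`,
#'   and the ground truth in `metadata(x)$markers` (named list: type ->
#'   marker gene ids) plus `metadata(x)$config`.
#' @examples
#' sim <- simulateCells(syntheticConfig(nCells = 50, nGenes = 60,
#'   nTypes = 2, markersPerType = 5, seed = 1))
#' table(SummarizedExperiment::colData(sim)$label)
#' @export
simulateCells <- function(config) {
  methods::validObject(config)
  G <- config@nGenes; N <- config@nCells; K <- config@nTypes
  types <- sprintf("type%d", seq_len(K))
  geneIds <- sprintf("gene%0*d", nchar(G), seq_len(G))
  cellIds <- sprintf("cell%0*d", nchar(N), seq_len(N))
  libMean <- if (is.na(config@librarySizeMean))
    G * config@baselineMean else config@librarySizeMean
  fc <- 2^config@log2FoldChange

  withSeed(config@seed, {
    label <- factor(types[sample.int(K, N, replace = TRUE,
                                     prob = config@classProportions)],
                    levels = types)
    markerIdx <- matrix(sample.int(G, K * config@markersPerType),
                        nrow = K, byrow = TRUE)
    sdlog <- sqrt(log(1 + config@libraryCV^2))
    sizeFactor <- stats::rlnorm(N, meanlog = -sdlog^2 / 2, sdlog = sdlog)

    counts <- matrix(0L, G, N, dimnames = list(geneIds, cellIds))
    for (t in seq_len(K)) {
      cellsOfT <- which(label == types[t])
      if (!length(cellsOfT)) next
      mu <- rep(config@baselineMean, G)
      mu[markerIdx[t, ]] <- mu[markerIdx[t, ]] * fc
      scale <- libMean * sizeFactor[cellsOfT] / sum(mu)
      muMat <- outer(mu, scale)
      counts[, cellsOfT] <- stats::rnbinom(length(muMat),
                                           mu = as.vector(muMat),
                                           size = 1 / config@dispersion)
    }
  })

  markers <- stats::setNames(
    lapply(seq_len(K), function(t) geneIds[sort(markerIdx[t, ])]), types)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(label = label, row.names = cellIds))
  S4Vectors::metadata(sce)$markers <- markers
  S4Vectors::metadata(sce)$config <- configAsList(config)
  sce
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Emits the standard fixture layout: `matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv` (the Matrix Market triple), `labels.csv`, `truth.json`
#' (the planted marker map) and `config.yaml`. [readExpression()] and
#' [readLabels()] round-trip it exactly.
#'
#' @param sce a simulated `SingleCellExperiment` from [simulateCells()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeFixture <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeExpression(sce, dir, format = "mtx_triple")
  writeLabels(sce, file.path(dir, "labels.csv"))
  md <- S4Vectors::metadata(sce)
  if (!is.null(md$markers)) writeJson(md$markers, file.path(dir, "truth.json"))
  if (!is.null(md$config))
    yaml::write_yaml(md$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a fixture directory back into a labelled experiment
#'
#' @param dir a directory written by [writeFixture()] (or any CellRanger-style
#'   triple plus `labels.csv`).
#' @return a labelled `SingleCellExperiment`; planted-marker truth and config
#'   are restored into the metadata when present.
#' @export
readFixture <- function(dir) {
  sce <- readExpression(dir, format = "mtx_triple")
  labFile <- file.path(dir, "labels.csv")
  if (file.exists(labFile)) sce <- attachLabels(sce, readLabels(labFile))
  truth <- file.path(dir, "truth.json")
  if (file.exists(truth))
    S4Vectors::metadata(sce)$markers <-
      lapply(jsonlite::read_json(truth), unlist)
  cfg <- file.path(dir, "config.yaml")
  if (file.exists(cfg))
    S4Vectors::metadata(sce)$config <- yaml::read_yaml(cfg)
  sce
}
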