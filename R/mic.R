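#' Grid-partition mutual information coefficient against class labels
#'
#' Scores how well a grid over a gene's expression axis separates the cell
#' classes: among all partitions of `x` into `k` intervals (cut points falling
#' between sorted distinct values), for each `k` in `2..maxXBins` the
#' partition maximizing the plug-in mutual information with `y` is found by
#' dynamic programming, the resulting information is normalized by
#' `log2(min(k, k_y))` to make grids of different sizes comparable, and the
#' maximum normalized value is returned. Lies in `[0, 1]`; `1` is attained by
#' a gene that perfectly separates equiprobable classes. Invariant to strictly
#' monotone transforms of `x`, since cuts act on the order statistics only.
#'
#' The partition search is exact whenever the number of distinct expression
#' values does not exceed `maxCandidates`; beyond that the candidate cut set
#' is coarse-grained to approximately equal-frequency positions, keeping the
#' per-gene cost at `O(maxXBins * maxCandidates^2)`.
#'
#' @param x numeric expression values (length >= 4).
#' @param y class labels with at least two classes.
#' @param maxXBins largest number of expression intervals considered.
#' @param maxCandidates cap on the candidate cut positions.
#' @return normalized score in `[0, 1]`; `0` when `x` has fewer than two
#'   distinct values.
#' @examples
#' x <- c(1, 2, 3, 10, 11, 12)
#' y <- rep(c("a", "b"), each = 3)
#' micScore(x, y)  # 1: one cut separates the classes perfectly
#' @export
micScore <- function(x, y, maxXBins = 16L, maxCandidates = 64L) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("at least four observations are required", call. = FALSE)
  y <- droplevels(factor(y))
  ky <- nlevels(y)
  if (ky < 2) stop("at least two classes are required", call. = FALSE)
  if (maxXBins < 2) stop("maxXBins must be >= 2", call. = FALSE)

  ord <- order(x)
  ys <- as.integer(y)[ord]
  xs <- x[ord]
  bounds <- which(diff(xs) > 0)          # legal cut positions (after index i)
  if (length(bounds) < 1) return(0)      # fewer than two distinct values

  if (length(bounds) + 1L > maxCandidates) {
    # coarse-grain: snap ~equal-frequency targets to the nearest legal cut
    targets <- round(seq_len(maxCandidates - 1L) * n / maxCandidates)
    pick <- vapply(targets,
                   function(t) bounds[which.min(abs(bounds - t))], 0L)
    bounds <- sort(unique(pick))
  }

  # class counts per elementary segment (between consecutive candidate cuts)
  segLen <- diff(c(0L, bounds, n))
  nSeg <- length(segLen)
  seg <- rep(seq_len(nSeg), times = segLen)
  cnt <- matrix(0, nSeg, ky)
  for (cl in seq_len(ky)) cnt[, cl] <- tabulate(seg[ys == cl], nbins = nSeg)
  cum <- rbind(0, apply(cnt, 2, cumsum))
  if (!is.matrix(cum)) cum <- matrix(cum, ncol = ky)

  # cost[a + 1, b] = n_ab * H(Y | segment a+1..b), in bits
  cost <- matrix(Inf, nSeg, nSeg)
  for (a in 0:(nSeg - 1L)) {
    sub <- cum[(a + 2L):(nSeg + 1L), , drop = FALSE]
    sub <- sweep(sub, 2, cum[a + 1L, ])
    tot <- rowSums(sub)
    cost[a + 1L, (a + 1L):nSeg] <- xlog2x(tot) - rowSums(xlog2x(sub))
  }

  classTot <- colSums(cnt)
  hY <- (xlog2x(n) - sum(xlog2x(classTot))) / n

  best <- 0
  dpPrev <- cost[1L, ]                   # one interval covering segments 1..i
  for (k in 2:min(maxXBins, nSeg)) {
    dpNew <- rep(Inf, nSeg)
    for (i in k:nSeg) {
      js <- (k - 1L):(i - 1L)
      dpNew[i] <- min(dpPrev[js] + cost[cbind(js + 1L, i)])
    }
    info <- hY - dpNew[nSeg] / n
    norm <- info / log2(min(k, ky))
    if (norm > best) best <- norm
    dpPrev <- dpNew
  }
  min(max(best, 0), 1)
}
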