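## Differential accessibility between keratinocyte clusters and motif
## over-representation in the resulting class-specific peak sets.

#' Differentially accessible regions between two cell clusters
#'
#' Per-region two-sided Wilcoxon rank-sum test on depth-normalized
#' insertion counts between the two clusters, with Benjamini-Hochberg
#' correction. A region is classed `UK` (up in the first / undifferentiated
#' cluster) or `DK` (up in the second / differentiated cluster) iff
#' `q < alpha`, `|log2FC| > lfc_thresh`, and its detection fraction in
#' the favored cluster is at least `min_frac`; otherwise `NS`.
#' Log fold changes use a pseudocount of 1 on normalized cluster means.
#'
#' @param counts Region x cell integer matrix.
#' @param labels Two-level factor per cell; the first level is treated
#'   as the undifferentiated cluster.
#' @param min_frac Minimum detection fraction in the favored cluster
#'   (default 0.05).
#' @param lfc_thresh Minimum `|log2FC|` (default 0.25).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return A `diff_peak_table` data.frame: `region_id`, `frac1`,
#'   `frac2`, `log2fc`, `p`, `q`, `class`.
#' @export
differential_peaks <- function(counts, labels, min_frac = 0.05,
                               lfc_thresh = 0.25, alpha = 0.05) {
  counts <- as.matrix(counts)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (length(labels) != ncol(counts))
    stop("one label per cell column required")
  g1 <- labels == levels(labels)[1]
  if (sum(g1) < 2 || sum(!g1) < 2)
    stop("each cluster needs at least two cells")

  depth <- colSums(counts)
  if (all(depth == 0)) {
    sf <- rep(1, length(depth))
  } else {
    sf <- depth / stats::median(depth[depth > 0])
    sf[sf == 0] <- 1
  }
  norm <- sweep(counts, 2, sf, "/")

  frac1 <- rowMeans(counts[, g1, drop = FALSE] > 0)
  frac2 <- rowMeans(counts[, !g1, drop = FALSE] > 0)
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, !g1, drop = FALSE])
  log2fc <- log2((mu1 + 1) / (mu2 + 1))

  p <- apply(norm, 1, function(x) {
    if (all(x == x[1])) return(1)
    wilcox_p(x[g1], x[!g1])
  })
  q <- p.adjust(p, method = "BH")

  fav_frac <- ifelse(log2fc > 0, frac1, frac2)
  cls <- rep("NS", nrow(counts))
  hit <- q < alpha & abs(log2fc) > lfc_thresh & fav_frac >= min_frac
  cls[hit & log2fc > 0] <- "UK"
  cls[hit & log2fc < 0] <- "DK"
  out <- data.frame(region_id = rownames(counts), frac1 = frac1,
                    frac2 = frac2, log2fc = log2fc, p = p, q = q,
                    class = cls, stringsAsFactors = FALSE)
  class(out) <- c("diff_peak_table", "data.frame")
  out
}

#' Hypergeometric motif over-representation
#'
#' For each motif, the upper-tail hypergeometric probability of
#' observing at least the foreground occurrence count given the
#' background universe: `p = P[X >= k]`,
#' `X ~ Hypergeometric(N, K, n)` with universe size `N`, motif-positive
#' regions `K`, and foreground size `n`. Fold enrichment is
#' `(k/n) / (K/N)`; Benjamini-Hochberg q-values are computed across
#' motifs.
#'
#' @param fg_regions Foreground region ids (e.g. the UK peak set).
#' @param bg_regions Background region ids; the universe is the union
#'   of foreground and background.
#' @param motif_occurrence Binary region x motif matrix (rownames =
#'   region ids).
#' @return A `motif_enrichment` data.frame: `motif`, `k`, `n`, `K`,
#'   `N`, `fold`, `p`, `q`.
#' @export
motif_enrichment <- function(fg_regions, bg_regions, motif_occurrence) {
  if (length(fg_regions) == 0) stop("foreground region set is empty")
  occ <- as.matrix(motif_occurrence)
  if (!all(occ %in% c(0, 1))) stop("motif occurrence must be binary")
  universe <- union(fg_regions, bg_regions)
  miss <- setdiff(universe, rownames(occ))
  if (length(miss))
    stop("regions absent from occurrence table: ",
         paste(head(miss, 5), collapse = ", "))
  N <- length(universe)
  n <- length(unique(fg_regions))
  K <- colSums(occ[universe, , drop = FALSE])
  k <- colSums(occ[unique(fg_regions), , drop = FALSE])
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  out <- data.frame(motif = colnames(occ), k = k, n = n, K = K, N = N,
                    fold = fold, p = p,
                    q = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("motif_enrichment", "data.frame")
  out
}
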