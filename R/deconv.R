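## Simplified reference-based deconvolution of bulk methylomes into
## keratinocyte-population fractions: marker selection from a
## cell-type expression reference, imputation of a paired promoter
## methylation reference, and weighted non-negative least squares.

#' Build a marker-gene expression reference
#'
#' A gene becomes a marker for the cell type in which it is maximally
#' expressed iff (i) that expression is at least `fold` times the
#' second-highest type and (ii) its marker specificity score — the
#' number of cell types in which it exceeds `expr_threshold` — is at
#' most `mss`. Marker weight is `1/score`.
#'
#' @param expr Gene x cell-type matrix of mean expression.
#' @param mss Maximum marker specificity score (default 3).
#' @param expr_threshold Expression level counting a type as
#'   "expressing" (default 1).
#' @param fold Required ratio of top to second expression (default 2).
#' @return An `expression_reference`: data.frame `gene`, `cell_type`,
#'   `score`, `weight`, plus the `expr` matrix as an attribute.
#' @export
build_expression_reference <- function(expr, mss = 3, expr_threshold = 1,
                                       fold = 2) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least two cell types")
  top_type <- colnames(expr)[max.col(expr, ties.method = "first")]
  top <- apply(expr, 1, max)
  second <- apply(expr, 1, function(r) sort(r, decreasing = TRUE)[2])
  score <- rowSums(expr > expr_threshold)
  is_marker <- top >= fold * second & score >= 1 & score <= mss
  out <- data.frame(gene = rownames(expr)[is_marker],
                    cell_type = top_type[is_marker],
                    score = as.integer(score[is_marker]),
                    weight = 1 / score[is_marker],
                    stringsAsFactors = FALSE)
  missing_types <- setdiff(colnames(expr), out$cell_type)
  if (length(missing_types))
    stop("cell type(s) without markers: ",
         paste(missing_types, collapse = ", "))
  attr(out, "expr") <- expr
  class(out) <- c("expression_reference", "data.frame")
  out
}

#' Impute the methylation reference for the expression markers
#'
#' Restricts markers to those present in a paired promoter-methylation
#' table and keeps only markers whose methylation is anti-correlated
#' with expression across cell types (negative Spearman rank
#' correlation) — encoding the assumption that promoter methylation
#' silences its gene. Marker weights carry over.
#'
#' @param exr An `expression_reference` from
#'   [build_expression_reference()].
#' @param paired Gene x cell-type promoter methylation matrix in
#'   `[0,1]`, columns matching the expression reference's cell types.
#' @return A `methylation_reference`: list with `meth` (markers x cell
#'   types), `weights` (named per marker), `cell_type` (designated type
#'   per marker).
#' @export
impute_methylation_reference <- function(exr, paired) {
  stopifnot(inherits(exr, "expression_reference"))
  paired <- as.matrix(paired)
  expr <- attr(exr, "expr")
  types <- colnames(expr)
  if (!all(types %in% colnames(paired)))
    stop("paired table lacks cell types: ",
         paste(setdiff(types, colnames(paired)), collapse = ", "))
  paired <- paired[, types, drop = FALSE]
  keep <- character(0)
  for (g in exr$gene) {
    if (!g %in% rownames(paired)) next
    rho <- suppressWarnings(cor(expr[g, ], paired[g, ], method = "spearman"))
    if (!is.na(rho) && rho < 0) keep <- c(keep, g)
  }
  lost <- setdiff(types, exr$cell_type[exr$gene %in% keep])
  if (length(lost))
    stop("cell type(s) lost all markers in imputation: ",
         paste(lost, collapse = ", "))
  idx <- match(keep, exr$gene)
  structure(list(meth = paired[keep, , drop = FALSE],
                 weights = setNames(exr$weight[idx], keep),
                 cell_type = setNames(exr$cell_type[idx], keep)),
            class = "methylation_reference")
}

#' Estimate cell-type fractions in bulk methylomes
#'
#' Per sample, weighted non-negative least squares of bulk promoter
#' beta values on the reference columns (marker weights scale the
#' rows), followed by renormalization onto the unit simplex.
#'
#' @param bulk Markers x samples matrix (or [beta_matrix()]) of bulk
#'   promoter methylation.
#' @param ref A `methylation_reference` from
#'   [impute_methylation_reference()].
#' @return A `fraction_estimate`: list with `fractions` (samples x cell
#'   types, rows on the simplex) and `residual` (per-sample weighted
#'   residual norm).
#' @export
estimate_fractions <- function(bulk, ref) {
  stopifnot(inherits(ref, "methylation_reference"))
  x <- if (inherits(bulk, "beta_matrix")) bulk$values else as.matrix(bulk)
  genes <- intersect(rownames(ref$meth), rownames(x))
  K <- ncol(ref$meth)
  if (length(genes) < K)
    stop("need at least as many shared markers as cell types")
  A <- ref$meth[genes, , drop = FALSE]
  if (qr(A)$rank < K)
    stop("methylation reference is rank-deficient across cell types")
  w <- sqrt(ref$weights[genes])
  Aw <- A * w
  fr <- matrix(NA_real_, ncol(x), K,
               dimnames = list(colnames(x), colnames(ref$meth)))
  resid <- setNames(numeric(ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    bw <- x[genes, j] * w
    fit <- pracma::lsqnonneg(Aw, bw)
    f <- fit$x
    if (sum(f) == 0) f <- rep(1 / K, K) else f <- f / sum(f)
    fr[j, ] <- f
    resid[j] <- sqrt(sum((Aw %*% fit$x - bw)^2))
  }
  structure(list(fractions = fr, residual = resid),
            class = "fraction_estimate")
}

#' Compare estimated fractions between subclasses
#'
#' Two-sided Wilcoxon rank-sum test per cell type between two sample
#' groups.
#'
#' @param fr A `fraction_estimate` from [estimate_fractions()].
#' @param groups Named character per sample with two levels.
#' @return Data.frame: `cell_type`, group means, `p`.
#' @export
compare_fractions <- function(fr, groups) {
  stopifnot(inherits(fr, "fraction_estimate"))
  g <- as.character(groups[rownames(fr$fractions)])
  lev <- unique(g[!is.na(g)])
  if (length(lev) != 2) stop("groups must have exactly two levels")
  if (!all(table(factor(g, lev)) >= 1)) stop("each group needs a sample")
  res <- lapply(colnames(fr$fractions), function(ct) {
    a <- fr$fractions[g == lev[1], ct]
    b <- fr$fractions[g == lev[2], ct]
    data.frame(cell_type = ct,
               mean_1 = mean(a), mean_2 = mean(b),
               p = wilcox_p(a, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", lev)
  out
}
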