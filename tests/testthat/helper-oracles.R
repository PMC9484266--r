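# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package's code paths.

# Exhaustive complete-linkage agglomeration cut at k = 2: at each step,
# scan every cluster pair for the minimum complete-linkage distance.
naive_complete_linkage_k2 <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X, method = "euclidean"))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 2) {
    best <- list(d = Inf, i = NA, j = NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best$d) best <- list(d = d, i = i, j = j)
      }
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  membership <- integer(n)
  membership[clusters[[1]]] <- 1L
  membership[clusters[[2]]] <- 2L
  membership
}

same_partition <- function(a, b) {
  identical(unname(a == a[1]), unname(b == b[1]))
}

# Explicit hypergeometric upper-tail sum.
hyper_upper_oracle <- function(k, K, N, n) {
  jmax <- min(n, K)
  if (k > jmax) return(0)
  j <- seq(max(k, max(0, n + K - N)), jmax)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Root-mean-square error after optimal rigid alignment (rotation /
# reflection, no scaling) of centered configurations.
procrustes_rmse <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sqrt(mean((Yc %*% R - Xc)^2))
}

# Minimal region_beta wrapper for hand-built matrices (regions x samples).
as_region_beta <- function(values, region_class = NULL, groups = "Other") {
  if (is.null(region_class))
    region_class <- rep("UK", nrow(values))
  structure(list(
    values = values,
    region_class = setNames(factor(region_class, c("UK", "DK")),
                            rownames(values)),
    n_probes = setNames(rep(1L, nrow(values)), rownames(values)),
    sample_group = setNames(factor(rep_len(groups, ncol(values)),
                                   epiorigin:::SAMPLE_GROUPS),
                            colnames(values))),
    class = "region_beta")
}

# mean silhouette width on 2-D coordinates for given labels
silhouette_mean <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  labs <- as.character(labels)
  s <- vapply(seq_along(labs), function(i) {
    a <- mean(D[i, labs == labs[i] & seq_along(labs) != i])
    b <- min(vapply(setdiff(unique(labs), labs[i]),
                    function(l) mean(D[i, labs == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
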