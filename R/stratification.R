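## Cell-of-origin stratification: probe-to-region mapping, region-level
## methylation averaging, hierarchical subclass assignment, external
## cohort classification, and the supporting probe-level statistics.

#' Map probes into regulatory regions
#'
#' A probe maps to a region iff `start <= pos < end` (half-open). Within
#' a region class regions are disjoint, so a probe maps to at most one
#' region per class; a probe overlapping both a UK and a DK region
#' contributes to both (the classes are analyzed separately).
#'
#' @param manifest A [probe_manifest()].
#' @param regions A [region_set()].
#' @return A `probe_region_map` data.frame with columns `probe_id`,
#'   `region_id`, `region_class`, plus an attribute `class_totals`
#'   giving mapped probe counts per class.
#' @export
map_probes_to_regions <- function(manifest, regions) {
  stopifnot(inherits(manifest, "probe_manifest"), inherits(regions, "region_set"))
  hits <- GenomicRanges::findOverlaps(manifest_granges(manifest),
                                      regions_granges(regions))
  out <- data.frame(
    probe_id = manifest$probe_id[S4Vectors::queryHits(hits)],
    region_id = regions$region_id[S4Vectors::subjectHits(hits)],
    region_class = as.character(regions$region_class[S4Vectors::subjectHits(hits)]),
    stringsAsFactors = FALSE)
  attr(out, "class_totals") <- table(factor(out$region_class, c("UK", "DK")))
  class(out) <- c("probe_region_map", "data.frame")
  out
}

#' Average methylation per region
#'
#' For each region and sample, the arithmetic mean of beta over the
#' region's non-missing probes. A region is missing for a sample only
#' when all of its probes are missing; regions with no mapped probes in
#' the matrix are absent.
#'
#' @param beta A [beta_matrix()].
#' @param map A probe-region map from [map_probes_to_regions()].
#' @return A `region_beta` object: list with `values` (regions x samples
#'   matrix), `region_class` (named factor), `n_probes` (probes used per
#'   region), and `sample_group` carried over.
#' @export
region_beta <- function(beta, map) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (nrow(map) == 0) stop("probe-region map is empty")
  m <- map[map$probe_id %in% rownames(beta$values), , drop = FALSE]
  if (nrow(m) == 0) stop("no mapped probes present in the beta matrix")
  ## a probe can appear once per class; treat (region) as the grouping key
  x <- beta$values[m$probe_id, , drop = FALSE]
  grp <- m$region_id
  obs <- !is.na(x)
  x0 <- ifelse(obs, x, 0)
  sums <- rowsum(x0, grp)
  ns <- rowsum(obs + 0, grp)
  vals <- sums / ns
  vals[ns == 0] <- NA_real_
  cls <- m$region_class[match(rownames(vals), m$region_id)]
  npr <- as.integer(table(grp)[rownames(vals)])
  structure(list(values = vals,
                 region_class = setNames(factor(cls, c("UK", "DK")),
                                         rownames(vals)),
                 n_probes = setNames(npr, rownames(vals)),
                 sample_group = beta$sample_group),
            class = "region_beta")
}

#' Stratify tumors into cell-of-origin subclasses
#'
#' Hierarchical clustering (complete linkage, Euclidean distance over
#' region methylation vectors) of all samples, cut into two clusters at
#' the final merge. The cluster containing the strict majority of
#' healthy samples defines the keratinocyte-like side — healthy
#' epidermis predominantly carries the methylome of terminally
#' differentiated keratinocytes — and tumors in the other cluster are
#' labeled EpSC-like.
#'
#' Samples missing more than 20% of the retained regions are dropped
#' with a warning; regions with remaining missing values are then
#' removed so the distance matrix is complete.
#'
#' @param rb A `region_beta` object from [region_beta()].
#' @param healthy_ids Sample ids of the healthy reference samples.
#' @param region_class_filter `"UK"`, `"DK"`, or `"both"`.
#' @param row_zscore If TRUE, z-score each region across samples before
#'   clustering (display-parity option; default clusters on raw means).
#' @return A `subclass_assignment`: list with `labels` (named character:
#'   `EpSC-like`, `Keratinocyte-like`, `Healthy-reference`), `hclust`
#'   (the dendrogram), `k = 2`, and `n_regions_used`.
#' @export
hierarchical_stratify <- function(rb, healthy_ids,
                                  region_class_filter = c("both", "UK", "DK"),
                                  row_zscore = FALSE) {
  region_class_filter <- match.arg(region_class_filter)
  stopifnot(inherits(rb, "region_beta"))
  vals <- rb$values
  if (region_class_filter != "both")
    vals <- vals[rb$region_class[rownames(vals)] == region_class_filter, ,
                 drop = FALSE]
  if (nrow(vals) == 0) stop("no regions left after class filtering")
  if (!all(healthy_ids %in% colnames(vals)))
    stop("healthy_ids not all present in the matrix")
  if (length(healthy_ids) < 1) stop("need at least one healthy sample")

  ## completeness filtering: drop bad samples, then incomplete regions
  frac_missing <- colMeans(is.na(vals))
  bad <- frac_missing > 0.2
  if (any(bad)) {
    warning("dropping ", sum(bad), " sample(s) missing >20% of regions: ",
            paste(colnames(vals)[bad], collapse = ", "))
    vals <- vals[, !bad, drop = FALSE]
    healthy_ids <- intersect(healthy_ids, colnames(vals))
    if (length(healthy_ids) < 1)
      stop("no healthy samples left after completeness filtering")
  }
  vals <- vals[complete.cases(vals), , drop = FALSE]
  if (nrow(vals) == 0) stop("no complete regions left")
  tumor_ids <- setdiff(colnames(vals), healthy_ids)
  if (length(tumor_ids) < 2) stop("need at least two tumor samples")

  if (row_zscore) {
    mu <- rowMeans(vals); s <- apply(vals, 1, sd)
    s[s == 0] <- 1
    vals <- (vals - mu) / s
  }

  hc <- hclust(dist(t(vals), method = "euclidean"), method = "complete")
  cl <- cutree(hc, k = 2)
  if (length(unique(cl)) < 2) stop("clustering did not yield two clusters")

  n_healthy_in <- tabulate(cl[healthy_ids], 2)
  if (n_healthy_in[1] == n_healthy_in[2])
    stop("healthy samples split evenly between clusters; ",
         "keratinocyte-like side is ambiguous")
  ker_cluster <- which.max(n_healthy_in)

  labels <- ifelse(cl == ker_cluster, "Keratinocyte-like", "EpSC-like")
  labels[healthy_ids] <- "Healthy-reference"
  structure(list(labels = labels[colnames(vals)], hclust = hc, k = 2L,
                 n_regions_used = nrow(vals),
                 region_class_filter = region_class_filter),
            class = "subclass_assignment")
}

#' @export
print.subclass_assignment <- function(x, ...) {
  cat("<subclass_assignment> on", x$n_regions_used, "regions (",
      x$region_class_filter, ")\n")
  print(table(x$labels))
  invisible(x)
}

#' Export a stratification dendrogram as Newick
#' @param assignment A `subclass_assignment`.
#' @param path Output file.
#' @export
write_dendrogram <- function(assignment, path) {
  ape::write.tree(ape::as.phylo(assignment$hclust), file = path)
  invisible(path)
}

#' Classify an external cohort against a healthy reference
#'
#' Combines an external cohort with the reference healthy samples,
#' restricts to shared probes, and reruns region averaging and
#' hierarchical stratification, so the external tumors are labeled by
#' which side of the healthy-anchored split they fall on.
#'
#' @param new_beta External cohort [beta_matrix()].
#' @param healthy_ref Healthy reference [beta_matrix()].
#' @param regions,manifest Region set and manifest defining the mapping.
#' @param region_class_filter Passed to [hierarchical_stratify()].
#' @param min_overlap Minimum fraction of region-mapped reference probes
#'   that the external cohort must share (default 0.5).
#' @return A `subclass_assignment` over the combined samples.
#' @export
classify_cohort <- function(new_beta, healthy_ref, regions, manifest,
                            region_class_filter = "both", min_overlap = 0.5) {
  map <- map_probes_to_regions(manifest, regions)
  ref_mapped <- intersect(map$probe_id, rownames(healthy_ref$values))
  shared <- intersect(ref_mapped, rownames(new_beta$values))
  if (length(ref_mapped) == 0) stop("no region-mapped probes in reference")
  overlap <- length(shared) / length(ref_mapped)
  if (overlap < min_overlap)
    stop(sprintf("probe overlap %.3f below the %.2f floor", overlap, min_overlap))
  if (any(colnames(new_beta$values) %in% colnames(healthy_ref$values)))
    stop("sample ids collide between cohorts")
  comb <- cbind(new_beta$values[shared, , drop = FALSE],
                healthy_ref$values[shared, , drop = FALSE])
  bm <- beta_matrix(comb, c(as.character(new_beta$sample_group),
                            as.character(healthy_ref$sample_group)))
  rb <- region_beta(bm, map)
  hierarchical_stratify(rb, healthy_ids = colnames(healthy_ref$values),
                        region_class_filter = region_class_filter)
}

#' PCA overview of a methylome cohort
#'
#' Centered (unscaled) principal component analysis over samples using
#' all complete probes. Axis signs are fixed by orienting each
#' component so its largest-magnitude loading is positive.
#'
#' @param beta A [beta_matrix()].
#' @param n_components Number of components to return (default 2).
#' @return List with `coords` (samples x components), `explained`
#'   (variance fractions), and `sdev`.
#' @export
pca_overview <- function(beta, n_components = 2) {
  x <- beta$values[complete.cases(beta$values), , drop = FALSE]
  if (ncol(x) < 2) stop("need at least two samples")
  if (nrow(x) == 0) stop("no complete probes")
  if (all(apply(x, 1, sd) == 0)) stop("constant matrix: no variance to decompose")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  list(coords = coords,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       sdev = pc$sdev[seq_len(k)])
}

#' Differentially methylated probes via a moderated two-group test
#'
#' Per-probe two-group linear model with empirical-Bayes variance
#' shrinkage: residual variances are shrunk toward a pooled prior with
#' prior degrees of freedom `d0` estimated by method-of-moments on
#' log-variances (set `d0 = 0` for ordinary t-tests, `d0 = Inf` for a
#' fully pooled variance). Benjamini-Hochberg q-values are reported;
#' the significance flag applies a raw `p < p_threshold` rule.
#'
#' @param beta A [beta_matrix()].
#' @param groups Two-level factor (or character) per sample.
#' @param p_threshold Significance threshold on the raw p-value
#'   (default 0.05).
#' @param d0 Optional prior degrees of freedom override.
#' @param s0 Optional prior standard deviation override (used with
#'   `d0 = Inf`; defaults to the moment estimate, or the root mean
#'   pooled variance when `d0 = Inf`).
#' @return A `dmp_table` data.frame: `probe_id`, `diff` (group1 -
#'   group2 mean difference), `t`, `p`, `q`, `significant`, plus
#'   attributes `d0` and `s0`.
#' @export
dmp_test <- function(beta, groups, p_threshold = 0.05, d0 = NULL, s0 = NULL) {
  x <- beta$values
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two samples")

  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, var)
  v2 <- apply(x[, !g1, drop = FALSE], 1, var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df

  if (is.null(d0) || is.null(s0)) {
    mom <- moment_prior(s2, df)
    if (is.null(d0)) d0 <- mom$d0
    if (is.null(s0)) s0 <- if (is.infinite(d0)) sqrt(mean(s2)) else mom$s0
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0^2, length(s2)) else
    if (d0 == 0) s2 else (d0 * s0^2 + df * s2) / (d0 + df)
  tstat <- (m1 - m2) / sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat[s2_tilde == 0 & m1 == m2] <- 0
  df_tot <- df + d0
  p <- if (is.infinite(df_tot)) 2 * stats::pnorm(-abs(tstat)) else
    2 * pt(-abs(tstat), df = df_tot)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(probe_id = rownames(x), diff = m1 - m2, t = tstat,
                    p = p, q = q, significant = p < p_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0") <- s0
  class(out) <- c("dmp_table", "data.frame")
  out
}

## method-of-moments fit of the scaled-F prior on per-probe variances,
## via the log-variance mean/variance identities for the log-F.
moment_prior <- function(s2, df) {
  pos <- s2 > 0
  if (sum(pos) < 2) return(list(d0 = Inf, s0 = sqrt(mean(s2))))
  z <- log(s2[pos])
  ev <- var(z) - trigamma(df / 2)
  if (ev <= 1e-10) return(list(d0 = Inf, s0 = sqrt(mean(s2[pos]))))
  d0 <- 2 * trigamma_inverse(ev)
  s0_2 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0 = sqrt(s0_2))
}

## Newton inversion of trigamma on (0, Inf)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Probe fractions over CpG-island context
#'
#' @param probe_ids Probe ids to summarize.
#' @param manifest A [probe_manifest()].
#' @return Named numeric vector of fractions over
#'   `Island, Shore, Shelf, OpenSea` (sums to 1).
#' @export
probe_context_fractions <- function(probe_ids, manifest) {
  if (length(probe_ids) == 0) stop("empty probe list")
  hit <- match(probe_ids, manifest$probe_id)
  if (anyNA(hit)) stop("probes absent from manifest: ",
                       paste(head(probe_ids[is.na(hit)], 5), collapse = ", "))
  tab <- table(manifest$island_relation[hit])
  setNames(as.numeric(tab) / length(probe_ids), names(tab))
}

#' Score marker promoter regions per sample and compare groups
#'
#' For marker gene promoters (e.g. the miR-200c/141 cluster and miR-205),
#' computes each sample's mean beta over the marker's probes and tests
#' the requested group contrast with a two-sided Wilcoxon rank-sum test.
#'
#' @param beta A [beta_matrix()].
#' @param marker_spec Named list: marker name -> character vector of
#'   probe ids.
#' @param groups Named character/factor per sample.
#' @param contrast Length-2 character: the two group levels to compare.
#' @return List per marker with `scores` (named per-sample means),
#'   `group_means`, and `p` (Wilcoxon).
#' @export
marker_region_score <- function(beta, marker_spec, groups,
                                contrast = NULL) {
  stopifnot(is.list(marker_spec), !is.null(names(marker_spec)))
  groups <- setNames(as.character(groups), colnames(beta$values))
  if (is.null(contrast)) contrast <- unique(groups)[1:2]
  out <- list()
  for (mk in names(marker_spec)) {
    probes <- intersect(marker_spec[[mk]], rownames(beta$values))
    if (length(probes) == 0)
      stop("marker '", mk, "' has no probes present in the beta matrix")
    sc <- colMeans(beta$values[probes, , drop = FALSE], na.rm = TRUE)
    a <- sc[groups == contrast[1]]
    b <- sc[groups == contrast[2]]
    p <- wilcox_p(a, b)
    out[[mk]] <- list(scores = sc,
                      group_means = setNames(c(mean(a), mean(b)), contrast),
                      p = p)
  }
  out
}
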