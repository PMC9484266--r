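## Integration of sparse binary single-cell methylomes with binarized
## bulk methylomes: pairwise mismatch dissimilarity, classical MDS,
## proximity-based cell classification, and chromatin-state summaries.

#' Binarize a beta matrix
#'
#' Thresholds methylation fractions at 0.5 (inclusive: `>= 0.5` becomes
#' 1, `< 0.5` becomes 0) to match the binary nature of single-cell
#' calls. Missing stays missing.
#'
#' @param beta A [beta_matrix()] or numeric matrix in `[0,1]`.
#' @return Integer matrix of 0/1 (and `NA`) with the same dimnames.
#' @export
binarize <- function(beta) {
  x <- if (inherits(beta, "beta_matrix")) beta$values else as.matrix(beta)
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("beta values must lie in [0,1]")
  out <- ifelse(x >= 0.5, 1L, 0L)
  dimnames(out) <- dimnames(x)
  out
}

site_key <- function(chrom, pos) {
  if (length(pos) == 0) return(character(0))
  paste0(chrom, ":", pos)
}

## Assemble a sparse call representation over a common position space:
## entities = cells then bulk columns; returns observation and
## methylated-call indicator matrices (entities x sites).
call_matrices <- function(profiles, bulk_bin = NULL, positions = NULL) {
  keys <- character(0)
  if (length(profiles))
    keys <- unique(unlist(lapply(profiles, function(p) site_key(p$chrom, p$pos))))
  if (!is.null(bulk_bin)) keys <- unique(c(keys, rownames(bulk_bin)))
  if (!is.null(positions)) keys <- positions
  n_cell <- length(profiles)
  n_bulk <- if (is.null(bulk_bin)) 0L else ncol(bulk_bin)
  ents <- c(vapply(profiles, `[[`, "", "cell_id"),
            if (n_bulk) colnames(bulk_bin))
  ii_l <- list(); jj_l <- list(); vv_l <- list()
  for (i in seq_len(n_cell)) {
    p <- profiles[[i]]
    j <- match(site_key(p$chrom, p$pos), keys)
    keep <- !is.na(j)
    ii_l[[i]] <- rep.int(i, sum(keep))
    jj_l[[i]] <- j[keep]
    vv_l[[i]] <- p$call[keep]
  }
  if (n_bulk) {
    j <- match(rownames(bulk_bin), keys)
    for (b in seq_len(n_bulk)) {
      col <- bulk_bin[, b]
      keep <- !is.na(col) & !is.na(j)
      ii_l[[n_cell + b]] <- rep.int(n_cell + b, sum(keep))
      jj_l[[n_cell + b]] <- j[keep]
      vv_l[[n_cell + b]] <- as.integer(col[keep])
    }
  }
  ii <- unlist(ii_l); jj <- unlist(jj_l); vv <- unlist(vv_l)
  obs <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(length(ents), length(keys)),
                              dimnames = list(ents, keys))
  meth <- Matrix::sparseMatrix(i = ii[vv == 1L], j = jj[vv == 1L], x = 1,
                               dims = c(length(ents), length(keys)),
                               dimnames = list(ents, keys))
  list(obs = obs, meth = meth)
}

#' Pairwise methylation dissimilarity over shared covered sites
#'
#' The dissimilarity between two entities (single cells or binarized
#' bulk samples) is the fraction of mismatching binary calls over the
#' CpG sites covered in both — a normalized Hamming distance that
#' degrades gracefully under single-cell sparsity. Pairs sharing fewer
#' than `min_shared` sites are set to `NA`.
#'
#' @param profiles List of [scmeth_profile()] (may be empty).
#' @param bulk_bin Optional binarized bulk matrix (sites x samples,
#'   rownames `"chrom:pos"` with 0-based positions), e.g. from
#'   [binarize()] of a beta matrix indexed by manifest positions.
#' @param min_shared Minimum shared covered sites for a defined
#'   dissimilarity (default 50).
#' @return A `dissimilarity` object: list with `d` (symmetric matrix,
#'   zero diagonal, `NA` below the sharing floor) and `shared`
#'   (pairwise shared-site counts).
#' @export
pairwise_dissimilarity <- function(profiles, bulk_bin = NULL,
                                   min_shared = 50) {
  cm <- call_matrices(profiles, bulk_bin)
  ncov <- Matrix::rowSums(cm$obs)
  if (any(ncov == 0))
    stop("entities with zero covered sites: ",
         paste(head(rownames(cm$obs)[ncov == 0], 5), collapse = ", "))
  obs <- cm$obs
  m1 <- cm$meth
  m0 <- obs - m1
  shared <- as.matrix(obs %*% Matrix::t(obs))
  cross <- m1 %*% Matrix::t(m0)
  mism <- as.matrix(cross + Matrix::t(cross))
  d <- mism / shared
  d[shared < min_shared] <- NA_real_
  diag(d) <- 0
  structure(list(d = d, shared = shared, min_shared = min_shared),
            class = "dissimilarity")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities and embeds entities on
#' the top-2 eigenvectors. Pairs flagged missing (below the sharing
#' floor) are imputed with the maximum observed dissimilarity before
#' embedding. Each axis is oriented so that its largest-magnitude
#' coordinate is positive.
#'
#' @param d A `dissimilarity` object from [pairwise_dissimilarity()],
#'   or a symmetric numeric matrix.
#' @param k Number of dimensions (default 2).
#' @return An `embedding` list: `coords` (entities x k), `eig`
#'   (eigenvalues of the doubly-centered matrix), `imputed_pairs`
#'   (count of imputed entries above the diagonal).
#' @export
classical_mds <- function(d, k = 2) {
  dm <- if (inherits(d, "dissimilarity")) d$d else as.matrix(d)
  if (!isSymmetric(unname(ifelse(is.na(dm), -1, dm))))
    stop("dissimilarity matrix must be symmetric")
  n_imp <- sum(is.na(dm[upper.tri(dm)]))
  if (n_imp > 0) {
    mx <- max(dm, na.rm = TRUE)
    dm[is.na(dm)] <- mx
    diag(dm) <- 0
  }
  fit <- cmdscale(as.dist(dm), k = k, eig = TRUE)
  coords <- fit$points
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0)
      coords[, j] <- -coords[, j]
  }
  structure(list(coords = coords, eig = fit$eig, imputed_pairs = n_imp),
            class = "embedding")
}

#' Classify single cells by proximity to tumor subclasses
#'
#' Each cell is assigned to the side (EpSC-like bulks vs
#' keratinocyte-like plus healthy bulks) with the smaller mean
#' dissimilarity. Ties break toward the keratinocyte side, the
#' epidermal majority class, and are flagged; cells with no defined
#' dissimilarity to one side are flagged unclassifiable.
#'
#' @param d A `dissimilarity` object covering cells and bulk samples.
#' @param bulk_labels Named character vector over bulk sample ids with
#'   values `"EpSC-like"`, `"Keratinocyte-like"` or
#'   `"Healthy-reference"` (as from [hierarchical_stratify()]'s
#'   `labels`).
#' @return Data.frame: `cell_id`, `label` (`EpSC`/`Keratinocyte`/`NA`),
#'   `d_epsc`, `d_ker`, `margin` (unassigned minus assigned mean
#'   dissimilarity), `tie`, `unclassifiable`.
#' @export
classify_cells <- function(d, bulk_labels) {
  stopifnot(inherits(d, "dissimilarity"))
  dm <- d$d
  ids <- rownames(dm)
  epsc_bulks <- names(bulk_labels)[bulk_labels == "EpSC-like"]
  ker_bulks <- names(bulk_labels)[bulk_labels %in%
                                    c("Keratinocyte-like", "Healthy-reference")]
  if (length(epsc_bulks) == 0 || length(ker_bulks) == 0)
    stop("need at least one bulk sample per subclass")
  cells <- setdiff(ids, names(bulk_labels))
  res <- data.frame(cell_id = cells,
                    label = NA_character_, d_epsc = NA_real_,
                    d_ker = NA_real_, margin = NA_real_,
                    tie = FALSE, unclassifiable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cells)) {
    de <- mean(dm[cells[i], epsc_bulks], na.rm = TRUE)
    dk <- mean(dm[cells[i], ker_bulks], na.rm = TRUE)
    res$d_epsc[i] <- de; res$d_ker[i] <- dk
    if (is.nan(de) || is.nan(dk)) {
      res$unclassifiable[i] <- TRUE
      next
    }
    if (de == dk) {
      res$label[i] <- "Keratinocyte"
      res$tie[i] <- TRUE
      res$margin[i] <- 0
    } else if (de < dk) {
      res$label[i] <- "EpSC"; res$margin[i] <- dk - de
    } else {
      res$label[i] <- "Keratinocyte"; res$margin[i] <- de - dk
    }
  }
  res
}

#' Mean methylation per chromatin state
#'
#' Averages methylation over the CpGs falling within each chromatin
#' state's intervals, per entity. Entities may be sparse single-cell
#' profiles (binary calls) and/or columns of a beta matrix with
#' manifest positions. Missing where an entity covers no CpG in a
#' state.
#'
#' @param seg A [segmentation()] (states 1..15).
#' @param profiles Optional list of [scmeth_profile()].
#' @param beta Optional [beta_matrix()]; requires `manifest`.
#' @param manifest [probe_manifest()] giving positions of `beta` rows.
#' @return A `state_means` list: `means` (15 x entities matrix),
#'   `n_sites` (covered CpGs per state and entity).
#' @export
chromhmm_state_means <- function(seg, profiles = NULL, beta = NULL,
                                 manifest = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  seg_gr <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start + 1L, seg$end))
  ents <- character(0)
  means <- matrix(NA_real_, 15, 0)
  nsit <- matrix(0L, 15, 0)
  add_entity <- function(chrom, pos, value, id) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr, seg_gr)
    st <- seg$state[S4Vectors::subjectHits(hits)]
    v <- value[S4Vectors::queryHits(hits)]
    ok <- !is.na(v)
    mm <- rep(NA_real_, 15); nn <- integer(15)
    if (any(ok)) {
      agg <- tapply(v[ok], factor(st[ok], levels = 1:15), mean)
      mm <- as.numeric(agg)
      nn <- as.integer(table(factor(st[ok], levels = 1:15)))
    }
    means <<- cbind(means, mm)
    nsit <<- cbind(nsit, nn)
    ents <<- c(ents, id)
  }
  if (!is.null(profiles))
    for (p in profiles) add_entity(p$chrom, p$pos, p$call, p$cell_id)
  if (!is.null(beta)) {
    if (is.null(manifest)) stop("beta entities require a manifest for positions")
    idx <- match(rownames(beta$values), manifest$probe_id)
    if (anyNA(idx)) stop("beta probes missing from manifest")
    for (j in seq_len(ncol(beta$values)))
      add_entity(manifest$chrom[idx], manifest$pos[idx],
                 beta$values[, j], colnames(beta$values)[j])
  }
  dimnames(means) <- list(paste0("state", 1:15), ents)
  dimnames(nsit) <- dimnames(means)
  structure(list(means = means, n_sites = nsit), class = "state_means")
}

#' Compare enhancer-state methylation between groups
#'
#' Per entity, averages the strong-enhancer chromatin states (4 and 5
#' by default) and compares the two groups with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param sm A `state_means` object from [chromhmm_state_means()].
#' @param groups Named character/factor over entities with two levels.
#' @param states Integer states to average (default `c(4, 5)`).
#' @return List with `entity_means`, `group_means`, and `p`.
#' @export
compare_enhancer_states <- function(sm, groups, states = c(4, 5)) {
  stopifnot(inherits(sm, "state_means"))
  if (any(states < 1 | states > 15)) stop("states must lie in 1..15")
  groups <- groups[colnames(sm$means)]
  lev <- unique(as.character(groups[!is.na(groups)]))
  if (length(lev) != 2) stop("groups must have exactly two levels over entities")
  em <- colMeans(sm$means[states, , drop = FALSE], na.rm = TRUE)
  a <- em[groups == lev[1]]; b <- em[groups == lev[2]]
  a <- a[!is.nan(a)]; b <- b[!is.nan(b)]
  if (length(a) == 0 || length(b) == 0) stop("a group has no usable entities")
  list(entity_means = em,
       group_means = setNames(c(mean(a), mean(b)), lev),
       p = wilcox_p(a, b))
}

#' Site keys ("chrom:pos") for a beta matrix via its manifest
#'
#' Helper to place bulk probes into the same position space as
#' single-cell calls before [pairwise_dissimilarity()].
#'
#' @param beta A [beta_matrix()].
#' @param manifest A [probe_manifest()].
#' @return The binarized bulk matrix with `"chrom:pos"` rownames.
#' @export
bulk_binarized_sites <- function(beta, manifest) {
  idx <- match(rownames(beta$values), manifest$probe_id)
  if (anyNA(idx)) stop("beta probes missing from manifest")
  bb <- binarize(beta)
  rownames(bb) <- paste0(manifest$chrom[idx], ":", manifest$pos[idx])
  bb
}
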