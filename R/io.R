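## Readers/writers for the plain-text formats the pipeline consumes, plus
## probe-level preprocessing (beta computation, probe filtering).

#' Compute beta values from methylated/unmethylated intensities
#'
#' Beta is the methylation fraction per probe and sample,
#' `beta = M / (M + U + 100)`; the +100 offset regularises low-intensity
#' probes and bounds beta strictly below 1 for finite intensities.
#'
#' @param methylated,unmethylated Non-negative numeric matrices of equal
#'   dimension (probes x samples) with probe rownames and sample colnames.
#' @param sample_group Per-sample group passed through to the result
#'   (default `"Other"`).
#' @return A [beta_matrix()].
#' @export
beta_from_intensities <- function(methylated, unmethylated,
                                  sample_group = "Other") {
  methylated <- as.matrix(methylated)
  unmethylated <- as.matrix(unmethylated)
  if (!identical(dim(methylated), dim(unmethylated)))
    stop("methylated and unmethylated matrices must have identical dimensions")
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  beta <- methylated / (methylated + unmethylated + 100)
  dimnames(beta) <- dimnames(methylated)
  beta_matrix(beta, sample_group)
}

#' Filter array probes
#'
#' Removes probes on sex chromosomes, SNP-associated probes,
#' cross-reactive (self-hybridizing) probes, and probes flagged as
#' detection failures; probe order is preserved. The operation is
#' idempotent.
#'
#' @param beta A [beta_matrix()].
#' @param manifest A [probe_manifest()] covering all probes in `beta`.
#' @param detection_fail Optional character vector of probe ids (or named
#'   logical over probes) marking low-detected probes, precomputed
#'   upstream from detection p-values.
#' @return A [beta_matrix()] restricted to the retained probes.
#' @export
filter_probes <- function(beta, manifest, detection_fail = NULL) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(manifest, "probe_manifest"))
  ids <- rownames(beta$values)
  missing_ids <- setdiff(ids, manifest$probe_id)
  if (length(missing_ids))
    stop("probes absent from manifest: ",
         paste(head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ...")
  m <- manifest[match(ids, manifest$probe_id), ]
  drop <- m$flag_sex | m$flag_snp | m$flag_crossreactive
  if (!is.null(detection_fail)) {
    if (is.logical(detection_fail)) {
      fail_ids <- names(detection_fail)[detection_fail]
    } else {
      fail_ids <- as.character(detection_fail)
    }
    drop <- drop | ids %in% fail_ids
  }
  beta_matrix(beta$values[!drop, , drop = FALSE],
              as.character(beta$sample_group))
}

#' Read a BED file as a region set or segmentation
#'
#' BED coordinates are 0-based half-open and are kept that way
#' internally. Column 4 carries either the region class (`UK`/`DK`,
#' optionally as `region_id:class`) or an integer chromatin state.
#'
#' @param path Path to a tab-separated BED file (3+ columns, no header).
#' @param as `"regions"` or `"segmentation"`.
#' @return A [region_set()] or [segmentation()].
#' @export
read_bed <- function(path, as = c("regions", "segmentation")) {
  as <- match.arg(as)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 3) stop("BED file must have at least 3 columns: ", path)
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("malformed BED interval at line ", bad[1], " of ", path,
         " (need integer start < end)")
  if (as == "segmentation") {
    if (ncol(dt) < 4) stop("segmentation BED needs a state in column 4")
    state <- suppressWarnings(as.integer(dt[[4]]))
    if (anyNA(state))
      stop("non-integer chromatin state at line ",
           which(is.na(state))[1], " of ", path)
    return(segmentation(dt[[1]], start, end, state))
  }
  name <- if (ncol(dt) >= 4) as.character(dt[[4]]) else
    paste0("region_", seq_len(nrow(dt)))
  has_id <- grepl(":", name, fixed = TRUE)
  region_id <- ifelse(has_id, sub(":[^:]*$", "", name),
                      paste0("region_", seq_len(nrow(dt))))
  cls <- ifelse(has_id, sub("^.*:", "", name), name)
  region_set(region_id, dt[[1]], start, end, cls)
}

#' Write a region set or segmentation to BED
#'
#' Inverse of [read_bed()]: regions are written with `region_id:class`
#' in column 4, segmentations with the state. Round-trips losslessly.
#'
#' @param x A [region_set()] or [segmentation()].
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "region_set")) {
    name <- paste0(x$region_id, ":", x$region_class)
  } else if (inherits(x, "segmentation")) {
    name <- x$state
  } else stop("write_bed expects a region_set or segmentation")
  data.table::fwrite(
    data.table::data.table(x$chrom, x$start, x$end, name),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a beta matrix from TSV
#'
#' First column `probe_id`, remaining columns one per sample. Sample
#' groups come from a JSON sidecar (`{"sample": "group", ...}`) or a
#' `groups` argument.
#'
#' @param path TSV path.
#' @param groups Named character vector sample -> group, or path to a
#'   JSON sidecar. Unnamed samples default to `"Other"`.
#' @return A [beta_matrix()].
#' @export
read_beta <- function(path, groups = NULL) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  vals <- as.matrix(dt[, -1])
  rownames(vals) <- as.character(dt[[1]])
  grp <- rep("Other", ncol(vals))
  if (is.character(groups) && length(groups) == 1 && file.exists(groups))
    groups <- unlist(jsonlite::read_json(groups, simplifyVector = TRUE))
  if (!is.null(groups)) {
    hit <- match(colnames(vals), names(groups))
    grp[!is.na(hit)] <- groups[hit[!is.na(hit)]]
  }
  beta_matrix(vals, grp)
}

#' Write a beta matrix to TSV (plus optional group sidecar)
#'
#' @param beta A [beta_matrix()].
#' @param path Output TSV path.
#' @param groups_path Optional JSON sidecar path for sample groups.
#' @export
write_beta <- function(beta, path, groups_path = NULL) {
  dt <- data.table::data.table(probe_id = rownames(beta$values))
  dt <- cbind(dt, data.table::as.data.table(beta$values))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  if (!is.null(groups_path))
    jsonlite::write_json(as.list(setNames(as.character(beta$sample_group),
                                          colnames(beta$values))),
                         groups_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a probe manifest from TSV
#'
#' Expected columns: `probe_id, chrom, pos, island_relation,
#' gene_regions, gene_symbol, flag_snp, flag_crossreactive` (flags
#' optional, default FALSE). Positions may be delivered 1-based, in
#' which case `one_based = TRUE` converts them on load so that all
#' internal coordinates are 0-based.
#'
#' @param path TSV path with header.
#' @param one_based Set TRUE when the file stores 1-based positions.
#' @return A [probe_manifest()].
#' @export
read_manifest <- function(path, one_based = FALSE) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  pos <- as.integer(dt$pos) - if (one_based) 1L else 0L
  probe_manifest(
    probe_id = as.character(dt$probe_id),
    chrom = as.character(dt$chrom),
    pos = pos,
    island_relation = as.character(dt$island_relation),
    gene_regions = if ("gene_regions" %in% names(dt))
      as.character(dt$gene_regions) else "Intergenic",
    gene_symbol = if ("gene_symbol" %in% names(dt))
      as.character(dt$gene_symbol) else NA_character_,
    flag_snp = if ("flag_snp" %in% names(dt)) as.logical(dt$flag_snp) else FALSE,
    flag_crossreactive = if ("flag_crossreactive" %in% names(dt))
      as.logical(dt$flag_crossreactive) else FALSE
  )
}

#' Write a probe manifest to TSV
#' @param manifest A [probe_manifest()].
#' @param path Output path (0-based positions).
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read single-cell methylation calls with read-count QC
#'
#' Each cell is a TSV of `chrom, pos, call` (binary calls); a metadata
#' TSV (`cell_id, n_reads`) supplies total read counts. Cells below the
#' read threshold are excluded, mirroring the sequencing-depth QC used
#' for combinatorial-indexing bisulfite libraries. Coverage is expressed
#' against a supplied CpG universe.
#'
#' @param cell_paths Named character vector: cell_id -> per-cell TSV path.
#' @param meta_path TSV with columns `cell_id`, `n_reads`.
#' @param universe_size Number of CpGs in the reference universe.
#' @param min_reads Minimum sequencing reads to retain a cell
#'   (default 1e5).
#' @return List of [scmeth_profile()] for the retained cells.
#' @export
read_scmeth <- function(cell_paths, meta_path, universe_size,
                        min_reads = 1e5) {
  meta <- data.table::fread(meta_path, header = TRUE, sep = "\t")
  stopifnot(all(c("cell_id", "n_reads") %in% names(meta)))
  reads <- setNames(as.integer(meta$n_reads), as.character(meta$cell_id))
  if (is.null(names(cell_paths)))
    stop("cell_paths must be named by cell_id")
  out <- list()
  for (cid in names(cell_paths)) {
    if (!cid %in% names(reads))
      stop("no read count for cell ", cid)
    if (reads[[cid]] < min_reads) next
    dt <- data.table::fread(cell_paths[[cid]], header = TRUE, sep = "\t")
    if (nrow(dt) && !all(dt$call %in% c(0L, 1L)))
      stop("non-binary methylation call in ", cell_paths[[cid]])
    out[[cid]] <- scmeth_profile(cid, dt$chrom, dt$pos, dt$call,
                                 reads[[cid]], universe_size)
  }
  out
}

#' Write single-cell methylation profiles
#'
#' @param profiles List of [scmeth_profile()].
#' @param dir Output directory; writes one `<cell_id>.tsv` per cell and
#'   a `cells.tsv` metadata table.
#' @return Named vector of per-cell paths (invisibly).
#' @export
write_scmeth <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- data.table::data.table(
    cell_id = vapply(profiles, `[[`, "", "cell_id"),
    n_reads = vapply(profiles, `[[`, 0L, "n_reads"))
  data.table::fwrite(meta, file.path(dir, "cells.tsv"), sep = "\t")
  for (p in profiles) {
    f <- file.path(dir, paste0(p$cell_id, ".tsv"))
    data.table::fwrite(
      data.table::data.table(chrom = p$chrom, pos = p$pos, call = p$call),
      f, sep = "\t")
    paths[p$cell_id] <- f
  }
  invisible(paths)
}

#' Read a clock parameter table
#' @param path TSV with columns `cpg_id, delta, p`.
#' @return A [clock_model()].
#' @export
read_clock_model <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  clock_model(dt$cpg_id, dt$delta, dt$p)
}
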