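## Core domain containers. These are deliberately light S3 wrappers around
## data.frames and matrices: every downstream operation works on standard
## structures, and the constructors exist to enforce the invariants once,
## at the boundary.

ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
GENE_REGIONS <- c("TSS1500", "TSS200", "FirstExon", "UTR5", "Body", "Intergenic")
SAMPLE_GROUPS <- c("Healthy", "AK", "cSCC", "BD", "BCC", "SK", "Other")
SEX_CHROMS <- c("chrX", "chrY")

#' Construct a probe manifest
#'
#' The manifest is the probe universe against which all filtering and
#' region mapping acts: one row per array probe, carrying its genomic
#' CpG position (0-based), CpG-island relation, gene-region context and
#' exclusion flags.
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param chrom Chromosome name per probe (e.g. `"chr1"`).
#' @param pos Integer 0-based CpG coordinate per probe.
#' @param island_relation One of `"Island"`, `"Shore"`, `"Shelf"`,
#'   `"OpenSea"` per probe.
#' @param gene_regions Character vector per probe with one or more of
#'   `TSS1500, TSS200, FirstExon, UTR5, Body, Intergenic` separated by
#'   `";"`.
#' @param gene_symbol Optional gene symbol per probe (`NA` allowed).
#' @param flag_snp,flag_crossreactive Logical exclusion flags
#'   (SNP-associated / cross-reactive probes). The sex-chromosome flag is
#'   derived from `chrom` and cannot be set independently.
#' @return A `probe_manifest` data.frame with columns `probe_id`, `chrom`,
#'   `pos`, `island_relation`, `gene_regions`, `gene_symbol`, `flag_sex`,
#'   `flag_snp`, `flag_crossreactive`.
#' @export
probe_manifest <- function(probe_id, chrom, pos, island_relation,
                           gene_regions = "Intergenic",
                           gene_symbol = NA_character_,
                           flag_snp = FALSE, flag_crossreactive = FALSE) {
  n <- length(probe_id)
  stopifnot(is.character(probe_id), length(chrom) == n, length(pos) == n)
  if (anyDuplicated(probe_id))
    stop("probe_id values must be unique")
  if (any(pos < 0))
    stop("probe positions must be >= 0")
  if (!all(island_relation %in% ISLAND_RELATIONS))
    stop("island_relation must be one of: ", paste(ISLAND_RELATIONS, collapse = ", "))
  gr_ok <- vapply(strsplit(as.character(gene_regions), ";", fixed = TRUE),
                  function(g) all(g %in% GENE_REGIONS), logical(1))
  if (!all(gr_ok))
    stop("gene_regions entries must be ';'-separated subsets of: ",
         paste(GENE_REGIONS, collapse = ", "))
  out <- data.frame(
    probe_id = probe_id,
    chrom = as.character(chrom),
    pos = as.integer(pos),
    island_relation = factor(island_relation, levels = ISLAND_RELATIONS),
    gene_regions = rep_len(as.character(gene_regions), n),
    gene_symbol = rep_len(as.character(gene_symbol), n),
    flag_sex = as.character(chrom) %in% SEX_CHROMS,
    flag_snp = rep_len(as.logical(flag_snp), n),
    flag_crossreactive = rep_len(as.logical(flag_crossreactive), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("probe_manifest", "data.frame")
  out
}

#' Construct a labeled region set
#'
#' Accessibility-defined regulatory regions with half-open 0-based
#' coordinates. `region_class` distinguishes regions accessible only in
#' undifferentiated keratinocytes (`"UK"`) from those accessible only in
#' differentiated keratinocytes (`"DK"`). Regions of the same class must
#' not overlap.
#'
#' @param region_id Unique region identifiers.
#' @param chrom,start,end Genomic interval per region, 0-based half-open.
#' @param region_class `"UK"` or `"DK"` per region.
#' @return A `region_set` data.frame.
#' @export
region_set <- function(region_id, chrom, start, end, region_class) {
  n <- length(region_id)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  if (anyDuplicated(region_id)) stop("region_id values must be unique")
  if (any(start >= end)) stop("regions must satisfy start < end")
  if (!all(region_class %in% c("UK", "DK")))
    stop("region_class must be 'UK' or 'DK'")
  out <- data.frame(
    region_id = as.character(region_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    region_class = factor(region_class, levels = c("UK", "DK")),
    stringsAsFactors = FALSE
  )
  for (cls in levels(out$region_class)) {
    sub <- out[out$region_class == cls, , drop = FALSE]
    if (nrow(sub) > 1) {
      gr <- GenomicRanges::GRanges(sub$chrom,
                                   IRanges::IRanges(sub$start + 1L, sub$end))
      hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
      if (length(hits) > 0)
        stop("regions of class ", cls, " overlap; same-class regions must be disjoint")
    }
  }
  class(out) <- c("region_set", "data.frame")
  out
}

#' Construct a chromatin-state segmentation
#'
#' Genome segmentation into 15 chromatin states (promoters, enhancers,
#' transcription, repressed, heterochromatin, repetitive), as produced by
#' a hidden-Markov segmentation of histone-mark data.
#'
#' @param chrom,start,end Intervals, 0-based half-open.
#' @param state Integer chromatin state in 1..15 per interval.
#' @return A `segmentation` data.frame.
#' @export
segmentation <- function(chrom, start, end, state) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n, length(state) == n)
  if (any(start >= end)) stop("segments must satisfy start < end")
  state <- as.integer(state)
  if (any(state < 1L | state > 15L))
    stop("chromatin states must lie in 1..15")
  out <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end), state = state,
                    stringsAsFactors = FALSE)
  if (n > 1) {
    gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start + 1L, out$end))
    if (length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)) > 0)
      stop("segmentation intervals must be non-overlapping")
  }
  class(out) <- c("segmentation", "data.frame")
  out
}

#' Construct a beta-value matrix
#'
#' Probes-by-samples matrix of methylation fractions in `[0,1]`, with a
#' per-sample clinical group. Missing values are allowed and always mean
#' "not measured", never hypomethylation.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_group Character/factor per sample; one of
#'   `Healthy, AK, cSCC, BD, BCC, SK, Other`.
#' @return A `beta_matrix` object (list with `values` and `sample_group`).
#' @export
beta_matrix <- function(values, sample_group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry probe rownames and sample colnames")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0,1]")
  sample_group <- rep_len(as.character(sample_group), ncol(values))
  if (!all(sample_group %in% SAMPLE_GROUPS))
    stop("sample_group must be one of: ", paste(SAMPLE_GROUPS, collapse = ", "))
  structure(
    list(values = values,
         sample_group = setNames(factor(sample_group, levels = SAMPLE_GROUPS),
                                 colnames(values))),
    class = "beta_matrix"
  )
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("<beta_matrix> ", nrow(x$values), " probes x ", ncol(x$values),
      " samples\n", sep = "")
  print(table(x$sample_group))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Construct a single-cell methylation profile
#'
#' One cell's sparse binary methylation calls at genomic CpG positions,
#' as obtained from single-cell combinatorial-indexing whole-genome
#' bisulfite sequencing.
#'
#' @param cell_id Cell identifier.
#' @param chrom,pos Genomic CpG positions of the calls (0-based).
#' @param call Binary methylation call (0/1) per position.
#' @param n_reads Total sequencing reads for the cell.
#' @param universe_size Number of CpGs in the reference universe used to
#'   express coverage as a fraction.
#' @return An `scmeth_profile` object.
#' @export
scmeth_profile <- function(cell_id, chrom, pos, call, n_reads, universe_size) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(call))
  if (length(call) && !all(call %in% c(0, 1)))
    stop("methylation calls must be binary (0/1)")
  structure(
    list(cell_id = as.character(cell_id),
         chrom = as.character(chrom),
         pos = as.integer(pos),
         call = as.integer(call),
         n_reads = as.integer(n_reads),
         coverage_fraction = length(call) / universe_size),
    class = "scmeth_profile"
  )
}

#' Construct a mitotic clock model
#'
#' Per-CpG parameters of the division-tracking methylation model: the
#' ground-state methylation `delta` of each clock CpG and its
#' per-division probability `p` of gaining methylation.
#'
#' @param cpg_id Clock CpG identifiers.
#' @param delta Ground-state methylation per CpG, in `[0,1)`.
#' @param p Per-division methylation-gain probability, in `(0,1)`.
#' @return A `clock_model` data.frame.
#' @export
clock_model <- function(cpg_id, delta, p) {
  stopifnot(length(cpg_id) == length(delta), length(delta) == length(p))
  if (any(delta < 0 | delta >= 1)) stop("delta must lie in [0,1)")
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0,1)")
  out <- data.frame(cpg_id = as.character(cpg_id), delta = delta, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("clock_model", "data.frame")
  out
}

## GRanges view of probe positions (width-1 CpGs), used for interval joins.
manifest_granges <- function(manifest) {
  GenomicRanges::GRanges(manifest$chrom,
                         IRanges::IRanges(manifest$pos + 1L, width = 1L),
                         probe_id = manifest$probe_id)
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end),
                         region_id = regions$region_id,
                         region_class = regions$region_class)
}
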