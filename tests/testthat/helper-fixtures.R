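# Small hand-built fixtures shared across test files.

toy_manifest <- function() {
  probe_manifest(
    probe_id = paste0("cg", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chrX", "chr2"),
    pos = c(100L, 150L, 200L, 50L, 10L, 500L),
    island_relation = c("Island", "Shore", "OpenSea", "Island", "Shelf",
                        "OpenSea"),
    gene_regions = c("TSS200", "TSS1500", "Body", "TSS200", "Body",
                     "Intergenic"),
    flag_snp = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
}

toy_regions <- function() {
  region_set(region_id = c("uk1", "dk1"),
             chrom = c("chr1", "chr2"),
             start = c(100L, 0L), end = c(200L, 100L),
             region_class = c("UK", "DK"))
}

toy_beta <- function(values = NULL, groups = "Other") {
  if (is.null(values)) {
    values <- matrix(seq(0.1, 0.9, length.out = 12), 6, 2,
                     dimnames = list(paste0("cg", 1:6), c("s1", "s2")))
  }
  beta_matrix(values, groups)
}

# small synthetic config for fast unit tests (acceptance tests use the
# full default configuration)
small_cfg <- function(seed = 7L, ...) {
  args <- list(seed = seed, n_uk_regions = 40L, n_dk_regions = 30L,
               n_background_probes = 2000L, n_cells = 40L,
               atac_n_null_regions = 60L, atac_cells_per_cluster = 30L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

profile_from_calls <- function(id, pos, call, universe = 1000L) {
  scmeth_profile(id, rep("chr1", length(pos)), pos, call,
                 n_reads = 2e5, universe_size = universe)
}
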