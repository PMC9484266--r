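test_that("beta computation follows the offset-ratio definition", {
  M <- matrix(c(900, 0, 100), 3, 1, dimnames = list(paste0("cg", 1:3), "s1"))
  U <- matrix(c(0, 0, 100), 3, 1, dimnames = dimnames(M))
  b <- beta_from_intensities(M, U)
  expect_equal(unname(b$values[, 1]), c(0.9, 0, 100 / 300))
  expect_error(beta_from_intensities(-M, U), "non-negative")
})

test_that("beta values stay strictly below 1 for finite intensities", {
  M <- matrix(10^(0:7), 8, 1,
              dimnames = list(paste0("cg", 1:8), "s1"))
  U <- matrix(0, 8, 1, dimnames = dimnames(M))
  expect_true(all(beta_from_intensities(M, U)$values < 1))
})

test_that("probe filtering drops flagged probes, keeps order, is idempotent", {
  man <- toy_manifest()
  vals <- matrix(0.5, 6, 2, dimnames = list(man$probe_id, c("s1", "s2")))
  b <- beta_matrix(vals, "Healthy")
  f1 <- filter_probes(b, man)
  ## cg4 is SNP-flagged, cg5 sits on chrX
  expect_equal(rownames(f1$values), c("cg1", "cg2", "cg3", "cg6"))
  f2 <- filter_probes(f1, man)
  expect_identical(f1$values, f2$values)

  clean <- probe_manifest(man$probe_id, sub("chrX", "chr3", man$chrom),
                          man$pos, as.character(man$island_relation))
  expect_equal(nrow(filter_probes(b, clean)$values), 6)

  f3 <- filter_probes(b, man, detection_fail = "cg1")
  expect_false("cg1" %in% rownames(f3$values))
  expect_error(
    filter_probes(beta_matrix(matrix(0.1, 1, 1,
                                     dimnames = list("cgZZ", "s1")),
                              "Other"), man),
    "cgZZ")
})

test_that("five probes with two SNP flags retain three", {
  man <- probe_manifest(paste0("p", 1:5), rep("chr1", 5), 1:5,
                        rep("OpenSea", 5),
                        flag_snp = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  vals <- matrix(0.2, 5, 1, dimnames = list(man$probe_id, "s"))
  expect_equal(nrow(filter_probes(beta_matrix(vals, "Other"), man)$values), 3)
})

test_that("BED round-trip is lossless and malformed lines are rejected", {
  rs <- region_set(c("a", "b", "c"), c("chr1", "chr1", "chr2"),
                   c(100L, 300L, 0L), c(200L, 400L, 50L),
                   c("UK", "DK", "UK"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, f)
  back <- read_bed(f, as = "regions")
  expect_equal(as.data.frame(back), as.data.frame(rs))

  bare <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tUK", bare)
  r1 <- read_bed(bare, as = "regions")
  expect_equal(r1$start, 100L)
  expect_equal(r1$end, 200L)
  expect_equal(as.character(r1$region_class), "UK")

  badf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tUK", "chr1\t200\t100\tDK"), badf)
  expect_error(read_bed(badf), "line 2")
})

test_that("segmentation BED reads states and validates them", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\t4", "chr1\t100\t300\t13"), f)
  seg <- read_bed(f, as = "segmentation")
  expect_equal(seg$state, c(4L, 13L))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\t16", f2)
  expect_error(read_bed(f2, as = "segmentation"), "1..15")
})

test_that("beta matrix and manifest TSV round-trips preserve content", {
  b <- toy_beta(groups = c("Healthy", "cSCC"))
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".json")
  write_beta(b, f, groups_path = g)
  back <- read_beta(f, groups = g)
  expect_equal(back$values, b$values)
  expect_equal(back$sample_group, b$sample_group)

  man <- toy_manifest()
  mf <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(man, mf)
  mb <- read_manifest(mf)
  expect_equal(as.data.frame(mb), as.data.frame(man))
  ## 1-based delivery is shifted on load
  one <- data.table::fread(mf)
  one$pos <- one$pos + 1L
  mf1 <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(one, mf1, sep = "\t")
  expect_equal(read_manifest(mf1, one_based = TRUE)$pos, man$pos)
})

test_that("single-cell reader applies the read-count threshold", {
  dir <- withr::local_tempdir()
  p1 <- profile_from_calls("kept", c(10L, 20L), c(1L, 0L))
  p2 <- profile_from_calls("shallow", c(30L), c(1L))
  p2$n_reads <- 99999L
  p3 <- profile_from_calls("empty", integer(0), integer(0))
  paths <- write_scmeth(list(p1, p2, p3), dir)
  got <- read_scmeth(paths, file.path(dir, "cells.tsv"),
                     universe_size = 1000L)
  expect_setequal(names(got), c("kept", "empty"))
  expect_equal(got$empty$coverage_fraction, 0)
  expect_equal(got$kept$coverage_fraction, 2 / 1000)

  ten <- profile_from_calls("ten", as.integer(1:10), rep(1L, 10))
  paths2 <- write_scmeth(list(ten), dir)
  got2 <- read_scmeth(paths2, file.path(dir, "cells.tsv"), 1000L)
  expect_equal(got2$ten$coverage_fraction, 0.01)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("chrom\tpos\tcall", "chr1\t5\t2"), bad)
  meta_bad <- file.path(dir, "cells_bad.tsv")
  writeLines(c("cell_id\tn_reads", "bad\t200000"), meta_bad)
  expect_error(read_scmeth(c(bad = bad), meta_bad, 1000L), "non-binary")
})

test_that("domain constructors enforce their invariants", {
  expect_error(probe_manifest(c("a", "a"), c("chr1", "chr1"), c(1, 2),
                              c("Island", "Island")), "unique")
  expect_error(region_set("r1", "chr1", 200L, 100L, "UK"), "start < end")
  expect_error(region_set(c("r1", "r2"), c("chr1", "chr1"),
                          c(100L, 150L), c(200L, 250L), c("UK", "UK")),
               "overlap")
  expect_error(segmentation("chr1", 0L, 10L, 20L), "1..15")
  expect_error(beta_matrix(matrix(1.5, 1, 1,
                                  dimnames = list("p", "s")), "Other"),
               "\\[0,1\\]")
  expect_error(scmeth_profile("c", "chr1", 1L, 2L, 1e5, 10), "binary")
  ## sex-chromosome flag is derived from the chromosome
  man <- toy_manifest()
  expect_identical(man$flag_sex, man$chrom %in% c("chrX", "chrY"))
})
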