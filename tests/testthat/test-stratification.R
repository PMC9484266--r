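test_that("probe-to-region mapping honors half-open boundaries", {
  man <- probe_manifest(c("pL", "pR"), c("chr1", "chr1"), c(100L, 200L),
                        c("Island", "Island"))
  reg <- region_set("r", "chr1", 100L, 200L, "UK")
  map <- map_probes_to_regions(man, reg)
  expect_equal(map$probe_id, "pL")
  expect_equal(unname(attr(map, "class_totals")["UK"]), 1L)
})

test_that("region averaging uses non-missing probes and ignores order", {
  man <- probe_manifest(paste0("p", 1:4), rep("chr1", 4),
                        c(10L, 20L, 30L, 200L), rep("Island", 4))
  reg <- region_set("r1", "chr1", 0L, 100L, "UK")
  map <- map_probes_to_regions(man, reg)
  vals <- matrix(c(0.2, NA, 0.8, 0.9,
                   0.2, 0.4, NA, 0.9), 4, 2,
                 dimnames = list(man$probe_id, c("s1", "s2")))
  rb <- region_beta(beta_matrix(vals, "Other"), map)
  expect_equal(unname(rb$values["r1", ]), c(0.5, 0.3))
  expect_equal(unname(rb$n_probes["r1"]), 3L)

  perm <- beta_matrix(vals[c(3, 1, 4, 2), ], "Other")
  expect_equal(region_beta(perm, map)$values, rb$values)

  allna <- vals; allna[1:3, 1] <- NA
  rb2 <- region_beta(beta_matrix(allna, "Other"), map)
  expect_true(is.na(rb2$values["r1", "s1"]))
})

test_that("single-probe regions reproduce the probe value", {
  man <- probe_manifest("p1", "chr1", 10L, "Island")
  reg <- region_set("r1", "chr1", 0L, 100L, "DK")
  vals <- matrix(0.42, 1, 1, dimnames = list("p1", "s1"))
  rb <- region_beta(beta_matrix(vals, "Other"),
                    map_probes_to_regions(man, reg))
  expect_equal(unname(rb$values["r1", "s1"]), 0.42)
})

test_that("1-D toys are labeled by the healthy-majority rule", {
  mk <- function(v) as_region_beta(matrix(v, 1, 4,
    dimnames = list("r1", c("h1", "h2", "t1", "t2"))))
  sa <- hierarchical_stratify(mk(c(0, 0.1, 0.9, 1)), c("h1", "h2"))
  expect_equal(unname(sa$labels[c("t1", "t2")]),
               c("EpSC-like", "EpSC-like"))
  expect_equal(unname(sa$labels[c("h1", "h2")]),
               rep("Healthy-reference", 2))

  sa2 <- hierarchical_stratify(mk(c(0, 0.1, 0.05, 0.95)), c("h1", "h2"))
  expect_equal(unname(sa2$labels["t1"]), "Keratinocyte-like")
  expect_equal(unname(sa2$labels["t2"]), "EpSC-like")
})

test_that("an even healthy split raises the ambiguity error", {
  vals <- matrix(c(0, 0.01, 0.99, 1), 1, 4,
                 dimnames = list("r1", c("h1", "t1", "t2", "h2")))
  expect_error(hierarchical_stratify(as_region_beta(vals), c("h1", "h2")),
               "ambiguous")
})

test_that("stratification matches the exhaustive agglomerative oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    f <- sample(1:3, 1)
    X <- matrix(runif(n * f), n, f)
    ids <- sprintf("s%d", seq_len(n))
    oracle <- naive_complete_linkage_k2(X)
    pkg <- cutree(hclust(dist(X), method = "complete"), k = 2)
    expect_true(same_partition(oracle, pkg))

    n_h <- sample(c(1, 3), 1)
    if (n - n_h < 2 || n_h >= n) next
    healthy <- ids[seq_len(n_h)]
    rbv <- as_region_beta(matrix(t(X), f, n,
                                 dimnames = list(sprintf("r%d", 1:f), ids)))
    sa <- tryCatch(hierarchical_stratify(rbv, healthy),
                   error = function(e) e)
    if (inherits(sa, "error")) {
      expect_match(conditionMessage(sa), "ambiguous")
      next
    }
    ker_side <- oracle[match(healthy, ids)]
    maj <- as.integer(names(which.max(table(ker_side))))
    want <- ifelse(oracle == maj, "Keratinocyte-like", "EpSC-like")
    want[match(healthy, ids)] <- "Healthy-reference"
    expect_equal(unname(sa$labels[ids]), want)
  }
})

test_that("labels are invariant to sample and region permutations", {
  set.seed(1)
  vals <- cbind(matrix(runif(32, 0, 0.3), 8, 4),
                matrix(runif(48, 0.6, 1), 8, 6))
  dimnames(vals) <- list(sprintf("r%d", 1:8), sprintf("s%d", 1:10))
  rbv <- as_region_beta(vals)
  sa <- hierarchical_stratify(rbv, c("s1", "s2"))
  perm <- sample(ncol(vals))
  rbp <- as_region_beta(vals[sample(nrow(vals)), perm])
  sap <- hierarchical_stratify(rbp, c("s1", "s2"))
  expect_equal(sap$labels[names(sa$labels)], sa$labels)
})

test_that("external cohorts are classified against the healthy anchor", {
  cfg <- small_cfg(seed = 21)
  rm_ <- generate_regions_and_manifest(cfg)
  bk <- generate_bulk(cfg, rm_$regions, rm_$manifest)
  healthy_ids <- names(bk$truth$true_subclass)[
    bk$truth$true_subclass == "Healthy"]
  ref <- beta_matrix(bk$beta$values[, healthy_ids],
                     as.character(bk$beta$sample_group[healthy_ids]))

  cfg_m <- small_cfg(seed = 22, n_healthy = 0L, n_tumor_epsc = 11L,
                     n_tumor_ker = 0L)
  met <- generate_bulk(cfg_m, rm_$regions, rm_$manifest)
  mv <- met$beta$values
  colnames(mv) <- paste0("M", seq_len(ncol(mv)))
  newb <- beta_matrix(mv, "cSCC")

  sa <- classify_cohort(newb, ref, rm_$regions, rm_$manifest)
  expect_true(all(sa$labels[colnames(mv)] == "EpSC-like"))
  expect_true(all(sa$labels[healthy_ids] == "Healthy-reference"))

  ## insufficient probe overlap is refused
  few <- beta_matrix(mv[1:5, , drop = FALSE], "cSCC")
  expect_error(classify_cohort(few, ref, rm_$regions, rm_$manifest),
               "overlap")
})

test_that("PCA coordinates are deterministic and separate subclasses", {
  b <- toy_beta(matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6,
                         0.1, 0.2, 0.3, 0.4, 0.5, 0.6,
                         0.9, 0.8, 0.7, 0.6, 0.5, 0.4), 6, 3,
                       dimnames = list(paste0("cg", 1:6),
                                       c("a", "a2", "b"))))
  pc <- pca_overview(b)
  expect_equal(pc$coords["a", ], pc$coords["a2", ])

  two <- toy_beta(matrix(c(0.1, 0.4, 0.9, 0.2), 2, 2,
                         dimnames = list(c("p1", "p2"), c("x", "y"))))
  pc2 <- pca_overview(two)
  expect_equal(pc2$explained[1], 1)

  const <- toy_beta(matrix(0.5, 3, 3,
                           dimnames = list(paste0("p", 1:3),
                                           paste0("s", 1:3))))
  expect_error(pca_overview(const), "constant")

  cfg <- small_cfg(seed = 31)
  rm_ <- generate_regions_and_manifest(cfg)
  bk <- generate_bulk(cfg, rm_$regions, rm_$manifest)
  tum <- names(bk$truth$true_subclass)[bk$truth$true_subclass != "Healthy"]
  pc3 <- pca_overview(beta_matrix(bk$beta$values[, tum],
                                  as.character(bk$beta$sample_group[tum])))
  sil <- silhouette_mean(pc3$coords, bk$truth$true_subclass[tum])
  expect_gt(sil, 0.5)
})

test_that("identical groups give null moderated statistics", {
  vals <- matrix(runif(40), 10, 4,
                 dimnames = list(sprintf("p%d", 1:10),
                                 sprintf("s%d", 1:4)))
  vals[, 3:4] <- vals[, 1:2]
  d <- dmp_test(beta_matrix(vals, "Other"), c("A", "A", "B", "B"))
  expect_true(all(d$t == 0))
  expect_true(all(d$p == 1))
  expect_true(all(d$q >= d$p))
})

test_that("context fractions partition the probe set", {
  man <- toy_manifest()
  fr <- probe_context_fractions(c("cg1", "cg4"), man)
  expect_equal(unname(fr["Island"]), 1)
  expect_equal(sum(fr), 1)
  fr2 <- probe_context_fractions(c("cg1", "cg4", "cg3", "cg6"), man)
  expect_equal(unname(fr2[c("Island", "OpenSea")]), c(0.5, 0.5))
  expect_error(probe_context_fractions(character(0), man), "empty")

  ## generator bias: UK probes island-dominated, DK open-sea-dominated
  cfg <- small_cfg(seed = 41)
  rm_ <- generate_regions_and_manifest(cfg)
  cls <- attr(rm_$manifest, "probe_class")
  uk_fr <- probe_context_fractions(rm_$manifest$probe_id[cls == "UK"], rm_$manifest)
  dk_fr <- probe_context_fractions(rm_$manifest$probe_id[cls == "DK"], rm_$manifest)
  expect_gt(uk_fr["Island"], uk_fr["OpenSea"])
  expect_gt(dk_fr["OpenSea"], dk_fr["Island"])
})

test_that("marker promoter scores separate the planted subclasses", {
  vals <- matrix(c(0.9, 0.7, 0.1, 0.3), 2, 2,
                 dimnames = list(c("m1", "m2"), c("s1", "s2")))
  ms <- marker_region_score(beta_matrix(vals, "Other"),
                            list(mk = c("m1", "m2")),
                            groups = c(s1 = "A", s2 = "B"),
                            contrast = c("A", "B"))
  expect_equal(unname(ms$mk$scores["s1"]), 0.8)

  same <- marker_region_score(beta_matrix(vals, "Other"),
                              list(mk = c("m1", "m2")),
                              groups = c(s1 = "A", s2 = "A2"),
                              contrast = c("A", "A2"))
  expect_equal(same$mk$p, 1)  # exact rank-sum with one sample per side
  expect_error(marker_region_score(beta_matrix(vals, "Other"),
                                   list(bad = "zz"),
                                   groups = c(s1 = "A", s2 = "B")),
               "bad")

  cfg <- small_cfg(seed = 51)
  rm_ <- generate_regions_and_manifest(cfg)
  bk <- generate_bulk(cfg, rm_$regions, rm_$manifest)
  grp <- bk$truth$true_subclass
  ms2 <- marker_region_score(bk$beta, rm_$truth$marker_probes, grp,
                             contrast = c("EpSC-like", "Healthy"))
  for (mk in names(ms2)) {
    expect_gt(ms2[[mk]]$group_means["EpSC-like"],
              ms2[[mk]]$group_means["Healthy"])
    expect_lt(ms2[[mk]]$p, 0.01)
  }
})

test_that("moderated statistics agree with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(43)
  mu <- runif(300, 0.2, 0.8)
  phi <- runif(300, 5, 80)
  vals <- sapply(1:10, function(j) rbeta(300, mu * phi, (1 - mu) * phi))
  dimnames(vals) <- list(sprintf("p%d", 1:300), sprintf("s%d", 1:10))
  groups <- rep(c("A", "B"), each = 5)
  d <- dmp_test(beta_matrix(vals, "Other"), groups)
  design <- stats::model.matrix(~ factor(groups, c("B", "A")))
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(attr(d, "d0"), fit$df.prior, tolerance = 1e-10)
  expect_equal(attr(d, "s0")^2, fit$s2.prior, tolerance = 1e-10)
  expect_lt(max(abs(d$t - fit$t[, 2])), 1e-12)
  expect_lt(max(abs(d$p - fit$p.value[, 2])), 1e-12)
})
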