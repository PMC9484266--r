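test_that("binarization thresholds at 0.5 inclusively and is idempotent", {
  x <- matrix(c(0.5, 0.49, 0, 1, NA, 0.51), 3, 2,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  bz <- binarize(x)
  expect_equal(unname(bz[, 1]), c(1L, 0L, 0L))
  expect_equal(unname(bz[, 2]), c(1L, NA, 1L))
  expect_identical(binarize(bz), bz)
  expect_error(binarize(x * 3), "\\[0,1\\]")
})

test_that("mismatch dissimilarity matches hand enumeration", {
  a <- profile_from_calls("a", c(1L, 2L, 3L), c(1L, 1L, 0L))
  b <- profile_from_calls("b", c(1L, 2L, 3L, 4L), c(1L, 0L, 0L, 1L))
  d <- pairwise_dissimilarity(list(a, b), min_shared = 1)
  expect_equal(d$d["a", "b"], 1 / 3)
  expect_equal(d$shared["a", "b"], 3)
  expect_equal(diag(d$d), c(a = 0, b = 0))

  same <- pairwise_dissimilarity(list(a, profile_from_calls("a2", c(1L, 2L, 3L), c(1L, 1L, 0L))),
                                 min_shared = 1)
  expect_equal(same$d["a", "a2"], 0)

  comp <- pairwise_dissimilarity(
    list(profile_from_calls("x", 1:10, rep(1L, 10)),
         profile_from_calls("y", 1:10, rep(0L, 10))), min_shared = 1)
  expect_equal(comp$d["x", "y"], 1)

  ## sharing floor flags sparse pairs as missing
  far <- pairwise_dissimilarity(list(a, profile_from_calls("z", 50:60, rep(1L, 11))),
                                min_shared = 5)
  expect_true(is.na(far$d["a", "z"]))
  expect_error(pairwise_dissimilarity(
    list(a, profile_from_calls("e", integer(0), integer(0)))),
    "zero covered")
})

test_that("dissimilarity is a pseudo-metric on full-coverage profiles", {
  set.seed(5)
  pos <- 1:200
  profs <- lapply(1:6, function(i)
    profile_from_calls(paste0("c", i), pos, rbinom(200, 1, 0.5)))
  d <- pairwise_dissimilarity(profs, min_shared = 1)$d
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("classical MDS reproduces closed-form configurations", {
  ## equilateral triangle with unit sides
  dm <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(dm) <- 0
  em <- classical_mds(dm)
  expect_equal(as.numeric(dist(em$coords)), rep(1, 3), tolerance = 1e-8)
  expect_equal(colMeans(em$coords), c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)

  ## collinear points embed exactly on one axis
  x <- c(0, 1, 3, 7)
  dm2 <- as.matrix(dist(x))
  em2 <- classical_mds(dm2)
  expect_lt(abs(em2$eig[2]), 1e-8)
  expect_lt(procrustes_rmse(cbind(x), em2$coords[, 1, drop = FALSE]), 1e-8)

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("planted 2-D configurations are recovered up to rigid motion", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  em <- classical_mds(as.matrix(dist(X)))
  expect_lt(procrustes_rmse(X, em$coords), 1e-8)
  ## duplicated entity lands on coincident coordinates
  X2 <- rbind(X, X[1, ])
  em2 <- classical_mds(as.matrix(dist(X2)))
  expect_equal(em2$coords[21, ], em2$coords[1, ], tolerance = 1e-8)
})

test_that("cells are assigned to the nearer subclass with declared ties", {
  bulk <- matrix(c(1, 1, 1, 0, 0, 0,
                   0, 0, 0, 1, 1, 1), 6, 2,
                 dimnames = list(paste0("chr1:", 1:6), c("E1", "K1")))
  cell_e <- profile_from_calls("ce", 1:6, c(1L, 1L, 1L, 0L, 0L, 0L))
  cell_tie <- profile_from_calls("ct", 1:6, rep(0L, 6))  # 3 mismatches to each side
  d <- pairwise_dissimilarity(list(cell_e, cell_tie), bulk, min_shared = 1)
  labs <- c(E1 = "EpSC-like", K1 = "Keratinocyte-like")
  res <- classify_cells(d, labs)
  expect_equal(res$label[res$cell_id == "ce"], "EpSC")
  expect_equal(res$margin[res$cell_id == "ce"], 1)
  tie_row <- res[res$cell_id == "ct", ]
  expect_equal(tie_row$label, "Keratinocyte")
  expect_true(tie_row$tie)
  expect_error(classify_cells(d, c(E1 = "EpSC-like")), "per subclass")
})

test_that("state means average CpGs within chromatin states", {
  seg <- segmentation(rep("chr1", 3), c(0L, 100L, 200L),
                      c(100L, 200L, 300L), c(4L, 7L, 5L))
  p <- profile_from_calls("c1", c(10L, 20L, 30L, 210L), c(1L, 0L, 1L, 1L))
  sm <- chromhmm_state_means(seg, profiles = list(p))
  expect_equal(sm$means["state4", "c1"], 2 / 3)
  expect_true(is.na(sm$means["state7", "c1"]))
  expect_equal(sm$means["state5", "c1"], 1)

  man <- probe_manifest(c("pA", "pB"), c("chr1", "chr1"), c(10L, 50L),
                        c("Island", "OpenSea"))
  bv <- matrix(c(0.2, 0.6), 2, 1, dimnames = list(c("pA", "pB"), "s1"))
  smb <- chromhmm_state_means(seg, beta = beta_matrix(bv, "Other"),
                              manifest = man)
  expect_equal(smb$means["state4", "s1"], 0.4)

  ## splitting a state interval changes nothing
  seg2 <- segmentation(rep("chr1", 4), c(0L, 50L, 100L, 200L),
                       c(50L, 100L, 200L, 300L), c(4L, 4L, 7L, 5L))
  sm2 <- chromhmm_state_means(seg2, profiles = list(p))
  expect_equal(sm2$means, sm$means)
})

test_that("enhancer-state comparison detects the planted direction", {
  seg <- segmentation(rep("chr1", 2), c(0L, 100L), c(100L, 200L),
                      c(4L, 5L))
  mk <- function(id, call) profile_from_calls(id, c(10L, 150L), call)
  profs <- c(lapply(1:4, function(i) mk(paste0("k", i), c(0L, 0L))),
             lapply(1:4, function(i) mk(paste0("e", i), c(1L, 1L))))
  sm <- chromhmm_state_means(seg, profiles = profs)
  grp <- setNames(rep(c("Keratinocyte", "EpSC"), each = 4),
                  vapply(profs, `[[`, "", "cell_id"))
  cmp <- compare_enhancer_states(sm, grp)
  expect_lt(cmp$group_means["Keratinocyte"], cmp$group_means["EpSC"])
  expect_lt(cmp$p, 0.05)

  ident <- compare_enhancer_states(sm, setNames(rep(c("a", "b"), 4),
                                                names(grp)))
  expect_equal(ident$p, 1)

  two <- chromhmm_state_means(seg, profiles = list(mk("x", c(1L, 0L)),
                                                   mk("y", c(0L, 1L))))
  cmp2 <- compare_enhancer_states(two, c(x = "g1", y = "g2"))
  expect_equal(cmp2$p, 1)
})
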