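test_that("TIME scoring returns one column per signature", {
  sigs <- simulateSignatures(4, 10, 200)
  m <- randomExprMatrix(200, 10, seed = 2)
  rownames(m) <- sprintf("G%05d", 1:200)
  tm <- suppressMessages(estimateTIME(m, sigs, nPerm = 150, seed = 3))
  expect_equal(dim(tm), c(10L, 4L))
  expect_identical(colnames(tm), names(sigs))
  # duplicated samples give duplicated rows
  m2 <- cbind(m, dup = m[, 1]); colnames(m2)[11] <- "dup"
  tm2 <- suppressMessages(estimateTIME(m2, sigs, nPerm = 150, seed = 3))
  expect_equal(tm2["dup", ], tm2[colnames(m)[1], ])
  bad <- c(sigs, list(Missing = GeneSignature("Missing", c("NOPE1", "NOPE2"))))
  expect_error(suppressMessages(estimateTIME(m, bad, nPerm = 150, seed = 3)),
               "Missing")
})

test_that("cell-type filtering applies named and abundance rules", {
  fr <- matrix(c(0.5, 0.6, 0.3, 0.2, 0.005, 0.004, 0.1, 0.1), 2, 4,
               dimnames = list(c("s1", "s2"),
                               c("CD8T", "NK", "Rare", "Osteoclast")))
  out <- filterCellTypes(fr, excludeNames = "Osteoclast",
                         minMeanFraction = 0.01)
  expect_identical(colnames(out), c("CD8T", "NK"))
  exc <- attr(out, "excluded")
  expect_setequal(exc$cell_type, c("Osteoclast", "Rare"))

  # abundance filter refuses score-scale input
  z <- matrix(rnorm(8), 2, 4, dimnames = dimnames(fr))
  expect_error(filterCellTypes(z, minMeanFraction = 0.01), "fraction-scale")
  # named exclusion alone works on any scale
  out2 <- filterCellTypes(z, excludeNames = "Osteoclast")
  expect_equal(ncol(out2), 3L)
  expect_error(filterCellTypes(fr[, 1, drop = FALSE],
                               excludeNames = "CD8T"), "all cell types")
})

test_that("z-normalization gives exact mean 0 / sample sd 1 and is idempotent", {
  m <- matrix(c(1, 2, 3, 5, 5, 8), 3, 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  z <- zNormalize(m)
  expect_equal(z[, "a"], c(s1 = -1, s2 = 0, s3 = 1))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  expect_equal(zNormalize(z), z, tolerance = 1e-12)
  m[, 2] <- 7
  expect_error(zNormalize(m), "b")
})

test_that("Ward clustering is deterministic, size-labelled and exact at k = n", {
  set.seed(44)
  m <- matrix(rnorm(40), 8, 5)
  rownames(m) <- paste0("s", 1:8)
  c1 <- clusterTIME(m, k = 3)
  expect_identical(c1, clusterTIME(m, k = 3))
  expect_equal(nlevels(c1), 3L)
  # labels ordered by decreasing size
  sz <- table(c1)
  expect_true(all(diff(as.vector(sz)) <= 0))
  # duplicated sample lands in the same cluster
  m2 <- rbind(m, dup = m[1, ]); rownames(m2)[9] <- "dup"
  c2 <- clusterTIME(m2, k = 3)
  expect_equal(c2[["dup"]], c2[["s1"]])
  expect_equal(nlevels(clusterTIME(m, k = 8)), 8L)
  expect_error(clusterTIME(m, k = 9), "fewer samples")
})

test_that("planted immune clusters are recovered through the full pipeline", {
  skip_if_not_installed("mclust")
  set.seed(50)
  lam <- runif(150)
  truth <- new("SimTruth", lambda = setNames(lam, sprintf("S%04d", 1:150)),
               params = list(), seed = 50L)
  sigs <- simulateSignatures(8, 25, 1000)
  w <- simulateWBM(truth, sigs, kPlanted = 4, nGenes = 1000, seed = 51)
  tm <- suppressMessages(estimateTIME(w$wbm, sigs, nPerm = 150, seed = 5))
  cl <- clusterTIME(zNormalize(tm), k = 4)
  expect_gt(mclust::adjustedRandIndex(cl, w$clusters), 0.8)
})

test_that("cluster associations report summaries, tests and misalignment", {
  set.seed(61)
  pbm <- setNames(c(rnorm(20, 0), rnorm(20, 2)), paste0("s", 1:40))
  clusters <- setNames(factor(rep(c("C1", "C2"), each = 20)), names(pbm))
  clin <- data.frame(sample_id = names(pbm),
                     os_time = rexp(40, 0.05), os_event = rbinom(40, 1, 0.8))
  ctm <- matrix(rnorm(80), 40, 2,
                dimnames = list(names(pbm), c("CD8T", "NK")))
  r <- clusterAssociations(clusters, pbm, clin, ctm)
  expect_equal(r$cluster_summary$cluster[which.max(r$cluster_summary$mean_pbm)],
               "C2")
  expect_lt(r$vs_top_cluster$p_value[1], 0.01)
  expect_s3_class(r$celltype_vs_pbm, "data.frame")
  expect_false(is.null(r$logrank))
  expect_error(clusterAssociations(clusters, pbm[-1], clin),
               "misaligned")
  # a singleton cluster is noted, not fatal
  cl2 <- clusters; cl2[1] <- "C2"; cl2[-1] <- "C1"
  r2 <- clusterAssociations(droplevels(cl2), pbm)
  expect_true(length(r2$notes) > 0)
})
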