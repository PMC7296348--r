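test_that("PCA reconstructs the centered matrix and orders variance", {
  set.seed(41)
  m <- matrix(rnorm(10 * 6, mean = 8), 10, 6,
              dimnames = list(paste0("S", 1:10), paste0("g", 1:6)))
  pca <- run_pca(expr_from_matrix(m))
  scores <- as.matrix(pca$scores[-1])
  load <- as.matrix(pca$loadings[-1])
  recon <- scores %*% t(load) + rep(pca$center, each = 10)
  expect_equal(unname(recon), unname(m), tolerance = 1e-10)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  # orthonormal loadings
  expect_equal(unname(t(load) %*% load), diag(ncol(load)), tolerance = 1e-10)
  # sign convention: largest-magnitude loading positive in each component
  for (j in seq_len(ncol(load))) {
    expect_gt(load[which.max(abs(load[, j])), j], 0)
  }
})

test_that("two perfectly anticorrelated genes put all variance on PC1", {
  x <- c(1, 3, 2, 5, 4)
  m <- cbind(g1 = x, g2 = 10 - x)
  pca <- run_pca(expr_from_matrix(m))
  expect_equal(pca$variance_explained[1], 1)
})

test_that("PCA scores are invariant to adding a constant to one gene", {
  set.seed(42)
  m <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("g", 1:5)))
  p1 <- run_pca(expr_from_matrix(m))
  m2 <- m
  m2[, 3] <- m2[, 3] + 7
  p2 <- run_pca(expr_from_matrix(m2))
  expect_equal(as.matrix(p1$scores[-1]), as.matrix(p2$scores[-1]),
               tolerance = 1e-10)
})

test_that("PCA input contracts hold", {
  m <- matrix(5, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(run_pca(expr_from_matrix(m)), "constant")
  expect_error(run_pca(expr_from_matrix(matrix(rnorm(4), 2, 2,
                                               dimnames = list(NULL, c("a", "b"))))),
               "at least 3 samples")
  expect_error(run_pca(expr_from_matrix(matrix(rnorm(12), 4, 3,
                                               dimnames = list(NULL, c("a", "b", "c"))),
                                        scale = "linear")),
               "log2")
})

test_that("top contributors use per-component Z-scored loadings", {
  # 10 genes at loading 0, one at 5: brute-force z of the high gene ~ 3.015
  l <- c(rep(0, 10), 5)
  z_oracle <- (l - mean(l)) / sd(l)
  fake <- structure(list(
    loadings = tibble::tibble(gene = paste0("g", 1:11), PC1 = l),
    loading_z = tibble::tibble(gene = paste0("g", 1:11), PC1 = z_oracle)
  ), class = "cortex_pca")
  out <- top_contributors(fake, 1, z_threshold = 2)
  expect_equal(out$gene, "g11")
  expect_equal(out$z, z_oracle[11], tolerance = 1e-12)
  expect_gt(out$z, 2.9)

  # all-equal loadings: every z is zero, nothing passes
  fake0 <- structure(list(
    loadings = tibble::tibble(gene = paste0("g", 1:5), PC1 = rep(0.3, 5)),
    loading_z = tibble::tibble(gene = paste0("g", 1:5), PC1 = rep(0, 5))
  ), class = "cortex_pca")
  expect_equal(nrow(top_contributors(fake0, 1)), 0)
  # degenerate threshold 0 returns everything with nonzero z
  expect_equal(nrow(top_contributors(fake, 1, z_threshold = 0)), 11)
})

test_that("run_pca Z-scores equal mean/sd brute force per component", {
  set.seed(43)
  m <- matrix(rnorm(12 * 7), 12, 7, dimnames = list(NULL, paste0("g", 1:7)))
  pca <- run_pca(expr_from_matrix(m))
  l <- pca$loadings$PC2
  expect_equal(pca$loading_z$PC2, (l - mean(l)) / sd(l), tolerance = 1e-12)
})

test_that("hierarchical clustering matches an O(n^3) brute-force linkage oracle", {
  set.seed(44)
  m <- matrix(rnorm(6 * 8), 6, 8,
              dimnames = list(paste0("S", 1:6), paste0("g", 1:8)))
  cl <- hier_cluster(expr_from_matrix(m), k_values = 2:3)
  d <- 1 - cor(t(m))
  expect_equal(sort(cl$tree$height),
               brute_complete_linkage_heights(stats::as.dist(d)),
               tolerance = 1e-12)
})

test_that("well-separated simulated groups are recovered at k = 2", {
  set.seed(45)
  g1 <- matrix(rnorm(5 * 12, mean = rep(c(3, 9), each = 6)), 5, 12, byrow = TRUE)
  g2 <- matrix(rnorm(5 * 12, mean = rep(c(9, 3), each = 6)), 5, 12, byrow = TRUE)
  m <- rbind(g1, g2)
  dimnames(m) <- list(paste0("S", 1:10), paste0("g", 1:12))
  cl <- hier_cluster(expr_from_matrix(m), k_values = 2)
  expect_identical(partition_sets(cl$labels$k2, cl$labels$sample_id),
                   partition_sets(rep(1:2, each = 5), paste0("S", 1:10)))
})

test_that("duplicate samples sit at distance zero and merge first", {
  set.seed(46)
  m <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("S", 1:4), paste0("g", 1:6)))
  m <- rbind(m, S5 = m[2, ])
  cl <- hier_cluster(expr_from_matrix(m), k_values = 4)
  expect_equal(min(cl$tree$height), 0, tolerance = 1e-12)
  expect_equal(cl$labels$k4[cl$labels$sample_id == "S2"],
               cl$labels$k4[cl$labels$sample_id == "S5"])
})

test_that("cluster labels are invariant to sample order and labeled by size", {
  set.seed(47)
  m <- matrix(rnorm(9 * 10), 9, 10,
              dimnames = list(paste0("S", 1:9), paste0("g", 1:10)))
  m[1:6, 1:5] <- m[1:6, 1:5] + 4   # a 6-sample cluster and a 3-sample cluster
  cl <- hier_cluster(expr_from_matrix(m), k_values = 2)
  perm <- sample(nrow(m))
  cl2 <- hier_cluster(expr_from_matrix(m[perm, ]), k_values = 2)
  lab1 <- setNames(cl$labels$k2, cl$labels$sample_id)
  lab2 <- setNames(cl2$labels$k2, cl2$labels$sample_id)
  expect_identical(lab1[paste0("S", 1:9)], lab2[paste0("S", 1:9)])
  # largest cluster gets label 1
  expect_equal(unname(lab1["S1"]), 1)
})

test_that("correlation distance is invariant to per-sample affine transforms", {
  set.seed(48)
  m <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("S", 1:5), paste0("g", 1:12)))
  cl <- hier_cluster(expr_from_matrix(m), k_values = 2)
  m2 <- m
  m2[2, ] <- 3 * m2[2, ] + 10
  m2[4, ] <- 0.2 * m2[4, ] - 1
  cl2 <- hier_cluster(expr_from_matrix(m2), k_values = 2)
  expect_equal(cl$tree$height, cl2$tree$height, tolerance = 1e-10)
  expect_identical(cl$labels$k2, cl2$labels$k2)
})

test_that("zero-variance samples are rejected by name", {
  m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("S", 1:3), paste0("g", 1:4)))
  m[2, ] <- 7
  expect_error(hier_cluster(expr_from_matrix(m), k_values = 2), "S2")
})

test_that("early/late marker correlation recovers identities and respects thresholds", {
  set.seed(49)
  me <- matrix(rnorm(12 * 6, 8), 12, 6,
               dimnames = list(paste0("E", 1:12), paste0("g", 1:6)))
  ml <- cbind(M1 = me[, 2], M2 = rnorm(12, 8))
  rownames(ml) <- paste0("L", 1:12)
  pairs <- tibble::tibble(early = rownames(me), late = rownames(ml))
  tab <- correlate_early_late(expr_from_matrix(me), expr_from_matrix(ml),
                              pairs, late_markers = c("M1", "M2"))
  # a late marker equal to an early gene correlates perfectly
  expect_equal(tab$r[tab$early_gene == "g2" & tab$marker == "M1"], 1,
               tolerance = 1e-12)
  filt <- correlate_early_late(expr_from_matrix(me), expr_from_matrix(ml),
                               pairs, late_markers = c("M1", "M2"),
                               r_threshold = 0.75)
  expect_true("g2" %in% filt$early_gene)
  expect_error(correlate_early_late(expr_from_matrix(me), expr_from_matrix(ml),
                                    pairs[1:2, ], c("M1")),
               "at least 3")
})

test_that("under independence, |r| > 0.75 at 44 pairs is as rare as its null predicts", {
  hits <- 0
  cells <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    me <- matrix(rnorm(44 * 20), 44, 20,
                 dimnames = list(paste0("E", 1:44), paste0("g", 1:20)))
    ml <- matrix(rnorm(44 * 3), 44, 3,
                 dimnames = list(paste0("L", 1:44), paste0("m", 1:3)))
    tab <- correlate_early_late(expr_from_matrix(me), expr_from_matrix(ml),
                                tibble::tibble(early = rownames(me),
                                               late = rownames(ml)),
                                late_markers = colnames(ml))
    hits <- hits + sum(abs(tab$r) > 0.75)
    cells <- cells + nrow(tab)
  }
  # null exceedance probability at n = 44 is ~1e-8 per cell
  expect_equal(hits, 0)
  expect_equal(cells, 5 * 60)
})

test_that("correlation of correlations is 1 for identical matrices and ~0 after shuffling", {
  set.seed(50)
  base <- matrix(rnorm(30 * 12), 30, 12)
  # correlated gene modules
  base[, 1:6] <- base[, 1:6] + rnorm(30)
  base[, 7:12] <- base[, 7:12] + rnorm(30)
  colnames(base) <- paste0("g", 1:12)
  rownames(base) <- paste0("E", 1:30)
  late <- base
  rownames(late) <- paste0("L", 1:30)
  pairs <- tibble::tibble(early = rownames(base), late = rownames(late))
  res <- correlation_of_correlations(expr_from_matrix(base),
                                     expr_from_matrix(late), pairs)
  expect_equal(res$r, 1, tolerance = 1e-10)
  # shuffling the late samples destroys the cross-time correlation
  shuffled <- late[sample(nrow(late)), ]
  rownames(shuffled) <- paste0("L", 1:30)
  res2 <- correlation_of_correlations(expr_from_matrix(base),
                                      expr_from_matrix(shuffled), pairs)
  expect_lt(abs(res2$r), 0.25)
})

test_that("module persistence strengthens the correlation of correlations", {
  set.seed(51)
  n <- 40
  rs <- sapply(c(0.1, 0.6, 0.95), function(persist) {
    module <- matrix(rnorm(n * 2), n, 2)
    me <- cbind(module[, rep(1:2, each = 5)] + matrix(rnorm(n * 10), n, 10))
    ml <- persist * me + (1 - persist) * matrix(rnorm(n * 10, sd = 2), n, 10)
    colnames(me) <- colnames(ml) <- paste0("g", 1:10)
    rownames(me) <- paste0("E", 1:n)
    rownames(ml) <- paste0("L", 1:n)
    correlation_of_correlations(
      expr_from_matrix(me), expr_from_matrix(ml),
      tibble::tibble(early = rownames(me), late = rownames(ml)))$r
  })
  expect_true(all(diff(rs) > 0))
})
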