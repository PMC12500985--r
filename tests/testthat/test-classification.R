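test_that("complete-linkage merges equal the brute-force oracle", {
  # hand-checkable 4-point configuration on a line
  X <- matrix(c(0, 1, 10, 12), ncol = 1)
  cg <- cluster_genotypes(X, k = 2)
  oracle <- brute_force_complete_linkage(X)
  got <- hclust_merges(cg$hclust)
  for (k in seq_along(oracle)) {
    expect_equal(got[[k]]$members, oracle[[k]]$members)
    expect_equal(got[[k]]$height, oracle[[k]]$height, tolerance = 1e-12)
  }
  # random configurations up to G = 6, several dimensions
  set.seed(31)
  for (i in 1:10) {
    G <- sample(3:6, 1)
    Y <- matrix(rnorm(G * 2), G, 2)
    got <- hclust_merges(cluster_genotypes(Y, k = 2)$hclust)
    oracle <- brute_force_complete_linkage(Y)
    for (k in seq_along(oracle)) {
      expect_equal(got[[k]]$members, oracle[[k]]$members)
      expect_equal(got[[k]]$height, oracle[[k]]$height, tolerance = 1e-10)
    }
  }
})

test_that("rescaled dendrogram heights span 0 to 25", {
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  cg <- cluster_genotypes(X, k = 3)
  expect_equal(max(cg$height_rescaled), 25)
  expect_equal(min(cg$height_rescaled), 0)
  # raw complete-linkage heights are monotone non-decreasing
  expect_true(all(diff(cg$height_raw) >= 0))
  # two-genotype edge case
  expect_equal(cluster_genotypes(X[1:2, ], k = 2)$height_rescaled, 25)
})

test_that("well-separated planted blobs are recovered at k = 2", {
  set.seed(14)
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 8, 0.1), 5, 2))
  rownames(X) <- paste0("g", 1:10)
  cg <- cluster_genotypes(X, k = 2)
  expect_equal(adjusted_rand_index(cg$labels, rep(1:2, each = 5)), 1)
  # labels partition the genotype set into k groups
  expect_equal(length(unique(cg$labels)), 2)
  expect_equal(names(cg$labels), rownames(X))
})

test_that("clustering is invariant to row order and rigid rotation", {
  set.seed(9)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("g", 1:8), NULL))
  cg <- cluster_genotypes(X, k = 3)
  perm <- sample(8)
  cgp <- cluster_genotypes(X[perm, ], k = 3)
  expect_equal(adjusted_rand_index(cgp$labels[rownames(X)], cg$labels), 1)
  expect_equal(sort(cgp$height_raw), sort(cg$height_raw), tolerance = 1e-12)
  # rotations preserve Euclidean distances hence the grouping
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cgr <- cluster_genotypes(X %*% R, k = 3)
  expect_equal(adjusted_rand_index(cgr$labels, cg$labels), 1)
})

test_that("cutting at a rescaled height matches the equivalent k", {
  set.seed(4)
  X <- matrix(rnorm(24), 12, 2)
  cg <- cluster_genotypes(X, k = 3)
  # choose a threshold between the 3rd- and 2nd-last rescaled merges
  hr <- sort(cg$height_rescaled, decreasing = TRUE)
  cut_at <- mean(hr[2:3])
  cgh <- cluster_genotypes(X, h_rescaled = cut_at)
  expect_equal(cgh$k, 3)
  expect_equal(adjusted_rand_index(cgh$labels, cg$labels), 1)
  expect_error(cluster_genotypes(X, h_rescaled = 30), "parameter error")
  expect_error(cluster_genotypes(X, k = 0), "parameter error")
  expect_error(cluster_genotypes(X, k = 13), "parameter error")
})

test_that("newick export round-trips through ape with correct leaves", {
  set.seed(2)
  X <- matrix(rnorm(50), 25, 2, dimnames = list(paste0("S", 1:25), NULL))
  cg <- cluster_genotypes(X, k = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cg, path)
  phy <- ape::read.tree(path)
  expect_equal(sort(phy$tip.label), sort(paste0("S", 1:25)))
  expect_equal(phy$Nnode, 24)
})

test_that("heatmap matrix standardizes index rows and orders both axes", {
  set.seed(6)
  X <- matrix(rnorm(40, 50, 10), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("ix", 1:5)))
  hm <- heatmap_matrix(X)
  expect_equal(dim(hm$matrix), c(5, 8))  # index rows x genotype columns
  expect_equal(unname(rowMeans(hm$matrix)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(hm$matrix, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(sort(hm$col_order), sort(rownames(X)))
  expect_equal(sort(hm$row_order), sort(colnames(X)))
  # constant index row becomes zeros with a warning
  Xc <- X; Xc[, 2] <- 7
  expect_warning(hmc <- heatmap_matrix(Xc), "constant")
  expect_equal(unname(hmc$matrix["ix2", ]), rep(0, 8))
})

test_that("adjusted Rand index behaves as a chance-corrected agreement", {
  a <- rep(1:3, each = 5)
  expect_equal(adjusted_rand_index(a, a), 1)
  # label permutation does not matter
  expect_equal(adjusted_rand_index(a, c("z", "x", "y")[a]), 1)
  expect_lt(abs(adjusted_rand_index(a, rep(1:5, 3))), 0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})
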