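# builds a block dissimilarity: planted modules tight, everything else loose
planted_dissim <- function(sizes, n_background = 0, within = 0.15,
                           between = 0.9, noise = 0.03, seed = 1) {
  set.seed(seed)
  n <- sum(sizes) + n_background
  lab <- rep(c(seq_along(sizes), 0L), times = c(sizes, n_background))
  d <- matrix(between, n, n)
  for (m in seq_along(sizes)) {
    idx <- which(lab == m)
    d[idx, idx] <- within
  }
  d <- d + matrix(stats::runif(n * n, -noise, noise), n, n)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  d <- pmin(pmax(d, 0), 1)
  dimnames(d) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  list(d = d, labels = stats::setNames(lab, rownames(d)))
}

test_that("dissimilarity is the complement of the network weight", {
  w <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  d <- dissimilarity(w)
  expect_equal(d[1, 2], 0.7, tolerance = 1e-15)
  expect_identical(diag(d), c(0, 0))
  set.seed(31)
  w2 <- random_adjacency(6)
  d2 <- dissimilarity(w2)
  off <- row(d2) != col(d2)
  expect_equal(d2[off] + w2[off], rep(1, sum(off)), tolerance = 1e-15)
  expect_error(dissimilarity(w2 * 2), "0, 1")
})

test_that("average linkage reproduces hand-computed UPGMA merges", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                    c("A", "B", "C")))
  hc <- average_linkage(d)
  expect_equal(hc$height, c(0.1, 0.9), tolerance = 1e-12)
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))   # A and B merge first

  d2 <- matrix(c(0, 0.42, 0.42, 0), 2, 2, dimnames = list(c("x", "y"),
                                                          c("x", "y")))
  hc2 <- average_linkage(d2)
  expect_equal(hc2$height, 0.42, tolerance = 1e-12)
  expect_error(average_linkage(matrix(0, 1, 1)), "at least 2")
})

test_that("block-diagonal structure merges within blocks before across", {
  pd <- planted_dissim(c(10, 10), noise = 0.01, seed = 32)
  hc <- average_linkage(pd$d)
  expect_gt(hc$height[19], max(hc$height[1:18]))   # last merge joins blocks
})

test_that("well-separated planted blocks are fully recovered", {
  pd <- planted_dissim(c(50, 50), noise = 0.02, seed = 33)
  hc <- average_linkage(pd$d)
  asg <- dynamic_tree_cut(hc, pd$d, min_module_size = 30L)
  expect_identical(asg$n_modules, 2L)
  expect_identical(asg$n_unassigned, 0L)
  # partition identical to the planted one
  expect_identical(unname(asg$labels[pd$labels == 1]),
                   rep(asg$labels[[1]], 50))
  expect_true(all(table(asg$labels, pd$labels) %in% c(0, 50)))
})

test_that("blocks below min_module_size stay unassigned", {
  pd <- planted_dissim(c(40, 10), n_background = 0, noise = 0.02, seed = 34)
  asg <- dynamic_tree_cut(average_linkage(pd$d), pd$d, min_module_size = 30L)
  small <- names(pd$labels)[pd$labels == 2]
  expect_true(all(asg$labels[small] == 0L))
  expect_identical(asg$n_modules, 1L)
})

test_that("module size, conservation and label-ordering invariants hold", {
  pd <- planted_dissim(c(60, 45, 35), n_background = 25, noise = 0.02,
                       seed = 35)
  asg <- dynamic_tree_cut(average_linkage(pd$d), pd$d, min_module_size = 30L)
  expect_true(all(asg$module_sizes >= 30L))
  expect_identical(sum(asg$module_sizes) + asg$n_unassigned,
                   length(asg$labels))
  expect_identical(sort(unique(asg$labels[asg$labels > 0])),
                   seq_len(asg$n_modules))
  expect_true(all(diff(asg$module_sizes) <= 0))   # decreasing size order
  expect_error(dynamic_tree_cut(average_linkage(pd$d), pd$d,
                                min_module_size = 0L), "at least 1")
})

test_that("the cut is deterministic and permutation-equivariant", {
  pd <- planted_dissim(c(40, 40), n_background = 20, noise = 0.05, seed = 36)
  hc <- average_linkage(pd$d)
  a1 <- dynamic_tree_cut(hc, pd$d)
  a2 <- dynamic_tree_cut(average_linkage(pd$d), pd$d)
  expect_identical(a1$labels, a2$labels)

  set.seed(37)
  perm <- sample(nrow(pd$d))
  dp <- pd$d[perm, perm]
  ap <- dynamic_tree_cut(average_linkage(dp), dp)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(a1$labels[rownames(dp)], ap$labels),
               1, tolerance = 1e-12)
})

test_that("uniform random dissimilarity yields a deterministic result", {
  set.seed(38)
  n <- 60
  d <- matrix(stats::runif(n * n), n, n)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  hc <- average_linkage(d)
  expect_identical(dynamic_tree_cut(hc, d)$labels,
                   dynamic_tree_cut(hc, d)$labels)
})
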