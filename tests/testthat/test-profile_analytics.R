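# Minimal profile constructor for matrix tests.
.mk_profile <- function(id, genes, scores = seq(1, 0.1, length.out = length(genes)),
                        k = length(genes)) {
  structure(list(ingredient_id = id, genes = genes, scores = scores,
                 degenerate = rep(FALSE, length(genes)), k = k),
            class = "target_profile")
}

test_that("profile matrices encode top-k membership", {
  p1 <- .mk_profile("a", c("G1", "G2"))
  p2 <- .mk_profile("b", c("G1", "G2"))
  m <- build_profile_matrix(list(a = p1, b = p2))
  expect_identical(m["a", ], m["b", ])

  # disjoint gene sets give a block structure with row sums = k
  p3 <- .mk_profile("c", c("H1", "H2", "H3"))
  m2 <- build_profile_matrix(list(a = p1, c = p3))
  expect_equal(unname(rowSums(m2)), c(2, 3))
  expect_equal(sum(m2["a", c("H1", "H2", "H3")]), 0)

  # hand enumeration with overlap, k = 2
  pa <- .mk_profile("a", c("G1", "G2"), k = 2)
  pb <- .mk_profile("b", c("G2", "G3"), k = 2)
  pc <- .mk_profile("c", c("G1", "G3"), k = 2)
  m3 <- build_profile_matrix(list(a = pa, b = pb, c = pc))
  expect_identical(colnames(m3), c("G1", "G2", "G3"))
  expect_equal(unname(m3), rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)),
               ignore_attr = TRUE)

  # score encoding keeps the concordance values
  ms <- build_profile_matrix(list(a = pa, b = pb), encoding = "score")
  expect_equal(unname(ms["a", "G1"]), pa$scores[1])
  expect_error(build_profile_matrix(list(a = pa)), "at least 2")
})

test_that("PCA satisfies unit-norm and orthogonality and orders variance", {
  m <- generate_profile_groups(seed = 11)
  pca <- run_pca(m, n_components = 3)
  L <- pca$loadings
  expect_equal(unname(colSums(L^2)), rep(1, 3), tolerance = 1e-8)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(sum(L[, i] * L[, j])), 1e-8)
  }
  evr <- pca$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1) && sum(evr) <= 1 + 1e-12)
  # sign convention: the largest-magnitude loading element is positive
  for (j in 1:3) expect_gt(L[which.max(abs(L[, j])), j], 0)
})

test_that("a rank-1 matrix puts all variance on the first component", {
  m <- outer(c(1, 2, 3, 4), c(0.5, 1, 0.25))
  rownames(m) <- paste0("i", 1:4)
  pca <- run_pca(m, n_components = 1)
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-12)
})

test_that("PCA agrees with a direct covariance eigendecomposition", {
  set.seed(7)
  m <- matrix(as.integer(runif(60) < 0.4), nrow = 10, ncol = 6,
              dimnames = list(paste0("i", 1:10), paste0("g", 1:6)))
  pca <- run_pca(m, n_components = 4)
  eig <- eigen(stats::cov(m), symmetric = TRUE)
  expect_equal(unname(pca$explained_variance_ratio),
               (eig$values / sum(eig$values))[1:4], tolerance = 1e-10)
  for (j in 1:4) {
    expect_equal(abs(unname(pca$loadings[, j])), abs(eig$vectors[, j]),
                 tolerance = 1e-8)
  }
})

test_that("full-rank PCA reconstructs the matrix and conserves variance", {
  set.seed(13)
  m <- matrix(rnorm(40), nrow = 8, ncol = 5,
              dimnames = list(paste0("i", 1:8), paste0("g", 1:5)))
  pca <- run_pca(m, n_components = 5)
  recon <- pca$scores %*% t(pca$loadings) +
    matrix(pca$center, 8, 5, byrow = TRUE)
  expect_equal(unname(recon), unname(m), tolerance = 1e-6)
  expect_equal(sum(pca$explained_variance_ratio), 1, tolerance = 1e-10)
})

test_that("row permutation permutes scores and fixes loadings", {
  m <- generate_profile_groups(n_groups = 2, per_group = 5, seed = 3)
  pca <- run_pca(m, n_components = 2)
  perm <- sample(nrow(m))
  pca2 <- run_pca(m[perm, ], n_components = 2)
  expect_equal(pca2$loadings, pca$loadings, tolerance = 1e-10)
  expect_equal(unname(pca2$scores), unname(pca$scores[perm, ]),
               tolerance = 1e-10)
})

test_that("degenerate PCA inputs are rejected", {
  m <- matrix(1, 4, 3, dimnames = list(paste0("i", 1:4), paste0("g", 1:3)))
  expect_error(run_pca(m, 1), "constant")
  m2 <- generate_profile_groups(n_groups = 2, per_group = 3, seed = 2)
  expect_error(run_pca(m2, n_components = nrow(m2)), "n_components")
})

test_that("well-separated groups cluster to purity 1", {
  set.seed(9)
  scores <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 10), 10, 2))
  rownames(scores) <- paste0("i", 1:20)
  labels <- stats::setNames(rep(c("x", "y"), each = 10), rownames(scores))
  g <- assign_groups(scores, labels, k = 2)
  expect_equal(g$purity, 1)
})

test_that("identical points collapse to one effective cluster", {
  scores <- matrix(1, 6, 2, dimnames = list(paste0("i", 1:6), NULL))
  labels <- stats::setNames(c(rep("x", 4), rep("y", 2)), rownames(scores))
  expect_warning(g <- assign_groups(scores, labels, k = 3), "distinct")
  expect_equal(g$k, 1)
  expect_equal(g$purity, 4 / 6)  # majority-label fraction
})

test_that("planted profile groups are recovered with high purity", {
  set.seed(77)
  purities <- vapply(1:10, function(s) {
    m <- generate_profile_groups(n_groups = 3, per_group = 8, seed = s)
    pca <- run_pca(m, n_components = 2)
    assign_groups(pca, attr(m, "groups"), k = 3)$purity
  }, 0)
  expect_gte(mean(purities >= 0.9), 0.9)
})
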