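equilateral3 <- function() {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  d
}

test_that("closed-form PCoA solutions: equilateral triangle and two points", {
  fit <- pcoa(equilateral3())
  expect_equal(fit$eigenvalues, c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(fit$proportion_explained, c(0.5, 0.5), tolerance = 1e-12)
  # the embedding reproduces all unit distances
  emb <- as.matrix(dist(fit$coordinates))
  expect_equal(unname(emb), unname(equilateral3()), tolerance = 1e-12)

  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f2 <- pcoa(d2)
  expect_equal(f2$eigenvalues[1], 2, tolerance = 1e-12)
  expect_equal(sum(f2$eigenvalues > 0), 1L)
  expect_equal(sort(unname(f2$coordinates[, 1])), c(-1, 1), tolerance = 1e-12)
})

test_that("duplicate samples coincide and invalid matrices are rejected", {
  x <- matrix(c(1, 2, 3, 1, 2, 3, 9, 1, 4), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "a2", "b"), c("f1", "f2", "f3")))
  fit <- pcoa(pairwise_distances(x, "euclidean"))
  expect_lt(max(abs(fit$coordinates["a", ] - fit$coordinates["a2", ])), 1e-9)

  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcoa(bad), "symmetric")
  nonhollow <- matrix(c(1, 1, 1, 1), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcoa(nonhollow), "hollow")
})

test_that("PCoA on Euclidean distances is equivalent to PCA", {
  set.seed(99)
  for (rep in seq_len(10)) {
    x <- matrix(rnorm(12 * 8), 12, 8,
                dimnames = list(sprintf("s%02d", 1:12), sprintf("f%d", 1:8)))
    fit_pcoa <- pcoa(pairwise_distances(x, "euclidean"))
    fit_pca <- pca(x)
    k <- min(ncol(fit_pcoa$coordinates), ncol(fit_pca$coordinates))
    expect_equal(fit_pcoa$eigenvalues[1:k], fit_pca$eigenvalues[1:k],
                 tolerance = 1e-8)
    for (a in seq_len(k)) {
      u <- fit_pcoa$coordinates[, a]; v <- fit_pca$coordinates[, a]
      expect_lt(min(max(abs(u - v)), max(abs(u + v))), 1e-8)
    }
  }
})

test_that("eigenvalue bookkeeping: trace identity and distance preservation", {
  ft <- toy_table(404, n = 9, p = 14)
  dm <- pairwise_distances(ft, "euclidean")
  fit <- pcoa(dm)
  # sum of all eigenvalues equals trace of the Gower-centered matrix,
  # recomputed here from first principles
  m <- matrix(dm, nrow(dm))
  a <- -0.5 * m^2
  j <- diag(nrow(m)) - matrix(1 / nrow(m), nrow(m), nrow(m))
  b <- j %*% a %*% j
  expect_equal(sum(fit$eigenvalues), sum(diag(b)), tolerance = 1e-9)
  # a Euclidean matrix embeds exactly when all positive axes are kept
  emb <- as.matrix(dist(fit$coordinates))
  expect_equal(unname(emb), unname(m), tolerance = 1e-8)
  # proportions in [0, 1], summing to <= 1
  expect_true(all(fit$proportion_explained >= 0 & fit$proportion_explained <= 1))
  expect_lte(sum(fit$proportion_explained), 1 + 1e-9)
  # eigenvalues sorted descending
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
})

test_that("non-Euclidean dissimilarities report negative eigenvalue mass", {
  ft <- toy_table(71, n = 14, p = 10, sparsity = 0.4)
  fit <- pcoa(pairwise_distances(ft, "braycurtis"))
  expect_gt(fit$negative_eigenvalue_mass, 0)
  expect_true(all(fit$eigenvalues[seq_len(ncol(fit$coordinates))] > 0))
  # coordinates only span positive axes
  expect_equal(ncol(fit$coordinates), sum(fit$eigenvalues > 0))
})

test_that("pcoa agrees with cmdscale and ape::pcoa on random matrices", {
  skip_if_not_installed("ape")
  ft <- toy_table(88, n = 10, p = 12)
  dm <- pairwise_distances(ft, "braycurtis")
  fit <- pcoa(dm)
  k <- 3
  cm <- cmdscale(as.dist(dm), k = k, eig = TRUE)
  expect_equal(fit$eigenvalues[1:k], cm$eig[1:k], tolerance = 1e-9)
  for (a in 1:k) {
    u <- fit$coordinates[, a]; v <- cm$points[, a]
    expect_lt(min(max(abs(u - v)), max(abs(u + v))), 1e-8)
  }
  ap <- ape::pcoa(as.dist(dm))
  expect_equal(fit$eigenvalues[1:k], ap$values$Eigenvalues[1:k],
               tolerance = 1e-9)
})

test_that("PCA closed forms, trace convention and prcomp agreement", {
  # all rows on a line -> one axis explains everything
  line <- matrix(c(0, 0, 1, 2, 2, 4), 3, 2, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3), c("f1", "f2")))
  expect_equal(pca(line)$proportion_explained[1], 1, tolerance = 1e-12)

  m <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("f1", "f2")))
  fit <- pca(m)
  expect_equal(fit$eigenvalues[1], 2, tolerance = 1e-12)
  expect_equal(sort(unname(fit$coordinates[, 1])), c(-1, 1), tolerance = 1e-12)

  set.seed(12)
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:6)))
  fit <- pca(x)
  expect_equal(sum(fit$eigenvalues), sum(apply(x, 2, var)) * (10 - 1),
               tolerance = 1e-9)
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(fit$eigenvalues[1:6], unname(pr$sdev^2 * (10 - 1)),
               tolerance = 1e-9)
  for (a in 1:5) {
    u <- fit$coordinates[, a]; v <- pr$x[, a]
    expect_lt(min(max(abs(u - v)), max(abs(u + v))), 1e-8)
  }
  expect_error(pca(matrix(1, 1, 2, dimnames = list("s", c("a", "b")))),
               "at least 2")
})

test_that("ordination output is deterministic including eigenvector sign", {
  ft <- toy_table(5150, n = 11, p = 9)
  dm <- pairwise_distances(ft, "braycurtis")
  f1 <- pcoa(dm); f2 <- pcoa(dm)
  expect_identical(f1$coordinates, f2$coordinates)
  # sign convention: the largest-|loading| element of each axis is positive
  for (a in seq_len(ncol(f1$coordinates))) {
    v <- f1$coordinates[, a]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("num_axes truncates coordinates but keeps the full spectrum", {
  ft <- toy_table(2024, n = 8, p = 10)
  fit <- pcoa(pairwise_distances(ft, "euclidean"), num_axes = 3)
  expect_equal(ncol(fit$coordinates), 3L)
  expect_length(fit$eigenvalues, 8)
  full <- pcoa(pairwise_distances(ft, "euclidean"))
  expect_equal(fit$coordinates, full$coordinates[, 1:3])
  expect_output(print(fit), "PCOA")
})
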