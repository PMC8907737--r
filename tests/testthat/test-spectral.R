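block_affinity <- function(sizes, within = 0.8) {
  n <- sum(sizes)
  A <- matrix(0, n, n)
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b + 1] - 1)
    A[idx, idx] <- within
  }
  diag(A) <- 1
  A
}

test_that("standardisation gives zero mean and unit population variance", {
  expect_equal(standardize_features(matrix(c(1, 2, 3))),
               matrix(c(-1, 0, 1) * sqrt(3 / 2)), tolerance = 1e-12)
  expect_warning(Z <- standardize_features(cbind(a = c(1, 1, 1), b = c(0, 1, 2))),
                 "constant")
  expect_equal(Z[, 1], rep(0, 3))
  for (seed in 1:5) {
    X <- withr::with_seed(seed, matrix(rnorm(60, 5, 3), 20))
    Z <- standardize_features(X)
    expect_true(all(abs(colMeans(Z)) < 1e-12))
    expect_true(all(abs(colMeans(Z^2) - 1) < 1e-12))
  }
  expect_error(standardize_features(matrix(1, 1, 2)),
               class = "leadrisk_domain_error")
})

test_that("RBF affinity has unit diagonal, symmetry, and the closed-form decay", {
  Z <- rbind(c(0, 0), c(1, 0), c(0, 0))
  A <- rbf_affinity(Z, 1)
  expect_equal(unname(diag(A)), rep(1, 3))
  expect_equal(A[1, 3], 1)           # identical rows
  expect_equal(A[1, 2], exp(-1))     # unit squared distance at gamma 1
  expect_equal(max(abs(A - t(A))), 0)
  A5 <- rbf_affinity(Z, 5)
  expect_equal(A5[1, 2], exp(-5))
  expect_error(rbf_affinity(Z, 0), class = "leadrisk_domain_error")
})

test_that("normalised Laplacian has the expected spectrum", {
  # complete graph with equal affinities on 3 nodes: eigenvalues 0, 1.5, 1.5
  A <- matrix(0.5, 3, 3); diag(A) <- 1
  L <- normalized_laplacian(A)
  expect_equal(sort(eigen(L, symmetric = TRUE)$values), c(0, 1.5, 1.5))

  # two disconnected blocks: eigenvalue 0 with multiplicity 2
  L2 <- normalized_laplacian(block_affinity(c(3, 4)))
  ev <- eigen(L2, symmetric = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10), 2)

  # symmetry and eigenvalue range on random affinities
  for (seed in 1:5) {
    Z <- withr::with_seed(seed, matrix(rnorm(30), 10))
    L3 <- normalized_laplacian(rbf_affinity(Z, 2))
    expect_equal(max(abs(L3 - t(L3))), 0)
    ev3 <- eigen(L3, symmetric = TRUE)$values
    expect_true(all(ev3 > -1e-10 & ev3 < 2 + 1e-10))
    expect_lt(min(abs(ev3)), 1e-10)
  }
  expect_error(normalized_laplacian(diag(3)), class = "leadrisk_domain_error")
})

test_that("spectral embedding returns verified eigenpairs with unit rows", {
  Z <- withr::with_seed(2, matrix(rnorm(36), 12))
  L <- normalized_laplacian(rbf_affinity(Z, 1))
  V <- spectral_embed(L, 3, row_normalize = FALSE)
  # columns satisfy the eigen equation: L v = lambda v with Rayleigh lambdas
  for (j in 1:3) {
    lambda <- drop(t(V[, j]) %*% L %*% V[, j])
    expect_lt(max(abs(L %*% V[, j] - lambda * V[, j])), 1e-8)
  }
  expect_equal(t(V) %*% V, diag(3), tolerance = 1e-8)
  Vn <- spectral_embed(L, 3)
  expect_equal(rowSums(Vn^2), rep(1, 12), tolerance = 1e-12)
  expect_error(spectral_embed(L, 13), class = "leadrisk_domain_error")
})

test_that("embedding of two disconnected blocks is block-constant", {
  L <- normalized_laplacian(block_affinity(c(5, 7)))
  V <- spectral_embed(L, 2)
  membership <- rep(1:2, c(5, 7))
  for (b in 1:2) {
    rows <- V[membership == b, , drop = FALSE]
    expect_lt(max(dist(rows)), 1e-8)
  }
  # and the two block rows are distinct
  expect_gt(sum((V[1, ] - V[6, ])^2), 0.5)
})

test_that("k-means attains known optima and keeps a non-increasing trace", {
  X <- withr::with_seed(4, matrix(rnorm(40), 20))
  one <- kmeans_lloyd(X, 1, seed = 1)
  expect_equal(one$inertia, sum(sweep(X, 2, colMeans(X))^2))
  alln <- kmeans_lloyd(X, nrow(X), seed = 1)
  expect_equal(alln$inertia, 0)
  expect_equal(sort(unique(alln$labels)), 1:20)

  # two well-separated blobs: every restart must find the exhaustive optimum
  blobs <- withr::with_seed(5, rbind(matrix(rnorm(20, 0, 0.3), 10),
                                     matrix(rnorm(20, 8, 0.3), 10)))
  fit <- kmeans_lloyd(blobs, 2, seed = 3)
  expect_equal(fit$inertia, best_two_partition_inertia(blobs), tolerance = 1e-9)
  expect_equal(adjusted_rand_index(fit$labels, rep(1:2, each = 10)), 1)
  expect_true(all(diff(fit$trace) <= 1e-9))
  # deterministic under a fixed seed
  expect_identical(fit$labels, kmeans_lloyd(blobs, 2, seed = 3)$labels)
})

test_that("spectral clustering separates tiers and respects row permutation", {
  X <- withr::with_seed(6, rbind(matrix(rnorm(30, 0, 0.2), 15),
                                 matrix(rnorm(30, 4, 0.2), 15)))
  fit <- spectral_cluster(X, parameter = 2, k = 2, seed = 1)
  expect_equal(adjusted_rand_index(fit$labels, rep(1:2, each = 15)), 1)

  perm <- withr::with_seed(7, sample(nrow(X)))
  fit_p <- spectral_cluster(X[perm, ], parameter = 2, k = 2, seed = 1)
  expect_equal(adjusted_rand_index(fit_p$labels, fit$labels[perm]), 1)
})

test_that("spectral clustering recovers non-convex geometry where raw k-means fails", {
  geom <- ring_and_blob()
  sp <- spectral_cluster(geom$X, parameter = 10, k = 2, seed = 2)
  expect_equal(adjusted_rand_index(sp$labels, geom$membership), 1)
  km <- kmeans_lloyd(standardize_features(geom$X), 2, seed = 2)
  expect_lt(adjusted_rand_index(km$labels, geom$membership), 0.5)
})

test_that("CH index matches the hand-computed toy and the dispersion oracle", {
  X <- matrix(c(0, 1, 10, 11))
  # centroids 0.5 and 10.5, grand mean 5.5: B = 100, W = 1, CH = 200
  expect_equal(calinski_harabasz(X, c(1, 1, 2, 2)), 200)
  expect_equal(ch_oracle(X, c(1, 1, 2, 2)), 200)
  expect_error(calinski_harabasz(X, rep(1, 4)), class = "leadrisk_domain_error")

  for (seed in 1:10) {
    n <- 40 + seed * 10
    X <- withr::with_seed(seed, matrix(rnorm(3 * n), n))
    labels <- withr::with_seed(seed + 100, sample(1:4, n, TRUE))
    labels <- as.integer(factor(labels))
    expect_equal(calinski_harabasz(X, labels), ch_oracle(X, labels),
                 tolerance = 1e-9)
  }
})

test_that("CH rewards separation: true split beats random splits", {
  X <- withr::with_seed(8, rbind(matrix(rnorm(30, 0, 0.3), 15),
                                 matrix(rnorm(30, 6, 0.3), 15)))
  truth <- rep(1:2, each = 15)
  ch_true <- calinski_harabasz(X, truth)
  for (seed in 1:5) {
    rand <- withr::with_seed(seed, sample(truth))
    expect_gt(ch_true, calinski_harabasz(X, rand))
  }
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  for (seed in 1:5) {
    a <- withr::with_seed(seed, sample(1:4, 60, TRUE))
    b <- withr::with_seed(seed + 9, sample(1:3, 60, TRUE))
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("grid search selects the maximum with deterministic tie-breaks", {
  blobs <- withr::with_seed(9, rbind(matrix(rnorm(20, 0, 0.2), 10),
                                     matrix(rnorm(20, 5, 0.2), 10)))
  single <- ch_grid_search(blobs, parameters = 3, ks = 2, seed = 1)
  expect_equal(single$best_parameter, 3)
  expect_equal(single$best_k, 2)
  expect_equal(nrow(tidy(single)), 1)

  # both kernel widths give the identical perfect labelling: smaller wins
  two <- ch_grid_search(blobs, parameters = c(2, 4), ks = 2, seed = 1)
  expect_equal(dplyr::n_distinct(two$scores$score), 1)
  expect_equal(two$best_parameter, 2)

  # duplicated points: k = 2 and k = 3 both reach zero within-dispersion
  # (infinite CH); the tie goes to the smaller k
  dup <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  dup <- dup + withr::with_seed(1, matrix(0, 6, 2))
  tie <- ch_grid_search(dup, parameters = 1, ks = c(2, 3), seed = 1)
  expect_equal(tie$best_k, 2)

  # full determinism of the result object
  g1 <- ch_grid_search(blobs, parameters = 1:3, ks = 2:3, seed = 5)
  g2 <- ch_grid_search(blobs, parameters = 1:3, ks = 2:3, seed = 5)
  expect_identical(tidy(g1), tidy(g2))
  expect_identical(g1$labels, g2$labels)
  expect_error(ch_grid_search(blobs, parameters = numeric(0), ks = 2),
               class = "leadrisk_domain_error")
})

test_that("grid-search tidiers and plot expose the score table and optimum", {
  blobs <- withr::with_seed(10, rbind(matrix(rnorm(20, 0, 0.2), 10),
                                      matrix(rnorm(20, 5, 0.2), 10)))
  gs <- ch_grid_search(blobs, parameters = 1:2, ks = 2:3, seed = 1)
  expect_named(tidy(gs), c("parameter", "k", "score"))
  gl <- glance(gs)
  expect_equal(gl$best_score, max(tidy(gs)$score, na.rm = TRUE))
  p <- autoplot(gs)
  expect_s3_class(p, "ggplot")
})
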