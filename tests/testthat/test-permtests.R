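test_that("Mantel r is 1 for identical and affinely related matrices", {
  set.seed(81)
  D <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  m <- mantel_test(D, D, n_perm = 99, seed = 1)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_equal(m$p, 1 / 100)
  m2 <- mantel_test(D, 3 * D + 2 - diag(2, nrow(D)), n_perm = 99, seed = 1)
  expect_equal(m2$r, 1, tolerance = 1e-12)
})

test_that("Mantel statistic agrees with the established implementation", {
  skip_if_not_installed("vegan")
  set.seed(82)
  for (i in 1:5) {
    A <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
    B <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
    ours <- mantel_test(A, B, n_perm = 99, seed = i)
    ref <- vegan::mantel(A, B, permutations = 99)
    expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("Mantel rejects malformed inputs", {
  D <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  expect_error(mantel_test(D, D[1:8, 1:8]), "mismatch")
  asym <- D; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel_test(D, asym), "symmetric")
  diag(asym) <- 5
  expect_error(mantel_test(asym, asym), "diagonal|symmetric")
})

test_that("Procrustes r is invariant to rotation, scaling and translation", {
  set.seed(83)
  X <- matrix(rnorm(60), 30, 2)
  self <- procrustes_protest(X, X, n_perm = 99, seed = 1)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$m2, 0, tolerance = 1e-12)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- 2.5 * X %*% R + matrix(rep(c(3, -1), each = 30), 30, 2)
  rot <- procrustes_protest(X, Y, n_perm = 99, seed = 1)
  expect_equal(rot$r, 1, tolerance = 1e-12)
})

test_that("Procrustes r is symmetric and matches vegan and a numeric search", {
  set.seed(84)
  for (i in 1:5) {
    X <- matrix(rnorm(60), 30, 2)
    Y <- matrix(rnorm(60), 30, 2)
    ab <- procrustes_protest(X, Y, n_perm = 49, seed = i)
    ba <- procrustes_protest(Y, X, n_perm = 49, seed = i)
    expect_lt(abs(ab$r - ba$r), 1e-9)
    expect_equal(ab$r, sqrt(1 - ab$m2), tolerance = 1e-12)
    # independent oracle: numerically searched best rotation/reflection
    expect_equal(ab$r, oracle_protest_r_2d(X, Y), tolerance = 1e-6)
    if (requireNamespace("vegan", quietly = TRUE)) {
      ref <- vegan::protest(X, Y, permutations = 49)
      expect_equal(ab$r, ref$t0, tolerance = 1e-9)
    }
  }
  expect_error(procrustes_protest(matrix(0, 3, 2), matrix(0, 4, 2)),
               "shape")
})

test_that("permutation p-values respect the add-one convention", {
  set.seed(85)
  X <- matrix(rnorm(40), 20, 2)
  Y <- matrix(rnorm(40), 20, 2)
  pr <- procrustes_protest(X, Y, n_perm = 999, seed = 9)
  expect_gte(pr$p, 1 / 1000)
  expect_lte(pr$p, 1)
  D1 <- as.matrix(dist(X)); D2 <- as.matrix(dist(Y))
  mt <- mantel_test(D1, D2, n_perm = 999, seed = 9)
  expect_gte(mt$p, 1 / 1000)
  # identical inputs give the minimum attainable p
  expect_equal(mantel_test(D1, D1, n_perm = 999, seed = 9)$p, 1 / 1000)
})
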