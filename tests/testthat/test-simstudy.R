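# Simulation benchmark: the block-sparse ground truth and the recovery
# metrics.

test_that("ground truth has the documented block-sparse orthonormal structure", {
  gt <- make_ground_truth(seed = 3)
  expect_equal(dim(gt$P_M), c(150L, 5L))
  expect_equal(dim(gt$Q_M), c(600L, 5L))
  expect_lt(max(abs(crossprod(gt$P_M) - diag(5))), 1e-10)
  expect_lt(max(abs(crossprod(gt$Q_M) - diag(5))), 1e-10)
  # each column supported on the shared top block plus its own block,
  # each sub-vector of norm 2^(-1/2)
  for (l in 1:5) {
    expect_equal(l2norm(gt$P_M[1:25, l]), 2^-0.5, tolerance = 1e-10)
    expect_equal(l2norm(gt$P_M[l * 25 + 1:25, l]), 2^-0.5, tolerance = 1e-10)
    expect_equal(l2norm(gt$Q_M[1:100, l]), 2^-0.5, tolerance = 1e-10)
    supp <- c(1:25, l * 25 + 1:25)
    expect_true(all(gt$P_M[-supp, l] == 0))
    supp_q <- c(1:100, l * 100 + 1:100)
    expect_true(all(gt$Q_M[-supp_q, l] == 0))
  }
  # construction forces the singular values exactly (dense SVD oracle)
  X_M <- gt$P_M %*% (gt$delta_M * t(gt$Q_M))
  expect_equal(svd(X_M)$d[1:5], c(15, 14, 13, 12, 11), tolerance = 1e-9)
  # different seeds: different vectors, identical support pattern
  gt2 <- make_ground_truth(seed = 4)
  expect_false(isTRUE(all.equal(gt$P_M, gt2$P_M)))
  expect_identical(gt$P_M == 0, gt2$P_M == 0)
})

test_that("simulate_X adds Gaussian noise of the stated scale", {
  gt0 <- make_ground_truth(seed = 5, noise_sd = 0)
  X0 <- simulate_X(gt0)
  expect_lt(svd(X0)$d[6], 1e-10)              # exactly rank 5
  gt <- make_ground_truth(seed = 5, noise_sd = 0.01)
  X <- simulate_X(gt)
  E <- X - X0
  expect_equal(sd(E), 0.01, tolerance = 0.05)
  # same gt seed, same noise seed: reproducible
  expect_identical(X, simulate_X(gt))
})

test_that("squared error metric is zero for the truth, sign-invariant, and explicit", {
  gt <- make_ground_truth(seed = 6)
  truth_dec <- structure(list(P = gt$P_M, Q = gt$Q_M, delta = gt$delta_M),
                         class = "csvd_decomposition")
  se <- squared_error_to_truth(truth_dec, gt)
  expect_equal(max(se$p), 0)
  flipped <- truth_dec
  flipped$P <- -flipped$P; flipped$Q <- -flipped$Q
  se2 <- squared_error_to_truth(flipped, gt)
  expect_equal(max(se2$p), 0)
  expect_equal(max(se2$q), 0)
  # random estimate: direct formula
  set.seed(61)
  est <- truth_dec
  est$P <- matrix(rnorm(150 * 5), 150, 5)
  se3 <- squared_error_to_truth(est, gt)
  l <- 2
  s <- sign(sum(est$P[, l] * gt$P_M[, l]))
  expect_equal(se3$p[, l], (s * est$P[, l] - gt$P_M[, l])^2)
})

test_that("correlation metric behaves on identical, disjoint and degenerate vectors", {
  gt <- make_ground_truth(seed = 7)
  truth_dec <- structure(list(P = gt$P_M, Q = gt$Q_M, delta = gt$delta_M),
                         class = "csvd_decomposition")
  co <- correlation_to_truth(truth_dec, gt)
  expect_equal(diag(co$p), rep(1, 5), tolerance = 1e-12)
  expect_equal(dim(co$q), c(5L, 5L))
  # spot-check against the direct formula
  expect_equal(co$q[2, 4], cor(gt$Q_M[, 2], gt$Q_M[, 4]))
  bad <- truth_dec
  bad$P[, 3] <- 0
  w <- capture_warnings(co2 <- correlation_to_truth(bad, gt))
  expect_true(any(grepl("zero-variance", w)))
  expect_true(all(is.na(co2$p[, 3])))
})

test_that("crossprod and pseudo-eigenvalues follow their definitions", {
  set.seed(71)
  V <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  expect_equal(crossprod_matrix(V), t(V) %*% V)
  expect_equal(crossprod_matrix(V), diag(4), tolerance = 1e-12)
  W <- cbind(V[, 1], V[, 1])
  expect_equal(crossprod_matrix(W)[1, 2], 1, tolerance = 1e-12)
  # centered matrix: variance of factor scores = delta^2 / I for SVD vectors
  X <- matrix(rnorm(20 * 8), 20, 8)
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  ev <- pseudo_eigenvalues(X, sv$v[, 1:3])
  expect_equal(ev, sv$d[1:3]^2 / 20, tolerance = 1e-8)
  expect_equal(pseudo_eigenvalues(X, matrix(0, 8, 1)), 0)
})
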