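# Projection operators: thresholding, single balls, the exact L1/L2
# intersection operator, orthocomplements, and POCS.

test_that("soft thresholding follows the three-branch shrinkage rule", {
  expect_equal(soft_threshold(2.0, 0.5), 1.5)
  expect_equal(soft_threshold(-0.3, 0.5), 0.0)
  expect_equal(soft_threshold(-2.0, 0.5), -1.5)
  expect_error(soft_threshold(1, -0.1), "non-negative")
  expect_error(soft_threshold(c(1, 2), 0.5), "single number")

  expect_equal(soft_threshold_vec(c(1, -1, 0.1), 0.5), c(0.5, -0.5, 0))
  x <- rnorm(10)
  expect_equal(soft_threshold_vec(x, 0), x)            # identity at gamma = 0
  expect_equal(soft_threshold_vec(x, max(abs(x))), rep(0, 10))
})

test_that("proj_l2 scales outside points radially and leaves inside points alone", {
  expect_equal(proj_l2(c(3, 4), 1), c(0.6, 0.8))
  expect_equal(proj_l2(c(0.3, 0), 1), c(0.3, 0))
  expect_equal(proj_l2(c(0, 0), 1), c(0, 0))
  expect_error(proj_l2(1:3, -1), "positive")
  # variational characterization of the Euclidean projection:
  # (x - y)'(z - y) <= 0 for every feasible z
  set.seed(11)
  for (k in 1:20) {
    x <- rnorm(20) * 3
    y <- proj_l2(x, 1)
    z <- proj_l2(rnorm(20) * 2, 1)       # arbitrary feasible point
    expect_lte(sum((x - y) * (z - y)), 1e-10)
  }
})

test_that("proj_l1 matches the bisection oracle on random instances", {
  expect_equal(proj_l1(c(0.3, -0.2), 1), c(0.3, -0.2))   # inside
  expect_equal(proj_l1(c(3, 0), 1), c(1, 0))             # on-axis
  expect_equal(proj_l1(c(2, 1), 1), c(1, 0))             # oracle-derived
  expect_error(proj_l1(c(1, 2), 0), "positive")
  set.seed(21)
  worst <- 0
  for (k in 1:1000) {
    N <- sample(2:50, 1)
    x <- rnorm(N) * runif(1, 0.1, 10)
    c <- runif(1, 0.05, 1.2) * sum(abs(x))
    worst <- max(worst, max(abs(proj_l1(x, c) - oracle_proj_l1(x, c))))
  }
  expect_lt(worst, 1e-8)
  # sign pattern preserved and L1 norm hits the radius when active
  x <- c(3, -2, 0.5, -0.1)
  y <- proj_l1(x, 2)
  expect_equal(l1norm(y), 2, tolerance = 1e-9)
  expect_true(all(sign(y)[y != 0] == sign(x)[y != 0]))
})

test_that("psi is the norm ratio, plateaus at sqrt(#tied maxima), and is non-increasing", {
  x <- sort(abs(rnorm(8)), decreasing = TRUE)
  expect_equal(psi(x, 0), sum(x) / l2norm(x))
  # tied maxima: for lambda in [x2, x1), psi = sqrt(N_max)
  xt <- c(2, 2, 2, 1, 0.5)
  for (lam in c(1, 1.5, 1.999)) expect_equal(psi(xt, lam), sqrt(3))
  expect_error(psi(xt, 2), "lam")
  expect_error(psi(c(1, 2, 3), 0.5), "decreasing")
  set.seed(31)
  for (k in 1:10) {
    x <- sort(abs(rnorm(sample(3:30, 1))), decreasing = TRUE)
    grid <- seq(0, x[1] * (1 - 1e-9), length.out = 1000)
    vals <- vapply(grid, function(l) psi(x, l), numeric(1))
    expect_true(all(diff(vals) <= 1e-10))
  }
})

test_that("proj_l1l2 is exact against the psi-bisection oracle", {
  expect_equal(proj_l1l2(c(5, 0, 0), 1), c(1, 0, 0))
  x <- c(1, 2, -0.5)
  expect_equal(proj_l1l2(x, sqrt(3)), x / l2norm(x))    # constraint inactive
  expect_equal(proj_l1l2(c(2, 1, 0), 1.2),
               oracle_proj_l1l2(c(2, 1, 0), 1.2), tolerance = 1e-10)
  expect_error(proj_l1l2(c(1, 2), 3), "c")
  expect_error(proj_l1l2(c(0, 0, 0), 1.2), "zero")
  set.seed(41)
  worst <- 0
  for (k in 1:500) {
    N <- sample(2:50, 1)
    x <- rnorm(N) * runif(1, 0.1, 10)
    c <- runif(1, 1, sqrt(N))
    y <- proj_l1l2(x, c)
    worst <- max(worst, max(abs(y - oracle_proj_l1l2(x, c))))
    expect_equal(l2norm(y), 1, tolerance = 1e-10)
    expect_lte(l1norm(y), c + 1e-8)
  }
  expect_lt(worst, 1e-8)
})

test_that("proj_l1l2 warns and returns the tied-maxima limit when c < sqrt(N_max)", {
  x <- c(1, 1, 1, 0.2)
  expect_warning(y <- proj_l1l2(x, 1.2), "tied maxima")
  expect_equal(y, c(1, 1, 1, 0) / sqrt(3))
})

test_that("proj_ortho removes the span of an orthonormal basis", {
  x <- rnorm(6)
  expect_equal(proj_ortho(x, NULL), x)
  expect_equal(proj_ortho(x, matrix(numeric(0), 6, 0)), x)
  v <- x / l2norm(x)
  expect_equal(proj_ortho(v, matrix(v)), rep(0, 6), tolerance = 1e-12)
  expect_error(proj_ortho(x, rand_basis(5, 2)), "dimension mismatch")
  expect_error(proj_ortho(x, matrix(rnorm(12), 6, 2) * 3), "orthonormal")
  # least-squares oracle: the residual of regressing x on the basis
  set.seed(51)
  for (k in 1:20) {
    B <- rand_basis(15, sample(1:5, 1))
    x <- rnorm(15)
    res <- x - B %*% qr.solve(B, x)
    y <- proj_ortho(x, B)
    expect_equal(y, drop(res), tolerance = 1e-10)
    expect_lt(max(abs(crossprod(B, y))), 1e-10)
  }
})

test_that("projections are idempotent", {
  set.seed(61)
  for (k in 1:20) {
    N <- sample(3:30, 1)
    x <- rnorm(N) * 3
    c <- runif(1, 1, sqrt(N))
    y1 <- proj_l1(x, c);        expect_equal(proj_l1(y1, c), y1, tolerance = 1e-10)
    y2 <- proj_l2(x, 1);        expect_equal(proj_l2(y2, 1), y2, tolerance = 1e-10)
    y3 <- proj_l1l2(x, c);      expect_equal(proj_l1l2(y3, c), y3, tolerance = 1e-10)
    B <- rand_basis(N, 2)
    y4 <- proj_ortho(x, B);     expect_equal(proj_ortho(y4, B), y4, tolerance = 1e-10)
  }
})

test_that("pocs cycles projections to a point feasible for every set", {
  x <- c(2, -1, 0.5)
  # single set: identical to the direct projection
  y <- pocs(x, list(constraint_set(l2_radius = 1)))
  expect_equal(as.numeric(y), proj_l2(x, 1))
  # already in the intersection: fixed point after one sweep
  z <- c(0.5, 0.1, 0)
  y2 <- pocs(z, list(constraint_set(l1_radius = 1), constraint_set(l2_radius = 1)))
  expect_equal(as.numeric(y2), z)
  expect_equal(attr(y2, "iterations"), 1L)
  # L1 + L2 pair: the limit is feasible for both sets and sits on the L2
  # boundary like the exact PL1L2 point; the alternating-projection limit is
  # a feasible point, not the Euclidean projection, so the L1 constraint may
  # come out slack (here it does) -- PL1L2 is the operator of record
  y3 <- pocs(c(2, 1, 0), list(constraint_set(l1_radius = 1.2),
                              constraint_set(l2_radius = 1)),
             eps = 1e-10, max_iter = 10000)
  ref <- proj_l1l2(c(2, 1, 0), 1.2)
  expect_lte(l1norm(y3), 1.2 + 1e-8)
  expect_equal(l2norm(y3), l2norm(ref), tolerance = 1e-8)
  # exhausting max_iter warns and flags
  expect_warning(
    y4 <- pocs(c(2, 1, 0), list(constraint_set(l1_radius = 1.2),
                                constraint_set(l2_radius = 1)),
               eps = 1e-12, max_iter = 1),
    "not converged")
  expect_false(attr(y4, "converged"))
})

test_that("constraint_set validates its fields and projects combinations exactly", {
  expect_error(constraint_set(l1_radius = -1), "positive")
  expect_error(constraint_set(ortho_basis = matrix(rnorm(9), 3) * 2), "orthonormal")
  set.seed(71)
  B <- rand_basis(10, 2)
  s <- constraint_set(l1_radius = 1.5, l2_radius = 1, ortho_basis = B)
  x <- rnorm(10) * 2
  y <- project(s, x)
  expect_lte(l1norm(y), 1.5 + 1e-8)
  expect_lte(l2norm(y), 1 + 1e-10)
  # interior points of the balls are left unchanged by the ball projections
  s2 <- constraint_set(l1_radius = 30, l2_radius = 10)
  expect_equal(project(s2, x), x)
})
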