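# Independent oracles used across the suite.  All are deliberately dumb
# (bisection / direct formulas) and share no code with the package paths
# they check.

# Euclidean projection onto the L1 ball by bisection on the piecewise
# linear phi(lambda) = l1norm(soft_threshold(x, lambda)).
oracle_proj_l1 <- function(x, c, iters = 200L) {
  if (sum(abs(x)) <= c) return(x)
  f <- function(lam) sum(pmax(abs(x) - lam, 0)) - c
  lo <- 0; hi <- max(abs(x))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  lam <- (lo + hi) / 2
  sign(x) * pmax(abs(x) - lam, 0)
}

# Projection onto B_L1(c) n B_L2(1)-boundary by bisection on the norm
# ratio psi(lambda), then renormalization.
oracle_proj_l1l2 <- function(x, c, iters = 200L) {
  l2 <- sqrt(sum(x^2))
  if (sum(abs(x)) / l2 <= c) return(x / l2)
  f <- function(lam) {
    s <- pmax(abs(x) - lam, 0)
    sum(s) / sqrt(sum(s^2)) - c
  }
  lo <- 0; hi <- max(abs(x)) * (1 - 1e-15)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  lam <- (lo + hi) / 2
  y <- sign(x) * pmax(abs(x) - lam, 0)
  y / sqrt(sum(y^2))
}

# Random matrix with orthonormal columns.
rand_basis <- function(n, k) qr.Q(qr(matrix(rnorm(n * k), n, k)))

# Random matrix with a distinct spectrum (singular vectors of near-tied
# singular values are ill-conditioned, so gapless draws are rejected).
rand_distinct <- function(n, m, min_gap = 0.15) {
  repeat {
    X <- matrix(rnorm(n * m), n, m)
    if (min(-diff(svd(X)$d)) > min_gap) return(X)
  }
}

# Max column-wise difference after per-column optimal sign alignment.
max_diff_upto_sign <- function(A, B) {
  max(vapply(seq_len(ncol(A)), function(j) {
    s <- if (sum(A[, j] * B[, j]) < 0) -1 else 1
    max(abs(s * A[, j] - B[, j]))
  }, numeric(1)))
}

l1norm <- function(x) sum(abs(x))
l2norm <- function(x) sqrt(sum(x^2))
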