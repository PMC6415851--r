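# Simulation benchmark: a 150 x 600 rank-5 ground truth with block-sparse
# orthonormal singular vectors plus i.i.d. Gaussian noise, and the recovery
# metrics used to compare SVD / CSVD / PMD against that truth.

#' Generate the block-sparse rank-5 ground truth
#'
#' Builds orthonormal, sparse factor matrices `P_M` (150 x 5) and `Q_M`
#' (600 x 5) with singular values `delta_M = c(15, 14, 13, 12, 11)`.  Each
#' column of `P_M` is supported on exactly two blocks of `p_block = 25`
#' rows: a top block shared by all five components (holding five mutually
#' orthogonal sub-vectors) and one component-specific block; both
#' sub-vectors have L2 norm \eqn{2^{-1/2}} so each column has unit norm.
#' `Q_M` has the same two-block layout with `q_block = 100` rows per block.
#' Disjoint specific blocks plus the orthogonalized shared family make the
#' columns exactly orthonormal, so the singular values of
#' `P_M %*% diag(delta_M) %*% t(Q_M)` are exactly `delta_M`.
#'
#' Sub-vectors are seeded Gaussian draws; the shared-block families are
#' orthogonalized by QR (equivalent to Gram-Schmidt) before rescaling.
#'
#' @param seed Integer seed controlling every random draw.
#' @param delta_M True singular values (default `c(15, 14, 13, 12, 11)`).
#' @param noise_sd Standard deviation of the additive Gaussian noise used
#'   by [simulate_X()] (default 0.01).
#' @param p_block,q_block Block sizes for the left/right factors
#'   (defaults 25 and 100; dimensions are `(rank + 1) * block`).
#' @return An object of class `"csvd_ground_truth"` with fields `P_M`,
#'   `Q_M`, `delta_M`, `noise_sd`, `p_block`, `q_block`, `seed`.
#' @export
make_ground_truth <- function(seed = 1L, delta_M = c(15, 14, 13, 12, 11),
                              noise_sd = 0.01, p_block = 25L, q_block = 100L) {
  rank <- length(delta_M)
  set.seed(seed)
  build_factor <- function(block) {
    N <- (rank + 1L) * block
    if (block < rank) stop("block size must be at least the rank")
    # shared top block: `rank` mutually orthogonal sub-vectors of norm 2^-1/2
    shared <- qr.Q(qr(matrix(stats::rnorm(block * rank), block, rank)))
    shared <- shared / sqrt(2)
    M <- matrix(0, N, rank)
    M[seq_len(block), ] <- shared
    for (l in seq_len(rank)) {
      v <- stats::rnorm(block)
      v <- v / .l2(v) / sqrt(2)          # specific block, norm 2^-1/2
      M[l * block + seq_len(block), l] <- v
    }
    M
  }
  P_M <- build_factor(p_block)
  Q_M <- build_factor(q_block)
  structure(list(P_M = P_M, Q_M = Q_M, delta_M = delta_M,
                 noise_sd = noise_sd, p_block = as.integer(p_block),
                 q_block = as.integer(q_block), seed = as.integer(seed)),
            class = "csvd_ground_truth")
}

#' @export
print.csvd_ground_truth <- function(x, ...) {
  cat(sprintf("<ground truth: %d x %d, rank %d, noise sd %g, seed %d>\n",
              nrow(x$P_M), nrow(x$Q_M), length(x$delta_M), x$noise_sd, x$seed))
  invisible(x)
}

#' Simulate a noisy data matrix from a ground truth
#'
#' Returns `X = P_M %*% diag(delta_M) %*% t(Q_M) + E` where `E` has i.i.d.
#' Gaussian entries with mean 0 and standard deviation `gt$noise_sd`.
#'
#' @param gt A [make_ground_truth()] object.
#' @param seed Integer seed for the noise draw (default: `gt$seed + 1` so
#'   the noise is independent of the factor draws).
#' @return A numeric matrix (I x J).
#' @export
simulate_X <- function(gt, seed = gt$seed + 1L) {
  stopifnot(inherits(gt, "csvd_ground_truth"))
  X_M <- gt$P_M %*% (gt$delta_M * t(gt$Q_M))
  if (gt$noise_sd > 0) {
    set.seed(seed)
    X_M <- X_M + matrix(stats::rnorm(length(X_M), sd = gt$noise_sd),
                        nrow(X_M), ncol(X_M))
  }
  X_M
}

# Sign chosen to minimize the squared error against the reference vector.
.align_sign <- function(est, ref) {
  if (sum(est * ref) < 0) -est else est
}

#' Elementwise squared error of estimated singular vectors vs the truth
#'
#' For each of the first `min(5, R)` components, the elementwise squared
#' differences between the estimated and true singular vectors after
#' optimal sign alignment (the sign of each estimated vector is chosen to
#' minimize its error).
#'
#' @param est A `csvd_decomposition`.
#' @param gt A [make_ground_truth()] object.
#' @return A list with matrices `p` (I x L) and `q` (J x L) of squared
#'   differences, L = `min(ncol(gt$P_M), ncol(est$P))`.
#' @export
squared_error_to_truth <- function(est, gt) {
  stopifnot(inherits(gt, "csvd_ground_truth"))
  L <- min(ncol(gt$P_M), ncol(est$P))
  sq <- function(E, M) {
    vapply(seq_len(L),
           function(l) (.align_sign(E[, l], M[, l]) - M[, l])^2,
           numeric(nrow(M)))
  }
  list(p = sq(est$P, gt$P_M), q = sq(est$Q, gt$Q_M))
}

#' Correlations of estimated singular vectors with the truth
#'
#' Pearson correlation of every estimated vector with every true vector,
#' for the left and right sides separately.  Rows index the truth, columns
#' the estimates.  Estimated vectors with zero variance (e.g. a failed
#' component) yield `NA` entries with a warning.
#'
#' @inheritParams squared_error_to_truth
#' @return A list of two matrices `p` and `q`, each `rank x R`.
#' @export
correlation_to_truth <- function(est, gt) {
  stopifnot(inherits(gt, "csvd_ground_truth"))
  corr <- function(E, M) {
    out <- matrix(NA_real_, ncol(M), ncol(E))
    for (l in seq_len(ncol(M))) for (r in seq_len(ncol(E))) {
      if (stats::sd(E[, r]) == 0 || stats::sd(M[, l]) == 0) {
        warning("zero-variance vector: correlation undefined, set to NA")
      } else {
        out[l, r] <- stats::cor(M[, l], E[, r])
      }
    }
    out
  }
  list(p = corr(est$P, gt$P_M), q = corr(est$Q, gt$Q_M))
}

#' Cross-product matrix of a set of component vectors
#'
#' `t(V) %*% V`: the identity for orthonormal components; off-diagonal
#' structure reveals non-orthogonal (correlated) components.
#'
#' @param V Matrix whose columns are component vectors.
#' @return The R x R cross-product matrix.
#' @export
crossprod_matrix <- function(V) {
  crossprod(as.matrix(V))
}

#' Pseudo-eigenvalues: variance of the factor scores
#'
#' For each component, the population variance (denominator I) of the
#' factor scores `X %*% q_l` -- the scree-plot quantity for sparse
#' components.  For plain SVD vectors on a column-centered matrix this is
#' `delta_l^2 / I`.
#'
#' @param X The data matrix.
#' @param Q Matrix of right (pseudo-)singular vectors, one per column.
#' @return Numeric vector of length `ncol(Q)`.
#' @export
pseudo_eigenvalues <- function(X, Q) {
  FS <- X %*% as.matrix(Q)
  colMeans(FS^2) - colMeans(FS)^2
}
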