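# Unconstrained SVD by power iteration: deflation variant and the
# orthocomplement-projection (POCS) variant.  Both serve as baselines and as
# the no-sparsity limit of the constrained decomposition.

.unit <- function(x) {
  n <- .l2(x)
  if (n == 0) stop("cannot normalize the zero vector")
  x / n
}

# Flip signs so the largest-magnitude entry of q is positive; p flips with it
# so the singular value is unchanged.  Makes results deterministic despite
# the inherent sign indeterminacy of singular vectors.
.sign_fix <- function(p, q) {
  if (q[which.max(abs(q))] < 0) list(p = -p, q = -q) else list(p = p, q = q)
}

# One leading singular triplet of X by plain power iteration.
# init: "random" draws q0 ~ N(0, I) (caller controls the RNG state);
# "warmstart" uses the column of X with the largest norm, a deterministic
# start that needs no seed.
.power_triplet <- function(X, eps = 1e-9, max_iter = 10000L, init = "random") {
  I <- nrow(X); J <- ncol(X)
  if (init == "warmstart") {
    col_norms <- sqrt(colSums(X^2))
    jmax <- which.max(col_norms)
    if (col_norms[jmax] < 1e-300)
      return(list(delta = 0, p = numeric(I), q = numeric(J),
                  iterations = 0L, converged = TRUE, degenerate = TRUE))
    p <- X[, jmax] / col_norms[jmax]
    q <- .unit(crossprod(X, p))
  } else {
    q <- .unit(stats::rnorm(J))
  }
  delta <- 0
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    v <- X %*% q
    nv <- .l2(v)
    if (nv < 1e-300)
      return(list(delta = 0, p = numeric(I), q = numeric(J),
                  iterations = iter, converged = TRUE, degenerate = TRUE))
    p <- drop(v) / nv
    z <- crossprod(X, p)
    delta_new <- .l2(z)           # equals p' X q for the updated q
    q <- drop(z) / delta_new
    if (abs(delta_new - delta) < eps) {
      delta <- delta_new
      converged <- TRUE
      break
    }
    delta <- delta_new
    if (iter >= max_iter) break
  }
  s <- .sign_fix(p, q)
  list(delta = delta, p = s$p, q = s$q, iterations = iter,
       converged = converged, degenerate = FALSE)
}

.new_decomposition <- function(P, Q, delta, iterations, converged, method,
                               trace = NULL, plan = NULL) {
  structure(list(P = P, Q = Q, delta = delta, iterations = iterations,
                 converged = converged, method = method, trace = trace,
                 plan = plan),
            class = "csvd_decomposition")
}

#' @export
print.csvd_decomposition <- function(x, ...) {
  cat(sprintf("<%s decomposition: %d x %d, %d component(s)>\n",
              x$method, nrow(x$P), nrow(x$Q), length(x$delta)))
  cat("  delta:", paste(formatC(x$delta, digits = 4, format = "fg"), collapse = " "), "\n")
  cat("  converged:", paste(x$converged, collapse = " "), "\n")
  invisible(x)
}

.check_rank <- function(X, R) {
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric matrix")
  if (length(R) != 1L || R < 1 || R != round(R)) stop("`R` must be a positive integer")
  if (R > min(dim(X)))
    stop("`R` = ", R, " exceeds min(I, J) = ", min(dim(X)))
  invisible(R)
}

#' Power-iteration SVD with deflation
#'
#' Extracts `R` singular triplets of `X` one at a time: each inner loop
#' alternates `p <- normalize(X q)` and `q <- normalize(t(X) p)` until the
#' singular-value estimate `delta = p' X q` stabilizes to within `eps`, then
#' deflates `X <- X - delta p q'` so the next iteration finds the next
#' triplet.  Successive triplets of the deflated matrices are exactly the
#' successive triplets of `X` (the deflation theorem), so the columns of `P`
#' and `Q` come out orthonormal and `delta` non-increasing.
#'
#' @param X Numeric matrix (I x J).
#' @param R Number of components, at most `min(I, J)`.
#' @param eps Convergence threshold on `|delta_change|` (default 1e-9).
#' @param max_iter Maximum inner iterations per component (default 10000).
#' @param seed Integer seed for the random initialization (required for
#'   reproducibility; ignored for `init = "warmstart"`).
#' @param init `"random"` (seeded normalized Gaussian start, the default) or
#'   `"warmstart"` (deterministic start from the largest-norm column of `X`).
#' @return A `csvd_decomposition`: `P` (I x R), `Q` (J x R), `delta`
#'   (length R, non-increasing), plus per-component `iterations` and
#'   `converged` flags.
#' @export
power_svd_deflate <- function(X, R, eps = 1e-9, max_iter = 10000L,
                              seed = 1L, init = c("random", "warmstart")) {
  init <- match.arg(init)
  .check_rank(X, R)
  if (init == "random") set.seed(seed)
  I <- nrow(X); J <- ncol(X)
  P <- matrix(0, I, R); Q <- matrix(0, J, R)
  delta <- numeric(R); iters <- integer(R); conv <- logical(R)
  Xd <- X
  for (l in seq_len(R)) {
    tr <- .power_triplet(Xd, eps = eps, max_iter = max_iter, init = init)
    P[, l] <- tr$p; Q[, l] <- tr$q; delta[l] <- tr$delta
    iters[l] <- tr$iterations; conv[l] <- tr$converged
    Xd <- Xd - tr$delta * tcrossprod(tr$p, tr$q)
  }
  .new_decomposition(P, Q, delta, iters, conv, "svd")
}

#' Power-iteration SVD via projection onto orthogonal complements
#'
#' Same contract as [power_svd_deflate()], but instead of deflating `X`,
#' orthogonality to the previously found vectors is enforced inside the
#' power iteration: each update is projected onto
#' \eqn{B_{L_2}(1) \cap P^\perp} (resp. \eqn{Q^\perp}).  For the first
#' component the orthogonality constraint is inactive (the basis is empty)
#' and the update reduces to pure power iteration.  On matrices with
#' distinct singular values the result equals the deflation variant up to
#' sign.  This is the no-sparsity limit of the constrained decomposition.
#'
#' @inheritParams power_svd_deflate
#' @return A `csvd_decomposition` (method `"svd"`).
#' @export
power_svd_pocs <- function(X, R, eps = 1e-9, max_iter = 10000L,
                           seed = 1L, init = c("random", "warmstart")) {
  init <- match.arg(init)
  .check_rank(X, R)
  if (init == "random") set.seed(seed)
  I <- nrow(X); J <- ncol(X)
  P <- matrix(0, I, 0); Q <- matrix(0, J, 0)
  delta <- numeric(R); iters <- integer(R); conv <- logical(R)
  for (l in seq_len(R)) {
    res <- .constrained_triplet(X, c1 = NULL, c2 = NULL,
                                P_basis = P, Q_basis = Q,
                                eps = eps, max_iter = max_iter, init = init)
    P <- cbind(P, res$p); Q <- cbind(Q, res$q)
    delta[l] <- res$delta; iters[l] <- res$iterations; conv[l] <- res$converged
  }
  .new_decomposition(P, Q, delta, iters, conv, "svd")
}

# Projection onto B_L1(c) n B_L2-boundary n span(basis)-complement.
# c = NULL drops the L1 constraint (unconstrained SVD case).  Cycles
# orthocomplement projection with the exact L1/L2 operator, then finishes
# with an orthocomplement sweep and renormalization so the returned vector
# is orthogonal to machine precision.  Signals condition class
# "csvd_collapse" if the iterate collapses toward zero (sparsity
# incompatible with orthogonality).
.proj_intersect <- function(x, c = NULL, basis = NULL,
                            eps = 1e-8, max_iter = 1000L) {
  .ball <- function(v) {
    n <- .l2(v)
    if (n < 1e-12)
      stop(structure(class = c("csvd_collapse", "error", "condition"),
                     list(message = "iterate collapsed to (near-)zero vector",
                          call = NULL)))
    if (is.null(c)) v / n else proj_l1l2(v, c)
  }
  if (is.null(basis) || NCOL(basis) == 0L) return(.ball(x))
  y <- x
  iter <- 0L
  repeat {
    iter <- iter + 1L
    y_new <- .ball(proj_ortho(y, basis))
    if (.l2(y_new - y) < eps || iter >= max_iter) {
      y <- y_new
      break
    }
    y <- y_new
  }
  # final word to orthogonality, then back to the unit sphere
  y <- proj_ortho(y, basis)
  n <- .l2(y)
  if (n < 1e-12)
    stop(structure(class = c("csvd_collapse", "error", "condition"),
                   list(message = "iterate collapsed to (near-)zero vector",
                        call = NULL)))
  y / n
}

# One constrained (or unconstrained, c = NULL) triplet with orthogonality to
# the columns of P_basis / Q_basis, by block relaxation.  Warm start: leading
# power-iteration triplet of the doubly projected matrix; falls back to a
# random start (caller seeds the RNG) if that is degenerate.
.constrained_triplet <- function(X, c1, c2, P_basis, Q_basis,
                                 eps = 1e-9, max_iter = 10000L,
                                 pocs_eps = 1e-8, pocs_max_iter = 1000L,
                                 init = "warmstart") {
  J <- ncol(X)
  q <- NULL
  if (init == "warmstart") {
    M <- X
    if (NCOL(P_basis) > 0L) M <- M - P_basis %*% crossprod(P_basis, M)
    if (NCOL(Q_basis) > 0L) M <- M - (M %*% Q_basis) %*% t(Q_basis)
    tr0 <- .power_triplet(M, eps = max(eps, 1e-6), max_iter = 1000L,
                          init = "warmstart")
    if (!tr0$degenerate && tr0$delta > 1e-12) q <- tr0$q
  }
  if (is.null(q)) {
    q <- proj_ortho(stats::rnorm(J), Q_basis)
    q <- .unit(q)
  }
  delta <- NA_real_
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  p <- NULL
  repeat {
    iter <- iter + 1L
    a <- drop(X %*% q)
    p_new <- .proj_intersect(a, c1, P_basis, pocs_eps, pocs_max_iter)
    # monotone safeguard: the POCS point is feasible but not the exact block
    # maximizer, so it can (rarely, slightly) decrease the objective; keep
    # the previous feasible iterate in that case so ascent is guaranteed
    if (!is.null(p) && sum(p_new * a) < sum(p * a)) p_new <- p
    p <- p_new
    w <- drop(crossprod(X, p))
    q_new <- .proj_intersect(w, c2, Q_basis, pocs_eps, pocs_max_iter)
    if (iter > 1L && sum(q_new * w) < sum(q * w)) q_new <- q
    q <- q_new
    delta_new <- sum(w * q)
    trace <- c(trace, delta_new)
    if (!is.na(delta) && abs(delta_new - delta) < eps) {
      delta <- delta_new
      converged <- TRUE
      break
    }
    delta <- delta_new
    if (iter >= max_iter) break
  }
  if (delta < 0) {   # flip q rather than clamping
    q <- -q
    delta <- -delta
  }
  s <- .sign_fix(p, q)
  list(delta = delta, p = s$p, q = s$q, iterations = iter,
       converged = converged, trace = trace)
}
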