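# Penalized matrix decomposition (Witten, Tibshirani & Hastie): sparse
# rank-one fits with deflation.  Sparse like the constrained SVD, but with
# no orthogonality guarantee across components -- it is the comparison
# baseline whose late components correlate with earlier ones.

# Smallest soft-threshold lambda such that the normalized thresholded
# vector has L1 norm c; 0 if the unthresholded normalized vector already
# satisfies the bound.  g(lambda) = ||normalize(S(v, lambda))||_1 is
# decreasing in lambda, so plain bisection on [0, max|v|] suffices.
.pmd_lambda <- function(v, c, iter = 100L, width = 1e-12) {
  g <- function(lam) {
    s <- soft_threshold_vec(v, lam)
    n <- .l2(s)
    if (n == 0) 1 else sum(abs(s)) / n    # limit toward the tied maxima
  }
  if (g(0) <= c) return(0)
  lo <- 0
  hi <- max(abs(v))
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > c) lo <- mid else hi <- mid
    if (hi - lo < width) break
  }
  (lo + hi) / 2
}

#' Penalized matrix decomposition (PMD)
#'
#' Deflation-based sparse SVD: for each component, alternate
#' `p <- normalize(S(X q, lambda1))` with `lambda1` chosen (by bisection) so
#' that `l1norm(p) = c1`, and symmetrically for `q`, until
#' `delta = p' X q` stabilizes; then deflate `X <- X - delta p q'` and
#' repeat.  Components are unit-norm and L1-feasible, but -- because the
#' thresholded updates make the deflated matrices non-orthogonal to the
#' earlier rank-one terms -- there is NO orthogonality guarantee: components
#' extracted beyond the true rank of the signal are typically correlated
#' with earlier ones.  Compare [csvd()], which enforces orthogonality as an
#' explicit constraint.
#'
#' The L1 constraint is treated as an inequality: when the normalized
#' unthresholded update already satisfies the bound, `lambda = 0` is used.
#'
#' @inheritParams csvd
#' @return A `csvd_decomposition` (method `"pmd"`) with per-component
#'   objective traces.
#' @export
pmd <- function(X, R, c1 = NULL, c2 = NULL, level = NULL, plan = NULL,
                eps = 1e-9, max_iter = 10000L,
                seed = 1L, init = c("warmstart", "random")) {
  init <- match.arg(init)
  .check_rank(X, R)
  I <- nrow(X); J <- ncol(X)
  if (is.null(plan)) plan <- sparsity_plan(I, J, c1 = c1, c2 = c2, level = level)
  if (!inherits(plan, "sparsity_plan")) stop("`plan` must be a sparsity_plan")
  c1v <- rep_len(plan$c1, R)
  c2v <- rep_len(plan$c2, R)
  set.seed(seed)
  P <- matrix(0, I, R); Q <- matrix(0, J, R)
  delta <- numeric(R); iters <- integer(R); conv <- logical(R)
  traces <- list()
  Xd <- X
  for (l in seq_len(R)) {
    if (init == "warmstart") {
      tr0 <- .power_triplet(Xd, eps = 1e-6, max_iter = 1000L, init = "warmstart")
      q <- if (!tr0$degenerate && tr0$delta > 1e-12) tr0$q else .unit(stats::rnorm(J))
    } else {
      q <- .unit(stats::rnorm(J))
    }
    d <- NA_real_
    trace <- numeric(0)
    iter <- 0L
    cv <- FALSE
    repeat {
      iter <- iter + 1L
      v <- drop(Xd %*% q)
      p <- .unit(soft_threshold_vec(v, .pmd_lambda(v, c1v[l])))
      w <- drop(crossprod(Xd, p))
      q <- .unit(soft_threshold_vec(w, .pmd_lambda(w, c2v[l])))
      d_new <- sum(p * (Xd %*% q))
      trace <- c(trace, d_new)
      if (!is.na(d) && abs(d_new - d) < eps) {
        d <- d_new
        cv <- TRUE
        break
      }
      d <- d_new
      if (iter >= max_iter) break
    }
    if (d < 0) {
      q <- -q
      d <- -d
    }
    s <- .sign_fix(p, q)
    P[, l] <- s$p; Q[, l] <- s$q
    delta[l] <- d; iters[l] <- iter; conv[l] <- cv
    traces[[l]] <- trace
    Xd <- Xd - d * tcrossprod(s$p, s$q)
  }
  .new_decomposition(P, Q, delta, iters, conv, "pmd",
                     trace = traces, plan = plan)
}
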