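# Projection operators: soft-thresholding, L1/L2 balls, orthogonal
# complements, and projection onto intersections of convex sets (POCS).
# These are the numerical kernel consumed by the SVD/CSVD/PMD engines.

#' Scalar soft-thresholding
#'
#' Shrinks a scalar toward zero by `gamma`, mapping anything of magnitude
#' at most `gamma` to exactly zero:
#' \deqn{s(x, \gamma) = \mathrm{sign}(x)\,\max(|x| - \gamma, 0).}
#'
#' @param x A single real number.
#' @param gamma Non-negative shrinkage threshold.
#' @return The soft-thresholded scalar.
#' @seealso [soft_threshold_vec()] for the elementwise vector version.
#' @export
#' @examples
#' soft_threshold(2, 0.5)   # 1.5
#' soft_threshold(-0.3, 0.5) # 0
soft_threshold <- function(x, gamma) {
  if (length(x) != 1L) stop("`x` must be a single number; use soft_threshold_vec() for vectors")
  .check_gamma(gamma)
  sign(x) * max(abs(x) - gamma, 0)
}

#' Vector soft-thresholding
#'
#' Applies [soft_threshold()] elementwise: every component is shrunk toward
#' zero by `gamma` and components of magnitude at most `gamma` are zeroed.
#'
#' @param x Real vector.
#' @param gamma Non-negative shrinkage threshold.
#' @return Vector of the same length as `x`.
#' @export
soft_threshold_vec <- function(x, gamma) {
  .check_gamma(gamma)
  sign(x) * pmax(abs(x) - gamma, 0)
}

.check_gamma <- function(gamma) {
  if (length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop("`gamma` must be a single non-negative number")
  invisible(gamma)
}

.l2 <- function(x) sqrt(sum(x^2))
.l1 <- function(x) sum(abs(x))

#' Projection onto an L2 ball
#'
#' Euclidean projection onto \eqn{B_{L_2}(\rho) = \{y : \|y\|_2 \le \rho\}}:
#' points inside the ball are returned unchanged, points outside are scaled
#' radially onto the boundary.
#'
#' @param x Real vector.
#' @param rho Positive ball radius (default 1).
#' @return Vector with `l2norm(result) <= rho`.
#' @export
proj_l2 <- function(x, rho = 1) {
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("`rho` must be a single positive number")
  nrm <- .l2(x)
  if (nrm <= rho) x else x * (rho / nrm)
}

#' Projection onto an L1 ball
#'
#' Euclidean projection onto \eqn{B_{L_1}(c) = \{y : \|y\|_1 \le c\}} by the
#' sorted-magnitude root of the piecewise-linear map
#' \eqn{\phi(\lambda) = \|S(x,\lambda)\|_1}: if \eqn{\|x\|_1 \le c} the input
#' is already feasible; otherwise the unique threshold \eqn{\lambda} with
#' \eqn{\phi(\lambda) = c} is located exactly on the sorted magnitudes (no
#' bisection) and the soft-thresholded vector is returned.  The sign pattern
#' of the surviving entries is preserved.
#'
#' @param x Real vector.
#' @param c Positive L1 radius.
#' @return Vector with L1 norm `min(l1norm(x), c)`.
#' @export
proj_l1 <- function(x, c) {
  if (length(c) != 1L || !is.finite(c) || c <= 0)
    stop("`c` must be a single positive number")
  if (.l1(x) <= c) return(x)
  xt <- sort(abs(x), decreasing = TRUE)
  i_seq <- seq_along(xt)
  # phi(xt_i) = sum_{j<=i} (xt_j - xt_i), non-decreasing in i, phi(xt_1) = 0
  phi <- cumsum(xt) - i_seq * xt
  i <- max(which(phi <= c))
  lambda <- xt[i] - (c - phi[i]) / i
  sign(x) * pmax(abs(x) - lambda, 0)
}

#' L1/L2 norm ratio of a soft-thresholded magnitude vector
#'
#' For a magnitude-sorted vector \eqn{\tilde x} (absolute values, decreasing)
#' and a threshold \eqn{\lambda \in [0, \tilde x_1)}, returns
#' \deqn{\psi(\lambda) = \|S(\tilde x, \lambda)\|_1 / \|S(\tilde x, \lambda)\|_2.}
#' \eqn{\psi} is continuous and non-increasing on \eqn{[0, \tilde x_1)},
#' falling from \eqn{\|x\|_1/\|x\|_2} at 0 to \eqn{\sqrt{N_{\max}}} (the
#' square root of the number of tied maxima) as \eqn{\lambda \to \tilde x_1}.
#' Its root is what makes the exact L1-and-L2 ball projection
#' ([proj_l1l2()]) a sort-and-solve rather than an iterative problem.
#'
#' @param x_sorted Non-negative vector sorted in decreasing order.
#' @param lam Threshold in `[0, x_sorted[1])`.
#' @return The norm ratio, a value in `[1, sqrt(length(x_sorted))]`.
#' @export
psi <- function(x_sorted, lam) {
  if (length(x_sorted) == 0L || any(x_sorted < 0))
    stop("`x_sorted` must be a non-empty non-negative vector")
  if (is.unsorted(rev(x_sorted))) stop("`x_sorted` must be sorted in decreasing order")
  if (length(lam) != 1L || !is.finite(lam) || lam < 0 || lam >= x_sorted[1])
    stop("`lam` must lie in [0, x_sorted[1]): the denominator vanishes at and beyond the maximum")
  s <- pmax(x_sorted - lam, 0)
  sum(s) / .l2(s)
}

#' Exact projection onto the intersection of an L1 ball and the unit L2 sphere
#'
#' The constrained power-iteration update: the point of
#' \eqn{B_{L_1}(c) \cap B_{L_2}(1)} closest to `x`, rescaled to the unit L2
#' boundary.  If \eqn{\|x\|_1/\|x\|_2 \le c} the L1 constraint is inactive and
#' the result is simply `x / l2norm(x)`.  Otherwise the unique threshold
#' \eqn{\lambda} with \eqn{\psi(\lambda) = c} is found exactly: the index
#' \eqn{i} with \eqn{\psi(\tilde x_i) \le c < \psi(\tilde x_{i+1})} is located
#' on the sorted magnitudes and the offset \eqn{\delta} solves a quadratic,
#' \deqn{\delta = \frac{\|S(\tilde x,\tilde x_i)\|_2}{i}
#'   \left(c\sqrt{\frac{i-\psi(\tilde x_i)^2}{i-c^2}} - \psi(\tilde x_i)\right),}
#' after which \eqn{S(x, \tilde x_i - \delta)} is rescaled to unit norm.  The
#' output has `l2norm = 1` exactly and `l1norm = c` (to ~1e-8) whenever the L1
#' constraint is active.
#'
#' When `x` has more tied maxima than the budget `c` allows
#' (\eqn{c < \sqrt{N_{\max}}}), no threshold attains the ratio `c`; the
#' limiting vector supported on the tied maxima is returned with a warning.
#'
#' @param x Non-zero real vector of length N.
#' @param c Sparsity radius in `[1, sqrt(N)]`.
#' @return Unit-L2 vector satisfying the L1 bound.
#' @export
proj_l1l2 <- function(x, c) {
  N <- length(x)
  if (length(c) != 1L || !is.finite(c) || c < 1 || c > sqrt(N) + 1e-12)
    stop("`c` must lie in [1, sqrt(length(x))] = [1, ", format(sqrt(N)), "]")
  l2 <- .l2(x)
  if (l2 == 0) stop("proj_l1l2: degenerate all-zero input (sparsity and orthogonality constraints may be incompatible)")
  if (.l1(x) / l2 <= c) return(x / l2)
  xt <- sort(abs(x), decreasing = TRUE)
  i_seq <- seq_len(N)
  ell1 <- cumsum(xt) - i_seq * xt                      # ||S(xt, xt_i)||_1
  ell2sq <- cumsum(xt^2) - 2 * xt * cumsum(xt) + i_seq * xt^2
  ell2sq <- pmax(ell2sq, 0)                            # guard tiny negatives
  psi_i <- ifelse(ell2sq > 0, ell1 / sqrt(ell2sq), NA_real_)
  ok <- which(!is.na(psi_i) & psi_i <= c)
  if (length(ok) == 0L) {
    # c below sqrt(#tied maxima): psi never reaches down to c.  Return the
    # limiting vector supported on the tied maxima (lambda -> xt_1 from below).
    top <- which(abs(x) == max(abs(x)))
    warning("proj_l1l2: c = ", format(c), " is below sqrt(number of tied maxima) = ",
            format(sqrt(length(top))), "; returning the limiting vector on the tied maxima")
    y <- numeric(N)
    y[top] <- sign(x[top]) / sqrt(length(top))
    return(y)
  }
  i <- max(ok)
  psi_v <- psi_i[i]
  # positive root of the quadratic delta^2 (i^2 - i c^2) + 2 delta l1 (i - c^2)
  #   + l1^2 - c^2 l2^2 = 0, expressed via psi = l1/l2
  denom <- max(i - c^2, .Machine$double.eps)
  delta <- (sqrt(ell2sq[i]) / i) * (c * sqrt(max(i - psi_v^2, 0) / denom) - psi_v)
  lambda <- xt[i] - delta
  y <- sign(x) * pmax(abs(x) - lambda, 0)
  y / .l2(y)
}

#' Projection onto the orthogonal complement of a subspace
#'
#' Removes from `x` its component in the span of the columns of `basis`:
#' `x - basis %*% (t(basis) %*% x)`.  The basis columns must be orthonormal
#' (an empty or `NULL` basis stands for the zero subspace, whose orthogonal
#' complement is the whole space).
#'
#' @param x Real vector.
#' @param basis Matrix with orthonormal columns (or `NULL` / zero columns).
#' @return Vector orthogonal to every column of `basis`.
#' @export
proj_ortho <- function(x, basis = NULL) {
  if (is.null(basis) || NCOL(basis) == 0L) return(x)
  basis <- as.matrix(basis)
  if (nrow(basis) != length(x))
    stop("dimension mismatch: length(x) = ", length(x), " but nrow(basis) = ", nrow(basis))
  gram <- crossprod(basis)
  if (max(abs(gram - diag(ncol(basis)))) > 1e-8)
    stop("`basis` columns must be orthonormal")
  drop(x - basis %*% crossprod(basis, x))
}

#' Describe one convex constraint region
#'
#' Bundles up to three convex constraints into one feasible region: an L1
#' ball, an L2 ball, and the orthogonal complement of the span of
#' `ortho_basis`.  Each constraint is optional; [project()] dispatches to the
#' exact projector for the active combination (orthocomplement first, then
#' the exact joint L1-and-L2 ball projection when both balls are present).
#'
#' @param l1_radius Positive L1 radius, or `NULL`.
#' @param l2_radius Positive L2 radius, or `NULL`.
#' @param ortho_basis Matrix with orthonormal columns, or `NULL`.
#' @return An object of class `"constraint_set"`.
#' @export
constraint_set <- function(l1_radius = NULL, l2_radius = NULL, ortho_basis = NULL) {
  if (!is.null(l1_radius) && (length(l1_radius) != 1L || !is.finite(l1_radius) || l1_radius <= 0))
    stop("`l1_radius` must be a single positive number or NULL")
  if (!is.null(l2_radius) && (length(l2_radius) != 1L || !is.finite(l2_radius) || l2_radius <= 0))
    stop("`l2_radius` must be a single positive number or NULL")
  if (!is.null(ortho_basis)) {
    ortho_basis <- as.matrix(ortho_basis)
    if (ncol(ortho_basis) > 0L) {
      gram <- crossprod(ortho_basis)
      if (max(abs(gram - diag(ncol(ortho_basis)))) > 1e-10)
        stop("`ortho_basis` columns must be orthonormal (to 1e-10)")
    }
  }
  structure(list(l1_radius = l1_radius, l2_radius = l2_radius,
                 ortho_basis = ortho_basis),
            class = "constraint_set")
}

#' Project a vector onto a constraint set
#'
#' @param set A [constraint_set()].
#' @param x Real vector.
#' @return The projected vector.
#' @export
project <- function(set, x) UseMethod("project")

#' @export
project.constraint_set <- function(set, x) {
  y <- proj_ortho(x, set$ortho_basis)
  has_l1 <- !is.null(set$l1_radius)
  has_l2 <- !is.null(set$l2_radius)
  if (has_l1 && has_l2) {
    y <- .proj_l1l2_ball(y, set$l1_radius, set$l2_radius)
  } else if (has_l2) {
    y <- proj_l2(y, set$l2_radius)
  } else if (has_l1) {
    y <- proj_l1(y, set$l1_radius)
  }
  y
}

# Euclidean projection onto B_L1(c) n B_L2(rho); interior points unchanged.
.proj_l1l2_ball <- function(x, c, rho) {
  if (.l1(x) <= c) return(proj_l2(x, rho))
  z <- proj_l2(x, rho)
  if (.l1(z) <= c) return(z)
  # both constraints active: threshold so that the norm ratio equals c/rho,
  # then place the result on the L2 boundary
  rho * proj_l1l2(x, min(c / rho, sqrt(length(x))))
}

.residual <- function(set, x) {
  r <- 0
  if (!is.null(set$l1_radius)) r <- max(r, .l1(x) - set$l1_radius)
  if (!is.null(set$l2_radius)) r <- max(r, .l2(x) - set$l2_radius)
  if (!is.null(set$ortho_basis) && NCOL(set$ortho_basis) > 0L)
    r <- max(r, max(abs(crossprod(as.matrix(set$ortho_basis), x))))
  r
}

#' Projection onto an intersection of convex sets (POCS)
#'
#' Cyclically projects onto each set in turn until the L2 norm of the change
#' over a full sweep drops below `eps` or `max_iter` sweeps are exhausted.
#' The returned point is feasible for every set (to within `10 * eps`), but
#' is in general a feasible point rather than the exact Euclidean projection
#' onto the intersection; when the intersection is exactly
#' \eqn{B_{L_1}(c) \cap B_{L_2}(1)}, use [proj_l1l2()] instead, which is
#' exact and non-iterative.
#'
#' @param x Real vector.
#' @param sets List of [constraint_set()] objects (or bare projector
#'   functions taking and returning a vector).
#' @param eps Positive convergence threshold on the iterate change
#'   (default 1e-8).
#' @param max_iter Maximum number of sweeps (default 1000).
#' @return The final iterate, with attributes `iterations` (sweeps used) and
#'   `converged`.  A warning is raised if `max_iter` is exhausted.
#' @export
pocs <- function(x, sets, eps = 1e-8, max_iter = 1000L) {
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0) stop("`eps` must be positive")
  if (!is.list(sets) || length(sets) == 0L) stop("`sets` must be a non-empty list")
  projectors <- lapply(sets, function(s) {
    if (is.function(s)) s
    else if (inherits(s, "constraint_set")) function(v) project(s, v)
    else stop("each element of `sets` must be a constraint_set or a function")
  })
  y <- x
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    y_prev <- y
    for (pr in projectors) y <- pr(y)
    if (.l2(y - y_prev) < eps) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("pocs: not converged after ", max_iter, " sweeps (last change ",
            format(.l2(y - y_prev)), ")")
  attr(y, "iterations") <- iter
  attr(y, "converged") <- converged
  y
}
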