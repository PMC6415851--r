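# The constrained SVD: rank-R sparse decomposition with simultaneous L1,
# unit-L2, and mutual-orthogonality constraints on both the left and right
# pseudo-singular vectors.

#' Constrained singular value decomposition
#'
#' Rank-`R` sparse decomposition of `X` in which every left pseudo-singular
#' vector lies in \eqn{B_{L_1}(c_{1,\ell}) \cap B_{L_2}(1) \cap P^\perp} and
#' every right vector in \eqn{B_{L_1}(c_{2,\ell}) \cap B_{L_2}(1) \cap
#' Q^\perp}, where \eqn{P^\perp} / \eqn{Q^\perp} are the orthogonal
#' complements of the previously extracted vectors.  For each component the
#' algorithm alternates
#' \deqn{p \leftarrow \mathrm{proj}(Xq,\; B_{L_1}(c_1)\cap B_{L_2}(1)\cap P^\perp),
#'   \qquad q \leftarrow \mathrm{proj}(X^\top p,\; B_{L_1}(c_2)\cap B_{L_2}(1)\cap Q^\perp)}
#' until the pseudo-singular value \eqn{\delta = p^\top X q} stabilizes.
#' Each intersection projection cycles the exact L1/L2-ball operator
#' ([proj_l1l2()]) with the orthocomplement projection and finishes with an
#' orthocomplement sweep plus renormalization, so the reported vectors are
#' orthogonal to machine precision while satisfying the L1 bound to
#' tolerance.  This is a block-relaxation scheme (an instance of block
#' successive upper-bound minimization), so the objective trace is
#' non-decreasing and the iteration converges to a stationary point.
#'
#' Unlike deflation-based sparse decompositions (see [pmd()]), components
#' beyond the true rank remain orthogonal to all earlier components.
#'
#' @param X Numeric matrix (I x J).
#' @param R Number of components, at most `min(I, J)`.
#' @param c1,c2 L1 radii for the left/right vectors; scalars are broadcast
#'   to all `R` components.  Must lie in `[1, sqrt(I)]` / `[1, sqrt(J)]`.
#'   Ignored when `plan` is given.
#' @param level Optional symbolic sparsity level (`"H"`, `"M"`, `"L"`,
#'   `"N"`) applied to both sides instead of numeric radii.
#' @param plan A pre-built [sparsity_plan()]; overrides `c1`/`c2`/`level`.
#' @param eps Outer convergence threshold on `|delta_change|`
#'   (default 1e-9).
#' @param max_iter Maximum outer iterations per component (default 10000).
#' @param pocs_eps,pocs_max_iter Tolerance and iteration cap for the inner
#'   intersection projection (defaults 1e-8 and 1000).
#' @param seed Integer seed (used for the random fallback start).
#' @param init `"warmstart"` (default: deterministic start from the leading
#'   power-iteration triplet of the doubly projected matrix) or `"random"`.
#' @return A `csvd_decomposition` with unit-norm, pairwise-orthogonal,
#'   L1-feasible columns in `P` and `Q`, non-negative `delta`, per-component
#'   `iterations`/`converged` flags, and the per-component objective traces
#'   in `$trace`.  If a component collapses (its sparsity budget is
#'   incompatible with the orthogonality constraint) the decomposition is
#'   truncated there, with a warning identifying the component.
#' @export
#' @examples
#' X <- diag(c(3, 2, 1))
#' csvd(X, R = 2, c1 = sqrt(3), c2 = sqrt(3))$delta  # plain SVD limit
csvd <- function(X, R, c1 = NULL, c2 = NULL, level = NULL, plan = NULL,
                 eps = 1e-9, max_iter = 10000L,
                 pocs_eps = 1e-8, pocs_max_iter = 1000L,
                 seed = 1L, init = c("warmstart", "random")) {
  init <- match.arg(init)
  .check_rank(X, R)
  I <- nrow(X); J <- ncol(X)
  if (is.null(plan)) plan <- sparsity_plan(I, J, c1 = c1, c2 = c2, level = level)
  if (!inherits(plan, "sparsity_plan")) stop("`plan` must be a sparsity_plan")
  c1v <- rep_len(plan$c1, R)
  c2v <- rep_len(plan$c2, R)
  set.seed(seed)
  P <- matrix(0, I, 0); Q <- matrix(0, J, 0)
  delta <- numeric(0); iters <- integer(0); conv <- logical(0)
  traces <- list()
  for (l in seq_len(R)) {
    res <- tryCatch(
      .constrained_triplet(X, c1 = c1v[l], c2 = c2v[l],
                           P_basis = P, Q_basis = Q,
                           eps = eps, max_iter = max_iter,
                           pocs_eps = pocs_eps, pocs_max_iter = pocs_max_iter,
                           init = init),
      csvd_collapse = function(e) NULL)
    if (is.null(res)) {
      warning("csvd: component ", l, " collapsed (sparsity radius incompatible ",
              "with orthogonality to the previous components); decomposition ",
              "truncated to ", l - 1L, " component(s)")
      break
    }
    P <- cbind(P, res$p); Q <- cbind(Q, res$q)
    delta <- c(delta, res$delta)
    iters <- c(iters, res$iterations)
    conv <- c(conv, res$converged)
    traces[[l]] <- res$trace
  }
  out <- .new_decomposition(P, Q, delta, iters, conv, "csvd",
                            trace = traces, plan = plan)
  out
}
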