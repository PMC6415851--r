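# Sparsity radii: feasible range validation and the symbolic presets
# (H / M / L / N) used throughout the examples.

#' Map a symbolic sparsity level to an L1 radius
#'
#' The L1 radius of a unit-L2 N-vector can only lie in `[1, sqrt(N)]`
#' (Cauchy-Schwarz on both sides), so sparsity levels are expressed as
#' fractions of that range:
#' \describe{
#'   \item{H (High)}{`1 + eps` -- the sparsest level, most coefficients
#'     forced to (near) zero; the offset `eps` keeps the radius strictly
#'     inside the feasible range.}
#'   \item{M (Medium)}{`sqrt(N) / 3` -- very sparse.}
#'   \item{L (Low)}{`2 * sqrt(N) / 3` -- somewhat sparse.}
#'   \item{N (None)}{`sqrt(N)` -- no sparsity; recovers the regular SVD.}
#' }
#'
#' @param level One of `"H"`, `"M"`, `"L"`, `"N"`.
#' @param N Dimension of the vector being constrained (I for left vectors,
#'   J for right vectors); at least 2.
#' @param eps Small positive offset used for level `"H"` (default 0.01).
#' @return The L1 radius, a value in `[1, sqrt(N)]`.
#' @export
#' @examples
#' level_to_radius("M", 9)  # 1
#' level_to_radius("N", 9)  # 3
level_to_radius <- function(level, N, eps = 0.01) {
  if (length(N) != 1L || N < 2 || N != round(N)) stop("`N` must be an integer >= 2")
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0) stop("`eps` must be positive")
  switch(as.character(level),
         H = 1 + eps,
         M = sqrt(N) / 3,
         L = 2 * sqrt(N) / 3,
         N = sqrt(N),
         stop("unknown sparsity level '", level, "' (expected H, M, L or N)"))
}

#' Validate per-component sparsity radii
#'
#' A unit-L2 vector in `R^N` has L1 norm between 1 and `sqrt(N)`, so the L1
#' and L2 constraints can be simultaneously active only for radii in that
#' closed range; anything outside it is rejected with the offending
#' component named.  Radii sitting exactly on a bound are accepted with a
#' note (the upper bound means "no sparsity", the lower bound a single
#' surviving coefficient).
#'
#' @param c1 Left radii (recycled against `c2`); each in `[1, sqrt(I)]`.
#' @param c2 Right radii; each in `[1, sqrt(J)]`.
#' @param I,J Data matrix dimensions.
#' @param level_labels Optional character vector of symbolic levels the
#'   radii were derived from, kept for reporting.
#' @return An object of class `"sparsity_plan"` with fields `c1`, `c2`,
#'   `I`, `J`, `level_labels`.
#' @export
validate_sparsity <- function(c1, c2, I, J, level_labels = NULL) {
  if (length(c1) == 0L || length(c2) == 0L) stop("`c1` and `c2` must be non-empty")
  n <- max(length(c1), length(c2))
  c1 <- rep_len(as.numeric(c1), n)
  c2 <- rep_len(as.numeric(c2), n)
  .check_side <- function(cc, N, side) {
    bad <- which(!is.finite(cc) | cc < 1 | cc > sqrt(N) + 1e-12)
    if (length(bad))
      stop(sprintf("%s radius for component %d is %s, outside the feasible range [1, sqrt(%d)] = [1, %.4f]",
                   side, bad[1], format(cc[bad[1]]), N, sqrt(N)))
    at_bound <- which(cc == 1 | abs(cc - sqrt(N)) <= 1e-12)
    if (length(at_bound))
      message(sprintf("note: %s radius for component(s) %s sits on the feasible-range boundary",
                      side, paste(at_bound, collapse = ", ")))
    invisible(cc)
  }
  .check_side(c1, I, "left (c1)")
  .check_side(c2, J, "right (c2)")
  structure(list(c1 = c1, c2 = c2, I = I, J = J, level_labels = level_labels),
            class = "sparsity_plan")
}

#' Build a sparsity plan from radii or symbolic levels
#'
#' Convenience constructor: either give numeric radii `c1`/`c2` (scalars are
#' broadcast across components by the decomposition engines) or a symbolic
#' `level` in `{H, M, L, N}` that is mapped to radii on both sides via
#' [level_to_radius()].
#'
#' @param I,J Data matrix dimensions.
#' @param c1,c2 Numeric radii (ignored when `level` is given).
#' @param level Optional symbolic level applied to both sides.
#' @param eps1,eps2 Offsets for the `"H"` level on the left/right side.
#' @return A validated `"sparsity_plan"`.
#' @export
sparsity_plan <- function(I, J, c1 = NULL, c2 = NULL, level = NULL,
                          eps1 = 0.01, eps2 = 0.01) {
  if (!is.null(level)) {
    c1 <- vapply(level, level_to_radius, numeric(1), N = I, eps = eps1)
    c2 <- vapply(level, level_to_radius, numeric(1), N = J, eps = eps2)
    return(validate_sparsity(c1, c2, I, J, level_labels = as.character(level)))
  }
  if (is.null(c1) || is.null(c2))
    stop("give either numeric radii `c1` and `c2`, or a symbolic `level`")
  validate_sparsity(c1, c2, I, J)
}

#' @export
print.sparsity_plan <- function(x, ...) {
  cat(sprintf("<sparsity plan for a %d x %d matrix>\n", x$I, x$J))
  cat("  c1:", paste(formatC(x$c1, digits = 4, format = "fg"), collapse = " "), "\n")
  cat("  c2:", paste(formatC(x$c2, digits = 4, format = "fg"), collapse = " "), "\n")
  if (!is.null(x$level_labels))
    cat("  levels:", paste(x$level_labels, collapse = " "), "\n")
  invisible(x)
}
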