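# Delimited-text matrix I/O, decomposition serialization, and fixture
# round-trips.  Dialect: comma by default, tab accepted, decimal point only.

#' Read a numeric matrix from delimited text
#'
#' Strict reader for rectangular numeric tables: ragged rows, empty files
#' and non-numeric cells are rejected, the latter with the offending
#' row/column coordinates in the error message.
#'
#' @param path Path to a CSV/TSV file.
#' @param header Does the first row hold column names?
#' @param rownames Does the first column hold row names?
#' @param sep Field delimiter (default `","`).
#' @return A numeric matrix, with dimnames when present in the file.
#' @export
read_matrix <- function(path, header = FALSE, rownames = FALSE, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(nf) == 0L) stop("empty file: ", path)
  nf_data <- if (header) nf[-1] else nf
  if (header && length(nf_data) == 0L) stop("no data rows in ", path)
  if (length(unique(nf_data)) != 1L) {
    bad <- which(nf_data != nf_data[1])[1]
    stop("ragged rows in ", path, ": line ", bad + if (header) 1L else 0L,
         " has ", nf_data[bad], " fields, expected ", nf_data[1])
  }
  cn <- NULL
  if (header) {
    first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    # R convention: with row names, the header may omit the corner field
    if (!(nf[1] == nf_data[1] || (rownames && nf[1] == nf_data[1] - 1L)))
      stop("header of ", path, " has ", nf[1], " fields but data rows have ", nf_data[1])
    cn <- if (rownames && nf[1] == nf_data[1]) first[-1] else if (rownames) first
          else first
  }
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          skip = if (header) 1L else 0L,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  rn <- NULL
  if (rownames) {
    if (ncol(df) < 2L) stop("matrix in ", path, " has no data columns beyond the row names")
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  chr <- as.matrix(df)
  vals <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(vals) & !(trimws(chr) %in% c("NA", "NaN")))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(chr))
    stop("non-numeric cell '", chr[bad[1]], "' at data row ", rc[1],
         ", column ", rc[2], " of ", path)
  }
  m <- matrix(vals, nrow(chr), ncol(chr))
  rownames(m) <- rn
  if (header) colnames(m) <- cn
  m
}

#' Write a numeric matrix as delimited text
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @param sep Field delimiter (default `","`).
#' @param header Write column names (default: only when present)?
#' @param rownames Write row names (default: only when present)?
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sep = ",",
                         header = !is.null(colnames(x)),
                         rownames = !is.null(base::rownames(x))) {
  utils::write.table(x, path, sep = sep, quote = FALSE,
                     row.names = rownames, col.names = header)
  invisible(path)
}

.write_kv <- function(kv, path) {
  writeLines(paste0(names(kv), "=", vapply(kv, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = ","),
    character(1))), path)
  invisible(path)
}

.read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, character(1), 1))
}

#' Serialize a decomposition to a directory of text files
#'
#' Writes `P.csv`, `Q.csv` and `delta.csv` (columns named `comp_1` ...
#' `comp_R`) plus a `metadata.txt` key-value sidecar holding the method,
#' radii, tolerances, seed, per-component iteration counts and convergence
#' flags, and the orthogonality / sparsity residuals recomputed from the
#' written factors.
#'
#' @param dec A `csvd_decomposition`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(dec, dir) {
  stopifnot(inherits(dec, "csvd_decomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  R <- length(dec$delta)
  cn <- paste0("comp_", seq_len(R))
  P <- dec$P; Q <- dec$Q
  colnames(P) <- cn; colnames(Q) <- cn
  write_matrix(P, file.path(dir, "P.csv"), header = TRUE)
  write_matrix(Q, file.path(dir, "Q.csv"), header = TRUE)
  d <- matrix(dec$delta, ncol = 1, dimnames = list(NULL, "delta"))
  write_matrix(d, file.path(dir, "delta.csv"), header = TRUE)
  off <- function(M) {
    G <- crossprod(M)
    if (ncol(G) < 2) 0 else max(abs(G[upper.tri(G)]))
  }
  meta <- list(method = dec$method, rank = R,
               iterations = dec$iterations,
               converged = dec$converged,
               ortho_residual_P = off(dec$P),
               ortho_residual_Q = off(dec$Q),
               max_l1_P = max(colSums(abs(dec$P))),
               max_l1_Q = max(colSums(abs(dec$Q))))
  if (!is.null(dec$plan)) {
    meta$c1 <- dec$plan$c1
    meta$c2 <- dec$plan$c2
  }
  if (!is.null(dec$settings)) meta <- c(meta, dec$settings)
  .write_kv(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Read a serialized decomposition back from a directory
#'
#' @param dir Directory written by [write_decomposition()].
#' @return A `csvd_decomposition`.
#' @export
read_decomposition <- function(dir) {
  meta <- .read_kv(file.path(dir, "metadata.txt"))
  P <- read_matrix(file.path(dir, "P.csv"), header = TRUE)
  Q <- read_matrix(file.path(dir, "Q.csv"), header = TRUE)
  delta <- drop(read_matrix(file.path(dir, "delta.csv"), header = TRUE))
  .new_decomposition(P, Q, as.numeric(delta),
                     iterations = as.integer(strsplit(meta$iterations, ",")[[1]]),
                     converged = as.logical(strsplit(meta$converged, ",")[[1]]),
                     method = meta$method)
}

#' Write a simulation fixture (ground truth plus data matrix) as text
#'
#' Emits `X.csv`, `P_M.csv`, `Q_M.csv`, `delta_M.csv` and a plain-text
#' metadata sidecar (seed, noise sd, block sizes) so any simulated run can
#' be reconstructed or re-evaluated from disk.
#'
#' @param gt A [make_ground_truth()] object.
#' @param X The simulated data matrix from [simulate_X()] (or `NULL` to
#'   skip writing `X.csv`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(gt, X, dir) {
  stopifnot(inherits(gt, "csvd_ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  if (!is.null(X)) write_matrix(X, file.path(dir, "X.csv"))
  write_matrix(gt$P_M, file.path(dir, "P_M.csv"))
  write_matrix(gt$Q_M, file.path(dir, "Q_M.csv"))
  write_matrix(matrix(gt$delta_M, ncol = 1), file.path(dir, "delta_M.csv"))
  .write_kv(list(seed = gt$seed, noise_sd = gt$noise_sd,
                 p_block = gt$p_block, q_block = gt$q_block,
                 rank = length(gt$delta_M)),
            file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Read a simulation fixture back from a directory
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with the `"csvd_ground_truth"` object `gt` and the data
#'   matrix `X` (`NULL` if `X.csv` is absent).
#' @export
read_fixture <- function(dir) {
  meta <- .read_kv(file.path(dir, "metadata.txt"))
  gt <- structure(list(
    P_M = read_matrix(file.path(dir, "P_M.csv")),
    Q_M = read_matrix(file.path(dir, "Q_M.csv")),
    delta_M = as.numeric(drop(read_matrix(file.path(dir, "delta_M.csv")))),
    noise_sd = as.numeric(meta$noise_sd),
    p_block = as.integer(meta$p_block),
    q_block = as.integer(meta$q_block),
    seed = as.integer(meta$seed)), class = "csvd_ground_truth")
  xp <- file.path(dir, "X.csv")
  list(gt = gt, X = if (file.exists(xp)) read_matrix(xp) else NULL)
}
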