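# Orthonormal type-II DCT basis matrix: B[i+1, x+1] = d_i cos(pi (2x+1) i / 2M),
# with d_0 = sqrt(1/M) and d_i = sqrt(2/M) otherwise.  B is orthogonal, so the
# 2-D transform below conserves energy (Parseval) and inverts exactly.
dct_basis <- function(m) {
  i <- seq_len(m) - 1L
  x <- seq_len(m) - 1L
  b <- sqrt(2 / m) * cos(outer(i, 2 * x + 1) * pi / (2 * m))
  b[1, ] <- sqrt(1 / m)
  b
}

#' Two-dimensional discrete cosine transform
#'
#' Orthonormal type-II 2-D DCT:
#' `DCT(i,j) = d_i d_j sum_x sum_y f(x,y) cos(pi (2x+1) i / 2M) cos(pi (2y+1) j / 2N)`
#' with `d_0 = sqrt(1/M)`, `d_i = sqrt(2/M)` for `i > 0` (and likewise for
#' columns).  The transform is separable and computed as two matrix products;
#' being orthonormal it conserves energy and the constant matrix of ones maps
#' to a single DC coefficient `sqrt(M*N)`.
#'
#' @param x numeric matrix (M rows, N columns), nonempty.
#' @return M x N matrix of DCT coefficients; low frequencies sit in the
#'   top-left corner.
#' @seealso [idct2()] for the inverse, [extract_dct_descriptor()] for the
#'   protein descriptor built on this transform.
#' @export
dct2 <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("dct2: matrix must be nonempty")
  dct_basis(nrow(x)) %*% x %*% t(dct_basis(ncol(x)))
}

#' Inverse two-dimensional discrete cosine transform
#'
#' @param y coefficient matrix as produced by [dct2()].
#' @return the reconstructed matrix; `idct2(dct2(x))` equals `x` up to
#'   floating-point round-off.
#' @export
idct2 <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) == 0L || ncol(y) == 0L) stop("idct2: matrix must be nonempty")
  t(dct_basis(nrow(y))) %*% y %*% dct_basis(ncol(y))
}

#' Protein descriptor from the low-frequency DCT block of a PSSM
#'
#' Applies the 2-D DCT to the protein's L x 20 log-odds matrix and keeps the
#' top-left `n_rows` x `n_cols` low-frequency coefficient block, flattened
#' row-major -- 400 values at the defaults.  Because the DCT packs most of
#' the matrix energy into few low-frequency coefficients, this fixed-length
#' block summarises the evolutionary profile regardless of sequence length.
#'
#' Proteins shorter than `n_rows` residues are zero-padded to `n_rows` rows
#' before the transform.  With `normalize = TRUE` each score is first mapped
#' through the logistic function `1 / (1 + exp(-s))`; the default uses the
#' raw integer log-odds.  `order = "zigzag"` flattens the block in JPEG-style
#' zigzag (anti-diagonal) order instead of row-major.
#'
#' @param x a [pssm()].
#' @param n_rows,n_cols dimensions of the retained low-frequency block.
#' @param normalize logical; apply per-element logistic squashing first.
#' @param order `"row"` (default) or `"zigzag"` flattening of the block.
#' @return a `protein_descriptor`: list with `protein_id`, `method = "dct"`,
#'   and numeric `values` of length `n_rows * n_cols`.
#' @export
extract_dct_descriptor <- function(x, n_rows = 20L, n_cols = 20L,
                                   normalize = FALSE,
                                   order = c("row", "zigzag")) {
  stopifnot(inherits(x, "pssm"))
  order <- match.arg(order)
  scores <- x$scores
  if (normalize) scores <- 1 / (1 + exp(-scores))
  if (nrow(scores) < n_rows) {
    scores <- rbind(scores, matrix(0, n_rows - nrow(scores), ncol(scores)))
  }
  coef <- dct2(scores)
  block <- coef[seq_len(n_rows), seq_len(n_cols), drop = FALSE]
  values <- if (order == "row") as.vector(t(block)) else block[zigzag_index(n_rows, n_cols)]
  protein_descriptor(x$protein_id, values, method = "dct")
}

# linear indices of an m x n matrix in JPEG zigzag (anti-diagonal) order:
# even anti-diagonals are walked upwards (row decreasing), odd ones downwards
zigzag_index <- function(m, n) {
  r <- c(row(matrix(0, m, n)))
  s <- r + c(col(matrix(0, m, n)))  # anti-diagonal number + 2
  order(s, ifelse(s %% 2 == 0, -r, r))
}

#' Fixed-length numeric descriptor for a protein
#'
#' @param protein_id identifier string.
#' @param values numeric vector (length 400 for `method = "dct"`).
#' @param method `"dct"` or `"pseaac"`.
#' @return an object of class `protein_descriptor`.
#' @export
protein_descriptor <- function(protein_id, values, method = c("dct", "pseaac")) {
  method <- match.arg(method)
  if (method == "dct" && length(values) != 400L) {
    warning("dct descriptors conventionally have length 400; got ", length(values))
  }
  structure(
    list(protein_id = as.character(protein_id),
         values = as.numeric(values), method = method),
    class = "protein_descriptor"
  )
}

#' @export
print.protein_descriptor <- function(x, ...) {
  cat(sprintf("<%s descriptor> %s: %d values\n", x$method, x$protein_id,
              length(x$values)))
  invisible(x)
}

#' Write / read protein descriptor tables
#'
#' Descriptors are stored as a TSV keyed by protein id, one descriptor per
#' row, values in column order `v1..vK`.
#'
#' @param descriptors list of [protein_descriptor()] objects (write) .
#' @param path file path.
#' @return `write_descriptor_table` returns `path` invisibly;
#'   `read_descriptor_table` returns a named list of numeric vectors.
#' @export
write_descriptor_table <- function(descriptors, path) {
  stopifnot(length(descriptors) > 0)
  mat <- do.call(rbind, lapply(descriptors, function(d) d$values))
  df <- data.frame(protein_id = vapply(descriptors, function(d) d$protein_id, character(1)),
                   mat, check.names = FALSE)
  names(df) <- c("id", paste0("v", seq_len(ncol(mat))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, -1]))
  names(out) <- as.character(df[[1]])
  out
}
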