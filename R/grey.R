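#' Zero-starting-point image of a matrix, row-wise
#'
#' Subtracts each row's first entry from the whole row, so the first
#' column of the result is identically zero. Adding a constant to all
#' entries of the input leaves the image unchanged.
#'
#' @param X numeric matrix with at least one column.
#' @return matrix of the same shape.
#' @export
zero_start_rows <- function(X) {
  X <- as.matrix(X)
  if (length(X) == 0L) stop("zero_start_rows: empty matrix")
  X - X[, 1L]
}

#' Row-wise or column-wise grey relation degrees of two matrices
#'
#' For each line `k` along the chosen axis, over the zero-start images of
#' `X` and `Y` taken along that axis: `s(k)` and `t(k)` are the line sums
#' of the images, and
#' `eps(k) = (1 + |s| + |t|) / (1 + |s| + |t| + |s - t|)`,
#' always in `(0, 1]` and equal to 1 iff `s(k) = t(k)`.
#'
#' @param X,Y numeric matrices of identical shape.
#' @param axis `"rows"` or `"columns"`.
#' @return numeric vector of degrees (length `nrow` for rows, `ncol` for
#'   columns).
#' @export
directional_degrees <- function(X, Y, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)))
    stop("shape mismatch: ", paste(dim(X), collapse = "x"), " vs ",
         paste(dim(Y), collapse = "x"))
  if (axis == "columns") {
    X <- t(X)
    Y <- t(Y)
  }
  s <- rowSums(zero_start_rows(X))
  t <- rowSums(zero_start_rows(Y))
  base <- 1 + abs(s) + abs(t)
  base / (base + abs(s - t))
}

#' Matrix-extended grey relation degree
#'
#' The similarity score between two equal-shaped matrices:
#' `eta = 1/2 * (mean of row degrees + mean of column degrees)`, using
#' [directional_degrees()] along both axes. Always in `(0, 1]`;
#' symmetric in its arguments; exactly 1 when `X = Y` (and, more
#' generally, whenever the two matrices differ by a constant — the
#' zero-start images discard additive offsets).
#'
#' @param X,Y numeric matrices of identical shape (e.g. two
#'   `feature_matrix` descriptors).
#' @return object of class `grey_relation`: list with `eta`,
#'   `row_degrees`, `col_degrees`.
#' @export
grey_relation <- function(X, Y) {
  rd <- directional_degrees(X, Y, "rows")
  cd <- directional_degrees(X, Y, "columns")
  structure(list(eta = (mean(rd) + mean(cd)) / 2,
                 row_degrees = rd, col_degrees = cd),
            class = "grey_relation")
}

#' @export
print.grey_relation <- function(x, digits = 4L, ...) {
  cat(sprintf("grey relation degree eta = %.*f  (%d rows, %d columns)\n",
              digits, x$eta, length(x$row_degrees), length(x$col_degrees)))
  invisible(x)
}
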