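#' Collapse a table around one cell
#'
#' Builds the 2 x 2 table that isolates one (row, column) pair against the
#' pooled remainder: with \eqn{r_i} the row-i sum, \eqn{s_j} the column-j sum
#' and T the grand total, the result is
#' \deqn{\begin{pmatrix} c_{ij} & r_i - c_{ij} \\ s_j - c_{ij} & T - r_i - s_j + c_{ij} \end{pmatrix}.}
#' This is the building block of the singular coefficient matrix.
#'
#' @param table a `contingency_table` with at least 2 rows and 2 columns.
#' @param i,j row and column index of the distinguished cell.
#' @return A 2 x 2 `contingency_table` labelled
#'   `(label_i, "not_<label_i>") x (label_j, "not_<label_j>")`.
#' @examples
#' tab <- make_table(rbind(c(2, 1), c(1, 2), c(2, 2)))
#' singular_table(tab, 1, 1)
#' @export
singular_table <- function(table, i, j) {
  table <- as_contingency_table(table)
  k <- nrow(table)
  n <- ncol(table)
  if (k < 2L || n < 2L) {
    stop_zassoc("singular collapse needs at least a 2 x 2 table",
                "zassoc_error_shape")
  }
  if (i < 1L || i > k || j < 1L || j > n) {
    stop_zassoc("cell index out of range", "zassoc_error_dimension")
  }
  cij <- table[i, j]
  ri <- sum(table[i, ])
  sj <- sum(table[, j])
  tt <- sum(table)
  counts <- rbind(c(cij, ri - cij),
                  c(sj - cij, tt - ri - sj + cij))
  rl <- rownames(table)[i]
  cl <- colnames(table)[j]
  make_table(counts, c(rl, paste0("not_", rl)), c(cl, paste0("not_", cl)))
}

#' Matrix of singular Z coefficients
#'
#' For every cell of the (optionally collapsed) table, computes the Z
#' coefficient of the 2 x 2 table formed by that cell's row and column
#' against the pooled remainder (see [singular_table()]). On 2 x 2 tables Z
#' is symmetric, so the entries do not depend on direction. Groupings are
#' applied once, before cell enumeration: with groupings the entries refer
#' to row/column groups, not original categories.
#'
#' @inheritParams z_coefficient
#' @return An object of class `singular_z_matrix`: a k x n numeric matrix of
#'   values in \[0, 1\] with the (post-grouping) labels.
#' @examples
#' z_matrix(rbind(c(2, 1), c(1, 2), c(2, 2)))
#' @export
z_matrix <- function(table, row_groups = NULL, col_groups = NULL) {
  table <- as_contingency_table(table)
  table <- apply_groupings(table, row_groups, col_groups)
  k <- nrow(table)
  n <- ncol(table)
  if (k < 2L || n < 2L) {
    stop_zassoc(
      "singular coefficients need at least a 2 x 2 (post-grouping) table",
      "zassoc_error_shape")
  }
  values <- matrix(0, k, n, dimnames = dimnames(table))
  for (i in seq_len(k)) {
    for (j in seq_len(n)) {
      values[i, j] <- z_coefficient(singular_table(table, i, j))$z
    }
  }
  structure(values, class = c("singular_z_matrix", "matrix", "array"))
}

#' @export
print.singular_z_matrix <- function(x, digits = 6, ...) {
  cat(sprintf("singular_z_matrix: %d x %d\n", nrow(x), ncol(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Ranked list of singular Z coefficients
#'
#' Flattens [z_matrix()] into a list sorted by Z descending; ties are broken
#' by row index then column index (ascending), so the output order is fully
#' deterministic. Scanning the head of this list is the intended way to find
#' the strongest row-column associations in a large table.
#'
#' @inheritParams z_coefficient
#' @param top optional: keep only the `top` highest entries.
#' @return A data.frame with columns `row_label`, `col_label`, `z`, one row
#'   per (post-grouping) cell, sorted as described.
#' @examples
#' head(z_ranks(rbind(c(2, 1), c(1, 2), c(2, 2))))
#' @export
z_ranks <- function(table, row_groups = NULL, col_groups = NULL, top = NULL) {
  zm <- z_matrix(table, row_groups, col_groups)
  k <- nrow(zm)
  n <- ncol(zm)
  idx <- expand.grid(i = seq_len(k), j = seq_len(n))
  out <- data.frame(
    row_label = rownames(zm)[idx$i],
    col_label = colnames(zm)[idx$j],
    z = as.vector(unclass(zm)),
    stringsAsFactors = FALSE
  )
  ord <- order(-out$z, idx$i, idx$j)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) {
    top <- as.integer(top)
    if (is.na(top) || top < 1L) {
      stop_zassoc("top must be a positive integer", "zassoc_error_dimension")
    }
    out <- utils::head(out, top)
  }
  out
}
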