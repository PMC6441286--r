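#' Construct a validated contingency table
#'
#' A contingency table is a k x n matrix of non-negative finite counts (or
#' weights) with unique row and column labels. All association measures in
#' this package operate on proportions, so non-integral weights are accepted;
#' scaling all counts by a positive constant never changes any coefficient.
#'
#' @param counts numeric matrix (or object coercible to one) of non-negative
#'   finite values with a positive total.
#' @param row_labels character vector of unique row labels; defaults to
#'   existing `rownames(counts)` or `"R1"..."Rk"`.
#' @param col_labels character vector of unique column labels; defaults to
#'   existing `colnames(counts)` or `"C1"..."Cn"`.
#' @return An object of class `contingency_table`: the labelled numeric
#'   matrix.
#' @examples
#' make_table(rbind(c(3, 2), c(1, 4)), c("a", "not_a"), c("b", "not_b"))
#' @export
make_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop_zassoc("counts must be numeric", "zassoc_error_type")
  }
  k <- nrow(counts)
  n <- ncol(counts)
  if (k < 1L || n < 1L) {
    stop_zassoc("counts must have at least one row and one column",
                "zassoc_error_dimension")
  }
  if (is.null(row_labels)) {
    row_labels <- rownames(counts)
    if (is.null(row_labels)) row_labels <- paste0("R", seq_len(k))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(counts)
    if (is.null(col_labels)) col_labels <- paste0("C", seq_len(n))
  }
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != k) {
    stop_zassoc(sprintf("row_labels has length %d but counts has %d rows",
                        length(row_labels), k), "zassoc_error_dimension")
  }
  if (length(col_labels) != n) {
    stop_zassoc(sprintf("col_labels has length %d but counts has %d columns",
                        length(col_labels), n), "zassoc_error_dimension")
  }
  if (anyDuplicated(row_labels)) {
    stop_zassoc(paste0("duplicate row_labels: ",
                       paste(unique(row_labels[duplicated(row_labels)]),
                             collapse = ", ")),
                "zassoc_error_labels")
  }
  if (anyDuplicated(col_labels)) {
    stop_zassoc(paste0("duplicate col_labels: ",
                       paste(unique(col_labels[duplicated(col_labels)]),
                             collapse = ", ")),
                "zassoc_error_labels")
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop_zassoc("counts contains NA or non-finite entries",
                "zassoc_error_negative")
  }
  if (any(counts < 0)) {
    stop_zassoc("counts contains negative entries", "zassoc_error_negative")
  }
  if (sum(counts) <= 0) {
    stop_zassoc("counts sums to zero: the table carries no observations",
                "zassoc_error_zero_table")
  }
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts, class = c("contingency_table", "matrix", "array"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: %d x %d, total %g\n", nrow(x), ncol(x),
              sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Coerce to a contingency table
#'
#' @param x matrix, table, or data.frame of counts.
#' @param ... passed to [make_table()].
#' @return A `contingency_table`.
#' @export
as_contingency_table <- function(x, ...) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (inherits(x, "table")) x <- unclass(as.matrix(x))
  make_table(x, ...)
}

#' Transpose a contingency table
#'
#' Swaps rows and columns (with their labels). Because the Z coefficient is
#' directional, `z_coefficient(transpose(tab))` generally differs from
#' `z_coefficient(tab)` for tables larger than 2 x 2.
#'
#' @param table a `contingency_table`.
#' @return The transposed `contingency_table`.
#' @export
transpose <- function(table) {
  table <- as_contingency_table(table)
  make_table(t(unclass(table)), colnames(table), rownames(table))
}

#' Normalize a contingency table to a joint distribution
#'
#' Divides counts by the grand total to obtain joint probabilities
#' \eqn{p_{ij} = P(A_i \cap B_j)} with row marginals \eqn{p_{i\cdot}} and
#' column marginals \eqn{p_{\cdot j}}. Rows are the predicted partition
#' \eqn{A_1..A_k}; columns are the conditioning partition \eqn{B_1..B_n}.
#'
#' @param table a `contingency_table`.
#' @return An object of class `joint_distribution`: a list with elements
#'   `p` (k x n probability matrix), `row_marginals`, `col_marginals`,
#'   `row_labels`, `col_labels`.
#' @examples
#' normalize(make_table(rbind(c(3, 2), c(1, 4))))
#' @export
normalize <- function(table) {
  table <- as_contingency_table(table)
  p <- unclass(table) / sum(table)
  structure(list(
    p = p,
    row_marginals = rowSums(p),
    col_marginals = colSums(p),
    row_labels = rownames(table),
    col_labels = colnames(table)
  ), class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf("joint_distribution: %d x %d\n", nrow(x$p), ncol(x$p)))
  print(x$p, ...)
  invisible(x)
}

#' Define a category-to-group mapping for one table axis
#'
#' A grouping map assigns every category label of one axis to a group label;
#' [collapse()] sums the counts of categories sharing a group. The mapping
#' may be given as a named character vector (`c(gene1 = "Wnt", ...)`), or as
#' an unnamed vector/factor of group labels aligned positionally with the
#' axis (resolved when the map is applied to a table).
#'
#' @param mapping named character vector (category -> group), or an unnamed
#'   vector/factor of group labels aligned with the axis categories.
#' @param axis `"rows"` or `"cols"`.
#' @return An object of class `grouping_map`.
#' @examples
#' grouping_map(c(A1 = "g1", A2 = "g1", A3 = "g2"), "rows")
#' @export
grouping_map <- function(mapping, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (inherits(mapping, "grouping_map")) {
    return(structure(list(axis = axis, mapping = mapping$mapping),
                     class = "grouping_map"))
  }
  if (is.factor(mapping)) {
    mapping <- stats::setNames(as.character(mapping), names(mapping))
  }
  mapping <- stats::setNames(as.character(mapping), names(mapping))
  if (length(mapping) == 0L) {
    stop_zassoc("grouping mapping is empty", "zassoc_error_coverage")
  }
  if (anyNA(mapping)) {
    stop_zassoc("grouping mapping contains NA group labels",
                "zassoc_error_coverage")
  }
  nm <- names(mapping)
  if (!is.null(nm) && anyDuplicated(nm)) {
    stop_zassoc(paste0("duplicate categories in grouping: ",
                       paste(unique(nm[duplicated(nm)]), collapse = ", ")),
                "zassoc_error_coverage")
  }
  structure(list(axis = axis, mapping = mapping), class = "grouping_map")
}

#' @export
print.grouping_map <- function(x, ...) {
  cat(sprintf("grouping_map (%s): %d categories -> %d groups\n", x$axis,
              length(x$mapping), length(unique(x$mapping))))
  invisible(x)
}

# Resolve a grouping argument (grouping_map, named vector, or positional
# vector/factor) against the labels of the targeted axis. Returns a character
# vector of group labels aligned with `labels`, or signals a coverage error.
resolve_grouping <- function(grouping, labels, axis) {
  if (!inherits(grouping, "grouping_map")) {
    grouping <- grouping_map(grouping, axis)
  }
  m <- grouping$mapping
  nm <- names(m)
  if (is.null(nm) || all(nm == "")) {
    if (length(m) != length(labels)) {
      stop_zassoc(sprintf(
        "unnamed %s grouping has length %d but the axis has %d categories",
        axis, length(m), length(labels)), "zassoc_error_coverage")
    }
    return(unname(m))
  }
  missing <- setdiff(labels, nm)
  extra <- setdiff(nm, labels)
  if (length(missing) || length(extra)) {
    parts <- character(0)
    if (length(missing)) {
      parts <- c(parts, paste0("unmapped categories: ",
                               paste(missing, collapse = ", ")))
    }
    if (length(extra)) {
      parts <- c(parts, paste0("unknown categories: ",
                               paste(extra, collapse = ", ")))
    }
    stop_zassoc(paste0(axis, " grouping does not cover the axis (",
                       paste(parts, collapse = "; "), ")"),
                "zassoc_error_coverage")
  }
  unname(m[labels])
}

#' Collapse categories of one axis by grouping
#'
#' Sums the counts of categories mapped to the same group. Groups appear in
#' first-appearance order along the original axis, so the output is
#' deterministic under any input ordering of the mapping.
#'
#' @param table a `contingency_table`.
#' @param grouping a [grouping_map()] (or a vector acceptable to it); its
#'   `axis` decides whether rows or columns are collapsed.
#' @param axis used when `grouping` is a bare vector: `"rows"` or `"cols"`.
#' @return The collapsed `contingency_table`.
#' @examples
#' tab <- make_table(rbind(c(2, 1), c(1, 2), c(2, 2)),
#'                   c("A1", "A2", "A3"), c("B1", "B2"))
#' collapse(tab, grouping_map(c(A1 = "g1", A2 = "g1", A3 = "g2"), "rows"))
#' @export
collapse <- function(table, grouping, axis = NULL) {
  table <- as_contingency_table(table)
  if (inherits(grouping, "grouping_map")) {
    axis <- grouping$axis
  } else if (is.null(axis)) {
    stop_zassoc("axis must be given when grouping is not a grouping_map",
                "zassoc_error_coverage")
  }
  labels <- if (axis == "rows") rownames(table) else colnames(table)
  groups <- resolve_grouping(grouping, labels, axis)
  order_levels <- unique(groups)  # first-appearance order
  f <- factor(groups, levels = order_levels)
  m <- unclass(table)
  collapsed <- if (axis == "rows") {
    rowsum(m, f, reorder = FALSE)
  } else {
    t(rowsum(t(m), f, reorder = FALSE))
  }
  if (axis == "rows") {
    make_table(collapsed, order_levels, colnames(table))
  } else {
    make_table(collapsed, rownames(table), order_levels)
  }
}

# Apply optional row/col groupings to a table; bare vectors are interpreted
# for the stated axis.
apply_groupings <- function(table, row_groups = NULL, col_groups = NULL) {
  if (!is.null(row_groups)) {
    table <- collapse(table, grouping_map(row_groups, "rows"))
  }
  if (!is.null(col_groups)) {
    table <- collapse(table, grouping_map(col_groups, "cols"))
  }
  table
}

stop_zassoc <- function(msg, class) {
  stop(structure(class = c(class, "zassoc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
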