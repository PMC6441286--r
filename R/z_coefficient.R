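#' Error-rate ratio
#'
#' The ratio \eqn{(1 - P(A|B)) / (1 - P(A))} compares the error made when
#' predicting the event A with and without the knowledge of B. A value below
#' 1 means knowing B reduces the prediction error; 1 means B is uninformative
#' (independence); 0 means B determines A. The Z coefficient is built from a
#' marginal-weighted average of products of such ratios.
#'
#' @param p_a_given_b conditional probability \eqn{P(A|B)} in \[0, 1\].
#' @param p_a marginal probability \eqn{P(A)} in \[0, 1).
#' @return The ratio, a non-negative number.
#' @examples
#' error_rate_ratio(0.8, 0.5)  # 0.4: B is informative about A
#' error_rate_ratio(0.5, 0.5)  # 1:   independence
#' @export
error_rate_ratio <- function(p_a_given_b, p_a) {
  if (any(p_a_given_b < 0 | p_a_given_b > 1, na.rm = FALSE) ||
      anyNA(p_a_given_b)) {
    stop_zassoc("p_a_given_b must lie in [0, 1]", "zassoc_error_probability")
  }
  if (anyNA(p_a) || any(p_a < 0 | p_a > 1)) {
    stop_zassoc("p_a must lie in [0, 1]", "zassoc_error_probability")
  }
  if (any(p_a == 1)) {
    stop_zassoc(
      "p_a = 1: the error rate without conditioning is zero, ratio undefined",
      "zassoc_error_degenerate")
  }
  (1 - p_a_given_b) / (1 - p_a)
}

#' Row term of the squared Z coefficient
#'
#' For row i with positive marginal, the term is
#' \deqn{p_{i\cdot} \prod_{j: p_{\cdot j} > 0} \frac{p_{ij}}{p_{i\cdot}\, p_{\cdot j}},}
#' i.e. the row marginal times the product over (non-empty) columns of
#' \eqn{P(A_i|B_j)/P(A_i)}. Under independence the product is 1 and the term
#' reduces to \eqn{p_{i\cdot}}; a single zero cell in a non-empty column
#' annihilates it. Summing the terms over non-empty rows and subtracting from
#' 1 gives the squared Z coefficient.
#'
#' @param dist a `joint_distribution` (see [normalize()]).
#' @param i row index with `dist$row_marginals[i] > 0`.
#' @return The non-negative term value.
#' @export
row_term <- function(dist, i) {
  stopifnot(inherits(dist, "joint_distribution"))
  if (i < 1L || i > length(dist$row_marginals)) {
    stop_zassoc("row index out of range", "zassoc_error_dimension")
  }
  ri <- dist$row_marginals[[i]]
  if (ri <= 0) {
    stop_zassoc("row_term requires a positive row marginal; skip empty rows",
                "zassoc_error_degenerate")
  }
  cj <- dist$col_marginals
  live <- cj > 0
  ratios <- dist$p[i, live] / (ri * cj[live])
  ri * prod(ratios)
}

#' Squared Z coefficient of a joint distribution
#'
#' Computes the raw (unclamped) squared directional association coefficient
#' \deqn{Z^2(A{:}B) = 1 - \sum_{i: p_{i\cdot} > 0} p_{i\cdot}
#'   \prod_{j: p_{\cdot j} > 0} \frac{p_{ij}}{p_{i\cdot}\, p_{\cdot j}}.}
#' Rows with zero marginal are skipped and columns with zero marginal are
#' excluded from every product, so appending empty categories never changes
#' the value. The result is 0 for an exact product distribution, 1 when every
#' non-empty column concentrates its mass on a single row (and at least two
#' rows carry mass), and equals squared Cramer's V whenever exactly two
#' columns are non-empty.
#'
#' @param dist a `joint_distribution` or anything [normalize()] accepts.
#' @return The raw squared coefficient (not clamped; tiny negative values can
#'   arise from floating point).
#' @examples
#' z_squared(normalize(make_table(rbind(c(3, 2), c(1, 4)))))  # 1/6
#' @export
z_squared <- function(dist) {
  if (!inherits(dist, "joint_distribution")) dist <- normalize(dist)
  ri <- dist$row_marginals
  cj <- dist$col_marginals
  live_r <- which(ri > 0)
  live_c <- cj > 0
  total <- 0
  for (i in live_r) {
    ratios <- dist$p[i, live_c] / (ri[[i]] * cj[live_c])
    total <- total + ri[[i]] * prod(ratios)
  }
  1 - total
}

#' Directional Z association coefficient
#'
#' The central statistic of the package: a directional measure of association
#' in \[0, 1\] for a k x n contingency table. With the default direction the
#' rows are the predicted partition A and the columns the conditioning
#' partition B; `direction = "cols_given_rows"` transposes first. Optional
#' groupings collapse categories before anything else is computed.
#'
#' Properties: Z = 0 at independence; Z = 1 when each column determines a
#' single row; Z is asymmetric for tables larger than 2 x 2; Z equals
#' Cramer's V whenever the (effective) column count is 2, and the absolute
#' phi/Pearson coefficient on 2 x 2 tables. Merging categories can either
#' increase or decrease Z.
#'
#' @param table a `contingency_table` (or matrix coercible to one).
#' @param row_groups,col_groups optional groupings ([grouping_map()], named
#'   vector, or positional vector/factor) applied before computation.
#' @param direction `"rows_given_cols"` (default: how well the columns
#'   predict the rows) or `"cols_given_rows"`.
#' @return An object of class `association_result` with elements `z`,
#'   `z_squared_raw`, `direction`, `k_effective`, `n_effective` (counts of
#'   non-empty rows/columns of the analysed, possibly transposed table), and
#'   `warnings` (character vector; degenerate shapes and clamping are
#'   flagged here, never silently lost).
#' @examples
#' z_coefficient(rbind(c(3, 2), c(1, 4)))           # 0.408248 = |phi|
#' z_coefficient(rbind(c(2, 1), c(1, 2), c(2, 2)))  # 0.258199 = Cramer's V
#' @export
z_coefficient <- function(table, row_groups = NULL, col_groups = NULL,
                          direction = c("rows_given_cols",
                                        "cols_given_rows")) {
  direction <- match.arg(direction)
  table <- as_contingency_table(table)
  table <- apply_groupings(table, row_groups, col_groups)
  if (direction == "cols_given_rows") table <- transpose(table)
  dist <- normalize(table)
  k_eff <- sum(dist$row_marginals > 0)
  n_eff <- sum(dist$col_marginals > 0)
  warnings <- character(0)
  if (k_eff < 2L || n_eff < 2L) {
    zsq <- 0
    warnings <- c(warnings, sprintf(
      "degenerate table: %d effective row(s) x %d effective column(s); Z = 0",
      k_eff, n_eff))
  } else {
    zsq <- z_squared(dist)
    if (zsq < -1e-9) {
      warnings <- c(warnings, sprintf(
        "z_squared_raw = %.3e is negative beyond floating-point noise; clamped to 0",
        zsq))
    }
  }
  z <- sqrt(min(max(zsq, 0), 1))
  structure(list(
    z = z,
    z_squared_raw = zsq,
    direction = direction,
    k_effective = k_eff,
    n_effective = n_eff,
    warnings = warnings
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, digits = 6, ...) {
  cat(sprintf("Z = %.*f  (%s; %d x %d effective)\n", digits, x$z,
              x$direction, x$k_effective, x$n_effective))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
as.double.association_result <- function(x, ...) x$z
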