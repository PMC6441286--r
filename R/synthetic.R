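# Run code under a temporary RNG state so seeded generators leave the
# caller's random stream untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }, add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a table of independent variables
#'
#' In `"exact"` mode returns `total * outer(row_marginals, col_marginals)` —
#' an exact product table whose Z coefficient is 0 by construction (cells may
#' be non-integral; the coefficient only uses proportions). In
#' `"multinomial"` mode draws `total` observations from the product
#' distribution, so Z fluctuates around 0 and shrinks as `total` grows.
#'
#' @param row_marginals,col_marginals probability vectors (each sums to 1
#'   within 1e-12).
#' @param total positive target count sum.
#' @param mode `"exact"` or `"multinomial"`.
#' @param seed integer seed (required for `"multinomial"`).
#' @return A `contingency_table`.
#' @examples
#' independent_table(c(0.3, 0.7), c(0.4, 0.6), 100)
#' @export
independent_table <- function(row_marginals, col_marginals, total,
                              mode = c("exact", "multinomial"), seed = NULL) {
  mode <- match.arg(mode)
  check_marginals <- function(m, what) {
    if (anyNA(m) || any(m < 0) || abs(sum(m) - 1) > 1e-12) {
      stop_zassoc(paste0(what,
                         " must be non-negative and sum to 1 within 1e-12"),
                  "zassoc_error_probability")
    }
  }
  check_marginals(row_marginals, "row_marginals")
  check_marginals(col_marginals, "col_marginals")
  if (total <= 0) {
    stop_zassoc("total must be positive", "zassoc_error_dimension")
  }
  p <- outer(row_marginals, col_marginals)
  counts <- if (mode == "exact") {
    total * p
  } else {
    if (is.null(seed)) {
      stop_zassoc("multinomial mode requires a seed", "zassoc_error_type")
    }
    draw <- with_seed(seed, stats::rmultinom(1, size = total, prob = p))
    matrix(draw, nrow = length(row_marginals))
  }
  make_table(counts,
             paste0("A", seq_along(row_marginals)),
             paste0("B", seq_along(col_marginals)))
}

#' Generate a functionally dependent table
#'
#' Assigns the whole mass of each column to a single row: cell (i, j) equals
#' `total * col_marginals[j]` when `col_to_row[j] == i` and 0 otherwise. As
#' long as at least two distinct rows are used, every column determines its
#' row and the Z coefficient is exactly 1.
#'
#' @param col_to_row integer vector: for each column, the index of the row
#'   that carries it. Must use at least 2 distinct rows.
#' @param col_marginals probability vector over columns (sums to 1).
#' @param total positive target count sum.
#' @return A `contingency_table` with `max(col_to_row)` rows.
#' @examples
#' functional_table(c(1, 2), c(0.5, 0.5), 10)  # [[5,0],[0,5]]
#' @export
functional_table <- function(col_to_row, col_marginals, total) {
  col_to_row <- as.integer(col_to_row)
  if (length(col_to_row) != length(col_marginals)) {
    stop_zassoc("col_to_row and col_marginals must have the same length",
                "zassoc_error_dimension")
  }
  if (anyNA(col_to_row) || any(col_to_row < 1L)) {
    stop_zassoc("col_to_row must contain positive row indices",
                "zassoc_error_dimension")
  }
  if (length(unique(col_to_row)) < 2L) {
    stop_zassoc(
      "all columns map to one row: the dependency is degenerate, not maximal",
      "zassoc_error_degenerate")
  }
  if (anyNA(col_marginals) || any(col_marginals < 0) ||
      abs(sum(col_marginals) - 1) > 1e-12) {
    stop_zassoc("col_marginals must be non-negative and sum to 1 within 1e-12",
                "zassoc_error_probability")
  }
  k <- max(col_to_row)
  n <- length(col_to_row)
  counts <- matrix(0, k, n)
  counts[cbind(col_to_row, seq_len(n))] <- total * col_marginals
  make_table(counts, paste0("A", seq_len(k)), paste0("B", seq_len(n)))
}

#' Generate a random Dirichlet table
#'
#' Draws the k*n cell probabilities from a symmetric Dirichlet distribution
#' (via normalised gamma draws) and scales them by `total`. Concentration 1
#' gives a uniform draw over the probability simplex — the workhorse of the
#' randomised property sweeps; large concentrations approach the uniform
#' table and hence near-independence.
#'
#' @param k,n dimensions, both at least 2.
#' @param concentration positive Dirichlet concentration parameter.
#' @param total positive target count sum.
#' @param seed integer seed; a fixed seed reproduces the table bit for bit.
#' @return A `contingency_table` with positive real-valued cells.
#' @examples
#' dirichlet_table(3, 2, 1, 100, seed = 42)
#' @export
dirichlet_table <- function(k, n, concentration = 1, total = 1, seed) {
  if (k < 2L || n < 2L) {
    stop_zassoc("dirichlet_table needs k >= 2 and n >= 2",
                "zassoc_error_dimension")
  }
  if (concentration <= 0) {
    stop_zassoc("concentration must be positive", "zassoc_error_probability")
  }
  g <- with_seed(seed, stats::rgamma(k * n, shape = concentration, rate = 1))
  p <- matrix(g / sum(g), k, n)
  make_table(total * p, paste0("A", seq_len(k)), paste0("B", seq_len(n)))
}

#' Blend an independent table with a functional one
#'
#' Cellwise convex combination `(1 - epsilon) * base + epsilon * target`,
#' rescaled to `total`: a dial for association strength running from Z = 0
#' (epsilon 0, the independent base) to Z = 1 (epsilon 1, the functional
#' target). For 2 x 2 uniform-marginal endpoints the dial is exact: Z equals
#' epsilon.
#'
#' @param epsilon blend weight in \[0, 1\].
#' @param independent_base,functional_target `contingency_table`s of the
#'   same shape and labels.
#' @param total positive target count sum of the output.
#' @return A `contingency_table`.
#' @export
association_blend <- function(epsilon, independent_base, functional_target,
                              total = sum(independent_base)) {
  if (is.na(epsilon) || epsilon < 0 || epsilon > 1) {
    stop_zassoc("epsilon must lie in [0, 1]", "zassoc_error_probability")
  }
  base <- as_contingency_table(independent_base)
  target <- as_contingency_table(functional_target)
  if (!identical(dim(base), dim(target)) ||
      !identical(dimnames(base), dimnames(target))) {
    stop_zassoc("base and target must share shape and labels",
                "zassoc_error_dimension")
  }
  mix <- (1 - epsilon) * unclass(base) / sum(base) +
    epsilon * unclass(target) / sum(target)
  make_table(total * mix, rownames(base), colnames(base))
}
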