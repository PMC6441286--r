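#' Pearson chi-squared statistic of a contingency table
#'
#' Plain \eqn{\sum_{ij} (c_{ij} - e_{ij})^2 / e_{ij}} with expected counts
#' \eqn{e_{ij} = r_i s_j / T}; no continuity correction. Used here as the
#' backbone of the Cramer's V oracle, not as a test statistic (no p-values).
#'
#' @param table a `contingency_table`; all row and column marginals must be
#'   positive (drop empty categories first, e.g. with [drop_empty()]).
#' @return The non-negative statistic.
#' @examples
#' chi_squared(rbind(c(2, 1), c(1, 2), c(2, 2)))  # 2/3
#' @export
chi_squared <- function(table) {
  table <- as_contingency_table(table)
  r <- rowSums(table)
  s <- colSums(table)
  if (any(r == 0) || any(s == 0)) {
    stop_zassoc(
      "chi_squared requires positive marginals; drop empty rows/columns first",
      "zassoc_error_degenerate")
  }
  e <- outer(r, s) / sum(table)
  sum((unclass(table) - e)^2 / e)
}

#' Cramer's V
#'
#' \eqn{V = \sqrt{\chi^2 / (T \min(k - 1, n - 1))}}, the classical symmetric
#' chi-squared-based association measure in \[0, 1\]. Serves as the central
#' independent oracle for the Z coefficient: Z equals V exactly on any table
#' with two (effective) columns.
#'
#' @inheritParams chi_squared
#' @return V in \[0, 1\].
#' @examples
#' cramers_v(rbind(c(2, 1), c(1, 2), c(2, 2)))  # 0.258199
#' @export
cramers_v <- function(table) {
  table <- as_contingency_table(table)
  if (min(nrow(table), ncol(table)) < 2L) {
    stop_zassoc("Cramer's V needs at least 2 rows and 2 columns",
                "zassoc_error_shape")
  }
  sqrt(chi_squared(table) / (sum(table) * (min(dim(table)) - 1)))
}

#' Phi coefficient of a 2 x 2 table
#'
#' The signed measure \eqn{(ad - bc) / \sqrt{(a+b)(c+d)(a+c)(b+d)}} in
#' \[-1, 1\], equal to the Pearson correlation of the two binary indicator
#' variables. Its absolute value equals both Cramer's V and the Z coefficient
#' on 2 x 2 tables.
#'
#' @param table a 2 x 2 `contingency_table` with positive marginals.
#' @return The signed coefficient.
#' @examples
#' phi(rbind(c(3, 2), c(1, 4)))  # 10 / sqrt(600)
#' @export
phi <- function(table) {
  table <- as_contingency_table(table)
  if (nrow(table) != 2L || ncol(table) != 2L) {
    stop_zassoc("phi is defined for 2 x 2 tables only", "zassoc_error_shape")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) {
    stop_zassoc("phi undefined: a marginal of the 2 x 2 table is zero",
                "zassoc_error_degenerate")
  }
  (a * d - b * c) / sqrt(denom)
}

#' Pearson correlation of the binary expansion of a 2 x 2 table
#'
#' Expands an integral 2 x 2 table into its T paired 0/1 observations
#' (x = row indicator, y = column indicator) and returns their Pearson
#' correlation via [stats::cor()]. By the phi-Pearson identity this equals
#' [phi()] exactly; the deliberately naive expansion keeps it an independent
#' oracle rather than a reimplementation.
#'
#' @param table a 2 x 2 `contingency_table` of non-negative integers with
#'   positive marginals.
#' @return The correlation in \[-1, 1\].
#' @examples
#' pearson_binary(rbind(c(3, 2), c(1, 4)))
#' @export
pearson_binary <- function(table) {
  table <- as_contingency_table(table)
  if (nrow(table) != 2L || ncol(table) != 2L) {
    stop_zassoc("pearson_binary is defined for 2 x 2 tables only",
                "zassoc_error_shape")
  }
  counts <- unclass(table)
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop_zassoc("pearson_binary needs integral counts for the expansion",
                "zassoc_error_type")
  }
  counts <- round(counts)
  x <- rep(c(0L, 0L, 1L, 1L), times = c(counts[1, 1], counts[1, 2],
                                        counts[2, 1], counts[2, 2]))
  y <- rep(c(0L, 1L, 0L, 1L), times = c(counts[1, 1], counts[1, 2],
                                        counts[2, 1], counts[2, 2]))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_zassoc("pearson_binary undefined: a marginal is zero",
                "zassoc_error_degenerate")
  }
  stats::cor(x, y)
}

#' Drop empty rows and columns
#'
#' Removes all-zero rows and columns. The Z coefficient ignores empty
#' categories by construction; the chi-squared-based oracles require them to
#' be removed explicitly.
#'
#' @param table a `contingency_table`.
#' @return The `contingency_table` restricted to non-empty rows and columns.
#' @export
drop_empty <- function(table) {
  table <- as_contingency_table(table)
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  make_table(unclass(table)[keep_r, keep_c, drop = FALSE],
             rownames(table)[keep_r], colnames(table)[keep_c])
}
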