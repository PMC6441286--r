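# Independent oracles and fixture builders shared across the suite. These
# deliberately avoid the package's own z/phi code paths.

# Closed-form signed phi of a 2x2 matrix.
oracle_phi <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  (a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d))
}

# Cramer's V via stats::chisq.test (no continuity correction).
oracle_cramers_v <- function(m) {
  chi2 <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic
  sqrt(unname(chi2) / (sum(m) * (min(dim(m)) - 1)))
}

# The worked 3x2 table used throughout the examples.
worked_3x2 <- function() {
  make_table(rbind(c(2, 1), c(1, 2), c(2, 2)),
             c("A1", "A2", "A3"), c("B1", "B2"))
}

# Random integral 2x2 table with all-positive marginals.
random_2x2 <- function() {
  repeat {
    m <- matrix(sample(0:20, 4, replace = TRUE), 2, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) &&
        sum(m) > 0) return(m)
  }
}
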