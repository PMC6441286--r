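# zassoc — directional Z association for contingency tables

`zassoc` is an R package for measuring how strongly one categorical variable
predicts another, when their joint behaviour is summarised in a k × n
contingency table. Typical users are biostatisticians and genomics analysts
working with co-occurrence matrices — the motivating application is a
mutated-genes × cancer-types count matrix, where one asks how well the
cancer type is determined by which genes are mutated (and vice versa).

## The statistic

For two partitions A₁…A_k (rows, the predicted variable) and B₁…B_n
(columns, the conditioning variable), with joint probabilities
p_ij, row marginals p_i· and column marginals p_·j, the squared Z
coefficient is

    Z²(A:B) = 1 − Σ_{i: p_i·>0}  p_i· · Π_{j: p_·j>0}  p_ij / (p_i· p_·j)

and Z = √max(Z², 0). Each factor p_ij/(p_i· p_·j) = P(A_i|B_j)/P(A_i) is an
(inverted) error-rate ratio: how much knowing B_j changes the odds of A_i.
Key properties, all enforced by the test suite:

- **Z = 0 at independence** (p_ij = p_i· p_·j) and **Z = 1 under functional
  dependency** (each column concentrated on one row).
- **Directional**: Z(A:B) ≠ Z(B:A) in general (except 2 × 2 tables); use
  `direction = "cols_given_rows"` or `transpose()` for the other direction.
- **Oracle identities**: Z equals Cramér's V on any table with two
  (effective) columns, and |φ| = |Pearson of the binary indicators| on
  2 × 2 tables.
- **Non-monotone under grouping**: merging categories can raise or lower Z.
- **Caveat found by the property sweep**: the raw Z² can be *negative* on
  some tables with 3+ columns (the advertised [0, 1] range has no proof and
  fails empirically); `z_coefficient()` then clamps to 0 and attaches an
  explicit warning. See the methods vignette.

Beyond the overall coefficient, the package computes **singular
coefficients**: for each cell (i, j), the Z of the 2 × 2 table formed by row
i and column j against the pooled remainder (`z_matrix()`), plus a ranked
list of the strongest row–column associations (`z_ranks()`). Either axis can
first be **collapsed** with an arbitrary category→group mapping (e.g. genes
→ pathway annotation groups). Seeded synthetic generators (`*_table()`,
`association_blend()`) produce tables with known association structure, and
classical measures (`phi()`, `cramers_v()`, `chi_squared()`,
`pearson_binary()`) are included as independent oracles.

## Worked example

```r
library(zassoc)
tab <- make_table(rbind(c(2, 1), c(1, 2), c(2, 2)),
                  c("A1", "A2", "A3"), c("B1", "B2"))
z_coefficient(tab)
#> Z = 0.258199  (rows_given_cols; 3 x 2 effective)
z_coefficient(tab, direction = "cols_given_rows")
#> Z = 0.333333  (cols_given_rows; 2 x 3 effective)
z_matrix(tab)
#> singular_z_matrix: 3 x 2
#>          B1       B2
#> A1 0.218218 0.218218
#> A2 0.218218 0.218218
#> A3 0.000000 0.000000
head(z_ranks(tab, top = 3))
#>   row_label col_label         z
#> 1        A1        B1 0.2182179
#> 2        A1        B2 0.2182179
#> 3        A2        B1 0.2182179
```

Reading: columns predict rows with Z = 0.258 (which here equals Cramér's V,
since the table has two columns); the reverse direction is stronger at
0.333 — the coefficient is directional. Per cell, distinguishing A1 or A2
against the pooled rest associates at 0.218 with either column, while A3 is
distributed exactly like the pooled remainder, hence 0. Grouping rows A1 and
A2 together collapses the table to an exact product and Z drops to 0:

```r
z_coefficient(tab, row_groups = c(A1 = "g1", A2 = "g1", A3 = "g2"))$z
#> [1] 0
```

## Command line

```sh
inst/exec/zassoc z inst/extdata/worked_table.tsv
# z=0.258199 z_squared_raw=0.066667 direction=rows_given_cols k_effective=3 n_effective=2 warnings=none
inst/exec/zassoc ranks inst/extdata/worked_table.tsv --top 2
inst/exec/zassoc simulate --kind dirichlet --k 4 --n 3 --seed 7 --total 100
```

Tables are TSV/CSV with a header row of column labels and a first column of
row labels; groupings are two-column files (category, group) without header.

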