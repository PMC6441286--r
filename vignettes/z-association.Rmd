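---
title: "The directional Z association coefficient: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The directional Z association coefficient: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zassoc)
```

## The model

Two categorical variables define two partitions of the same observations:
rows $A_1,\dots,A_k$ and columns $B_1,\dots,B_n$ of a contingency table,
with joint probabilities $p_{ij}$, row marginals $p_{i\cdot}$ and column
marginals $p_{\cdot j}$. The question the Z coefficient answers is
*directional*: how much does knowing the column category reduce the error
of predicting the row category?

The building block is the error-rate ratio
$(1 - P(A \mid B))/(1 - P(A))$: below 1 when conditioning on $B$ helps,
1 under independence, 0 when $B$ determines $A$. Aggregating over the whole
table — a marginal-weighted average over rows of products over columns of
the equivalent ratios $P(A_i \mid B_j)/P(A_i)$ — gives

$$Z^2(A{:}B) \;=\; 1 \;-\; \sum_{i:\,p_{i\cdot}>0} p_{i\cdot}
  \prod_{j:\,p_{\cdot j}>0} \frac{p_{ij}}{p_{i\cdot}\,p_{\cdot j}},
  \qquad Z = \sqrt{\max(Z^2, 0)}.$$

Under independence every product is 1, the sum telescopes to 1 and $Z = 0$.
When every column concentrates its mass on a single row (and at least two
rows carry mass), every product contains a zero factor and $Z = 1$. Rows
are the *predicted* partition: `z_coefficient(tab)` measures how well
columns predict rows, and `direction = "cols_given_rows"` (equivalently
`transpose()`) measures the reverse, which generally differs for tables
larger than $2\times 2$:

```{r asymmetry}
tab <- make_table(rbind(c(2, 1), c(1, 2), c(2, 2)),
                  c("A1", "A2", "A3"), c("B1", "B2"))
c(z_coefficient(tab)$z, z_coefficient(tab, direction = "cols_given_rows")$z)
```

This orientation convention was fixed by an identity, not by taste: with
rows predicted, Z coincides exactly with Cramér's V
$\sqrt{\chi^2/(N\min(k-1, n-1))}$ on every table with two (effective)
columns, and with $|\phi|$ (equivalently the absolute Pearson correlation
of the two binary indicator variables) on $2\times 2$ tables. These two
identities also adjudicated the formula itself: an *unweighted* average of
the row products fails the two-column identity and was rejected. Both are
enforced at $10^{-10}$ over a thousand random tables in the acceptance
suite, against independently coded oracles (`cramers_v()` built on the
plain $\chi^2$ statistic; `pearson_binary()` literally expands the table
into 0/1 observation pairs and calls `cor()`).

## Singular coefficients and ranked lists

For large sparse tables the overall coefficient hides *where* the
association lives. `z_matrix()` computes, for every cell $(i, j)$, the Z of
the $2\times 2$ table that isolates row $i$ and column $j$ against the
pooled remainder,
$$\begin{pmatrix} c_{ij} & r_i - c_{ij}\\ s_j - c_{ij} & T - r_i - s_j + c_{ij}\end{pmatrix},$$
which is symmetric (being $2\times 2$) and equals the $|\phi|$ of that
collapse. `z_ranks()` flattens the matrix into a list sorted by Z
descending; ties are broken by row index then column index so output order
is reproducible. Note that a functionally dependent table does *not*
guarantee unit singular entries: if a row carries several columns, pooling
the sibling columns dilutes the $2\times 2$ collapse (e.g. the assigned
cell of a two-columns-to-one-row block scores $0.5$, not $1$).

## Grouping

Either axis can be collapsed with a category→group mapping before any
computation (`collapse()`, or the `row_groups`/`col_groups` arguments
applied once, before singular-cell enumeration). Group order is the first
appearance of each group along the original axis — deterministic under any
mapping-file order. Coverage is strict: a mapping must name exactly the
axis's labels (positional vectors/factors of matching length are also
accepted). Z is deliberately *not* monotone under grouping — merging
categories can raise or lower it — so grouped and ungrouped analyses are
complementary, not redundant:

```{r grouping}
pre  <- rbind(c(18, 18, 4), c(7, 7, 46))    # merge columns 1,2: Z drops
post <- rbind(c(36, 4), c(14, 46))
c(z_coefficient(pre)$z, z_coefficient(post)$z)
```

## Tunable parameters

* `direction` (`"rows_given_cols"` default): which partition is predicted.
  There is no natural default for a given data set — for a genes × cancer
  types matrix both directions are scientifically meaningful — so results
  should state the direction used.
* `row_groups` / `col_groups`: optional category→group maps (unitless
  labels). Default `NULL` (no collapsing).
* Generator parameters (all unitless): marginal probability vectors and
  `total` (target count sum, default 100 in the CLI — the order of a small
  cohort); Dirichlet `concentration` (1 = uniform over the cell-probability
  simplex, the neutral choice for property sweeps; large values approach
  the uniform table); blend weight `epsilon` in $[0,1]$, which for
  uniform-marginal $2\times 2$ endpoints equals Z exactly.
* Every stochastic generator takes an explicit `seed` and restores the
  caller's RNG state: no hidden global randomness.

## What the synthetic generators emulate — and what they do not

`independent_table()` (exact product or multinomial draws),
`functional_table()` (column→row assignment), `dirichlet_table()` (random
simplex draws) and `association_blend()` (convex interpolation between an
independent base and a functional target) realise the coefficient's
boundary and intermediate regimes with *known* structure. They are the
stated world of the test suite: a green suite establishes the algebraic
contracts (identities, invariances, boundary values, monotone blend dial)
on such tables. They do not emulate real mutation matrices — no
overdispersion beyond multinomial noise, no structural zeros from
unobserved gene–cancer pairs, no row/column size imbalance of real cohorts
— so a green suite says nothing about sampling variability or significance
on biological data. No null distribution is provided for Z (none is known),
hence no p-values anywhere.

## Numerical choices

* **Zero marginals**: empty rows are skipped from the sum and empty columns
  from every product — appending an all-zero category never changes Z (this
  is an exact invariance, tested). The $\chi^2$-based oracles instead
  require `drop_empty()` first, mirroring the same policy explicitly.
* **Degenerate shapes**: an effective $1\times n$ or $k\times 1$ table
  yields $Z = 0$ with a warning — there is nothing to predict, or nothing
  to condition on; this agrees with the formula's limit.
* **Clamping**: $Z^2$ in $[-10^{-9}, 0)$ is floating-point noise and is
  clamped silently; anything below $-10^{-9}$ is clamped *with a warning*
  in the result object (see Limits below).
* **Tolerances**: oracle identities at $10^{-10}$ absolute; normalisation
  and independence checks at $10^{-12}$ on the squared scale (the square
  root maps $\sim 10^{-16}$ summation residue to $\sim 10^{-8}$ on Z, so
  exactness statements live on $Z^2$).
* **Ties in ranked output**: Z descending, then row index, then column
  index.
* **Weights, not counts**: any non-negative reals are accepted; only
  `pearson_binary()` requires integral counts (it physically expands the
  table).

## Limits: the range of Z² is not what it is said to be

The coefficient is commonly described as ranging over $[0, 1]$, but no
proof exists for tables with three or more columns — and the randomised
range sweep in this package's acceptance suite *disproves* it: on 10,000
random Dirichlet tables up to $8\times 8$, 58 had raw $Z^2 < -10^{-9}$,
the worst near $-2.95$ (a $2\times 5$ table at concentration $0.5$),
confirmed in exact rational arithmetic by an independent oracle. The
products of conditional-to-marginal ratios can jointly exceed 1 by far when
several columns favour the same row. Consequently:

* the corresponding acceptance test is intentionally left failing — it
  reports the violation count and the worst case rather than hiding them;
* `z_coefficient()` clamps such values to $Z = 0$ and attaches a warning,
  so user-facing output stays in $[0, 1]$ but never silently;
* comparisons of Z across different table shapes should be made with care:
  besides its unknown sampling distribution, the statistic's effective
  floor depends on the shape.

Other known limitations: no significance testing, confidence intervals or
bias correction (out of scope by design); heatmap rendering is left to
downstream tools (`z_matrix()` emits the TSV that such plots would
consume); and the published cancer-mutation reproduction requires an
external data set that is not redistributed with the package
(`scripts/fetch_cancer_data.R` documents its origin and the orientation
ambiguity of the original example calls).
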