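test_that("error_rate_ratio matches its definition and guards its domain", {
  expect_equal(error_rate_ratio(0.8, 0.5), 0.4)
  expect_equal(error_rate_ratio(1.0, 0.5), 0.0)
  for (p in c(0, 0.2, 0.5, 0.99)) {
    expect_equal(error_rate_ratio(p, p), 1.0)
  }
  expect_error(error_rate_ratio(0.5, 1), class = "zassoc_error_degenerate")
  expect_error(error_rate_ratio(1.2, 0.5), class = "zassoc_error_probability")
})

test_that("row_term reproduces hand computations", {
  d <- normalize(worked_3x2())
  expect_equal(row_term(d, 3), 0.4, tolerance = 1e-12)
  expect_equal(row_term(d, 1), 0.3 * (4 / 3) * (2 / 3), tolerance = 1e-12)
  expect_equal(row_term(normalize(make_table(rbind(c(5, 0), c(0, 5)))), 1), 0)
  expect_error(row_term(normalize(make_table(rbind(c(1, 1), c(0, 0)))), 2),
               class = "zassoc_error_degenerate")
})

test_that("z_squared matches oracle values on worked tables", {
  expect_equal(z_squared(make_table(rbind(c(3, 2), c(1, 4)))), 1 / 6,
               tolerance = 1e-12)
  expect_equal(z_squared(worked_3x2()), oracle_cramers_v(unclass(worked_3x2()))^2,
               tolerance = 1e-10)
  expect_equal(z_squared(make_table(rbind(c(2, 1, 2), c(1, 2, 2)))), 1 / 9,
               tolerance = 1e-12)
  exact_product <- make_table(100 * outer(c(0.3, 0.7), c(0.4, 0.6)))
  expect_equal(z_squared(exact_product), 0, tolerance = 1e-12)
})

test_that("z_coefficient reproduces the worked examples", {
  expect_equal(z_coefficient(rbind(c(3, 2), c(1, 4)))$z, 10 / sqrt(600),
               tolerance = 1e-10)
  expect_equal(z_coefficient(worked_3x2())$z, sqrt(1 / 15),
               tolerance = 1e-10)
  expect_equal(z_coefficient(worked_3x2(), direction = "cols_given_rows")$z,
               1 / 3, tolerance = 1e-10)
  expect_equal(z_coefficient(rbind(c(5, 0), c(0, 5)))$z, 1)

  res <- z_coefficient(matrix(c(3, 7), ncol = 1))
  expect_equal(res$z, 0)
  expect_length(res$warnings, 1)
  res2 <- z_coefficient(matrix(c(3, 7), nrow = 1))
  expect_equal(res2$z, 0)
  expect_length(res2$warnings, 1)
})

test_that("grouping before computation equals precollapsed computation", {
  tab <- worked_3x2()
  g <- grouping_map(c(A1 = "g1", A2 = "g1", A3 = "g2"), "rows")
  expect_identical(z_coefficient(tab, row_groups = g)$z,
                   z_coefficient(collapse(tab, g))$z)
  # the collapsed [[3,3],[2,2]] is an exact product: independence
  expect_equal(z_coefficient(tab, row_groups = g)$z, 0, tolerance = 1e-12)
})

test_that("asymmetry witness: transposing changes the coefficient", {
  z_ab <- z_coefficient(worked_3x2())$z
  z_ba <- z_coefficient(transpose(worked_3x2()))$z
  expect_equal(z_ab, sqrt(1 / 15), tolerance = 1e-10)
  expect_equal(z_ba, 1 / 3, tolerance = 1e-10)
  expect_gt(abs(z_ab - z_ba), 0.07)
  # direction flag is the same thing as transposing
  expect_identical(z_coefficient(worked_3x2(),
                                 direction = "cols_given_rows")$z, z_ba)
})

test_that("merging categories can raise or lower the coefficient", {
  # row merge that increases Z (oracle-frozen values)
  pre_up <- make_table(rbind(c(2, 2, 26), c(4, 4, 22), c(94, 94, 52)),
                       c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  post_up <- collapse(pre_up,
                      grouping_map(c(A1 = "g", A2 = "g", A3 = "h"), "rows"))
  z_pre_up <- z_coefficient(pre_up)$z
  z_post_up <- z_coefficient(post_up)$z
  expect_equal(z_pre_up, sqrt(0.236475), tolerance = 1e-10)
  expect_equal(z_post_up, sqrt(0.238875), tolerance = 1e-10)
  expect_gt(z_post_up, z_pre_up)

  # column merge that decreases Z
  pre_dn <- make_table(rbind(c(18, 18, 4), c(7, 7, 46)),
                       c("A1", "A2"), c("B1", "B2", "B3"))
  post_dn <- collapse(pre_dn,
                      grouping_map(c(B1 = "m", B2 = "m", B3 = "s"), "cols"))
  z_pre_dn <- z_coefficient(pre_dn)$z
  z_post_dn <- z_coefficient(post_dn)$z
  expect_equal(z_pre_dn, sqrt(608 / 1125), tolerance = 1e-10)
  expect_equal(z_post_dn, 1600 / sqrt(6e6), tolerance = 1e-10)
  expect_lt(z_post_dn, z_pre_dn)
})

test_that("z is invariant to scaling, permutation and empty categories", {
  set.seed(11)
  for (rep in 1:20) {
    tab <- dirichlet_table(sample(2:6, 1), sample(2:6, 1), 1, 100,
                           seed = 1000 + rep)
    z0 <- z_coefficient(tab)$z

    # count scaling (powers of two rescale exactly in binary floating point)
    for (c in c(0.25, 8, 2^20)) {
      expect_identical(z_coefficient(unclass(tab) * c)$z, z0)
    }
    expect_equal(z_coefficient(unclass(tab) * 7)$z, z0, tolerance = 1e-12)

    # row/column permutation (with labels)
    pr <- sample(nrow(tab))
    pc <- sample(ncol(tab))
    perm <- make_table(unclass(tab)[pr, pc, drop = FALSE],
                       rownames(tab)[pr], colnames(tab)[pc])
    expect_equal(z_coefficient(perm)$z, z0, tolerance = 1e-12)

    # appending an all-zero row and column
    padded <- make_table(
      cbind(rbind(unclass(tab), 0), 0),
      c(rownames(tab), "empty_row"), c(colnames(tab), "empty_col"))
    expect_equal(z_coefficient(padded)$z, z0, tolerance = 1e-15)
    expect_equal(z_coefficient(padded)$k_effective, nrow(tab))
    expect_equal(z_coefficient(padded)$n_effective, ncol(tab))
  }
})

test_that("z equals Cramer's V on random two-column tables", {
  for (s in 1:50) {
    k <- 2 + (s %% 9)
    tab <- dirichlet_table(k, 2, 1, 50, seed = s)
    expect_equal(z_coefficient(tab)$z, oracle_cramers_v(unclass(tab)),
                 tolerance = 1e-10)
  }
})
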