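test_that("independent_table realises exact and sampled independence", {
  it <- independent_table(c(0.3, 0.7), c(0.4, 0.6), 100)
  expect_equal(unname(unclass(it)), rbind(c(12, 18), c(28, 42)))
  expect_equal(z_coefficient(it)$z, 0, tolerance = 1e-12)

  u <- independent_table(rep(1 / 3, 3), rep(1 / 3, 3), 90)
  expect_equal(unname(unclass(u)), matrix(10, 3, 3))
  expect_equal(z_coefficient(u)$z, 0, tolerance = 1e-12)

  mt <- independent_table(c(0.3, 0.7), c(0.4, 0.6), 1e6,
                          mode = "multinomial", seed = 9)
  expect_equal(sum(mt), 1e6)
  expect_lt(z_coefficient(mt)$z, 0.01)  # consistency: z -> 0 as total grows

  expect_error(independent_table(c(0.3, 0.6), c(0.5, 0.5), 10),
               class = "zassoc_error_probability")
  expect_error(independent_table(c(0.5, 0.5), c(0.5, 0.5), 10,
                                 mode = "multinomial"),
               class = "zassoc_error_type")
})

test_that("functional_table has Z = 1 and unit singular hits", {
  ft <- functional_table(c(1, 2), c(0.5, 0.5), 10)
  expect_equal(unname(unclass(ft)), rbind(c(5, 0), c(0, 5)))
  expect_equal(z_coefficient(ft)$z, 1)

  ft2 <- functional_table(c(1, 1, 2), rep(1 / 3, 3), 30)
  expect_equal(unname(unclass(ft2)), rbind(c(10, 10, 0), c(0, 0, 10)))
  expect_equal(z_coefficient(ft2)$z, 1)
  # singular entries equal the phi oracle of each collapse; the assigned
  # cell is only perfect when its row carries a single column (pooling the
  # sibling column of row 1 leaves a 0.5 association)
  zm <- unclass(z_matrix(ft2))
  for (j in 1:3) {
    i <- c(1, 1, 2)[j]
    expect_equal(zm[i, j], abs(oracle_phi(unclass(singular_table(ft2, i, j)))),
                 tolerance = 1e-10)
  }
  expect_equal(zm[2, 3], 1)
  expect_equal(zm[1, 1], 0.5)

  # bijective assignment: every assigned cell is a perfect 2x2
  ft3 <- functional_table(c(1, 2, 3), rep(1 / 3, 3), 30)
  zm3 <- unclass(z_matrix(ft3))
  for (j in 1:3) expect_equal(zm3[j, j], 1)

  expect_error(functional_table(c(1, 1), c(0.5, 0.5), 10),
               class = "zassoc_error_degenerate")
})

test_that("dirichlet_table is seed-reproducible, valid and limits to uniform", {
  a <- dirichlet_table(5, 4, 1, 200, seed = 123)
  b <- dirichlet_table(5, 4, 1, 200, seed = 123)
  expect_identical(unclass(a), unclass(b))
  expect_s3_class(a, "contingency_table")
  expect_equal(sum(a), 200, tolerance = 1e-9)
  expect_true(all(unclass(a) >= 0))

  # huge concentration: near-uniform cells, hence near-independence
  flat <- dirichlet_table(4, 4, 1e4, 1, seed = 5)
  expect_lt(z_coefficient(flat)$z, 0.05)

  expect_error(dirichlet_table(1, 3, 1, 10, seed = 1),
               class = "zassoc_error_dimension")
  expect_error(dirichlet_table(2, 2, -1, 10, seed = 1),
               class = "zassoc_error_probability")
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(dirichlet_table(3, 3, 1, 10, seed = 7))
  invisible(independent_table(c(0.5, 0.5), c(0.5, 0.5), 10,
                              mode = "multinomial", seed = 8))
  expect_identical(.Random.seed, before)
})

test_that("association_blend interpolates from z = 0 to z = 1", {
  base <- independent_table(c(0.5, 0.5), c(0.5, 0.5), 1)
  target <- functional_table(c(1, 2), c(0.5, 0.5), 1)
  eps <- seq(0, 1, by = 0.1)
  z <- vapply(eps,
              function(e) z_coefficient(association_blend(e, base, target,
                                                          100))$z,
              numeric(1))
  # uniform-marginal 2x2 endpoints: the dial is exact, z = epsilon
  expect_equal(z, eps, tolerance = 1e-10)
  expect_false(is.unsorted(z))

  # monotone in epsilon for a larger pair of endpoints too
  base3 <- independent_table(rep(1 / 3, 3), rep(1 / 3, 3), 1)
  target3 <- functional_table(c(1, 2, 3), rep(1 / 3, 3), 1)
  dimnames_match <- identical(dimnames(base3), dimnames(target3))
  expect_true(dimnames_match)
  z3 <- vapply(eps,
               function(e) z_coefficient(association_blend(e, base3, target3,
                                                           90))$z,
               numeric(1))
  expect_false(is.unsorted(z3))
  expect_equal(z3[1], 0, tolerance = 1e-12)
  expect_equal(z3[11], 1)

  expect_error(association_blend(1.5, base, target, 10),
               class = "zassoc_error_probability")
  expect_error(association_blend(0.5, base, target3, 10),
               class = "zassoc_error_dimension")
})
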