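test_that("Fisher p-values equal the enumeration oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-10)
  expect_message(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)),
                 "zero margin")
  expect_identical(p0, 1)

  set.seed(314)
  for (i in 1:200) {
    tab <- matrix(sample(0:50, 4, TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("allele-frequency comparison builds correct 2x2 calls", {
  af_a <- data.frame(allele_id = c("rs1", "rs2", "rs3"),
                     population = "viet", alt_count = c(100L, 10L, 5L),
                     total_count = 200L,
                     af = c(0.5, 0.05, 0.025))
  af_b <- af_a
  af_b$population <- "global"
  cmp <- compare_allele_frequencies(af_a, af_b)
  expect_true(all(cmp$p_value == 1))
  expect_false(any(cmp$significant))

  af_b2 <- af_b
  af_b2$alt_count <- c(0L, 10L, 5L)
  af_b2$af <- af_b2$alt_count / af_b2$total_count
  cmp2 <- compare_allele_frequencies(af_a, af_b2, alpha = 0.05)
  expect_true(cmp2$significant[cmp2$allele_id == "rs1"])
  expect_false(cmp2$significant[cmp2$allele_id == "rs2"])

  # alpha = 1 makes every record significant (p is always <= 1 < boundary
  # handled as p < alpha, so use records with p < 1)
  cmp3 <- compare_allele_frequencies(af_a, af_b2, alpha = 1)
  expect_true(all(cmp3$significant[cmp3$p_value < 1]))

  # unmatched alleles are skipped and reported
  expect_message(
    cmp4 <- compare_allele_frequencies(af_a[1:2, ], af_b),
    "only one table")
  expect_identical(cmp4$allele_id, c("rs1", "rs2"))
  expect_identical(attr(cmp4, "unmatched"), "rs3")

  # Benjamini-Hochberg flagging behind the explicit flag
  cmp5 <- compare_allele_frequencies(af_a, af_b2, alpha = 0.05,
                                     p_adjust = TRUE)
  expect_identical(cmp5$p_value, cmp2$p_value)
})

test_that("Weir-Cockerham components match hand-evaluated formulas", {
  # pop_a dosages {0,1}; pop_b dosages {2,1}: frozen symbolic evaluation
  comp <- wc_fst_components(alt_count_a = 1, het_count_a = 1, n_a = 2,
                            alt_count_b = 3, het_count_b = 1, n_b = 2)
  expect_equal(unname(comp), c(0.0625, 0, 0.25), tolerance = 1e-12)

  # fixed difference: per-site ratio exactly 1
  cf <- wc_fst_components(20, 0, 10, 0, 0, 10)
  expect_equal(cf[["a"]] / sum(cf), 1)

  # identical populations: no among-population variance, ratio <= 0
  ci <- wc_fst_components(7, 5, 12, 7, 5, 12)
  expect_lte(ci[["a"]] / sum(ci), 1e-12)
})

test_that("weighted Fst behaves on degenerate and symmetric panels", {
  sim <- simulate_populations(2000, c(a = 60), F = 0, seed = 17)
  co <- sim$cohorts$a
  co2 <- co
  co2$population <- "a_copy"
  r <- suppressMessages(weighted_fst(co, co2))
  expect_lt(abs(r$weighted_fst), 0.01)

  # all-fixed-difference panel: weighted Fst exactly 1
  d_a <- matrix(2L, nrow = 8, ncol = 30)
  d_b <- matrix(0L, nrow = 8, ncol = 30)
  ca <- make_cohort(d_a, population = "a")
  cb <- make_cohort(d_b, population = "b")
  expect_identical(weighted_fst(ca, cb)$weighted_fst, 1)

  # symmetry in the pair
  sim2 <- simulate_populations(500, c(x = 30, y = 30), F = 0.1, seed = 5)
  r_xy <- suppressMessages(weighted_fst(sim2$cohorts$x, sim2$cohorts$y))
  r_yx <- suppressMessages(weighted_fst(sim2$cohorts$y, sim2$cohorts$x))
  expect_equal(r_xy$weighted_fst, r_yx$weighted_fst)

  # ref/alt label swap leaves every component unchanged
  sw <- make_cohort(2L - sim2$cohorts$x$dosage, population = "x_swap")
  co_y_sw <- make_cohort(2L - sim2$cohorts$y$dosage, population = "y_swap")
  r_sw <- suppressMessages(weighted_fst(sw, co_y_sw))
  expect_equal(r_sw$components$a, r_xy$components$a)
  expect_equal(r_sw$weighted_fst, r_xy$weighted_fst)

  # zero retained variants is an error naming the cause
  mono_a <- make_cohort(matrix(0L, 4, 5), population = "m1")
  mono_b <- make_cohort(matrix(0L, 4, 5), population = "m2")
  expect_error(suppressMessages(weighted_fst(mono_a, mono_b)),
               "zero retained")
})

test_that("missing genotypes enter via observed per-population counts", {
  d_a <- matrix(c(0L, 1L, 2L, NA), ncol = 1)
  d_b <- matrix(c(2L, 2L, 1L, 1L), ncol = 1)
  ca <- make_cohort(d_a, population = "a")
  cb <- make_cohort(d_b, population = "b")
  r <- weighted_fst(ca, cb)
  manual <- wc_fst_components(3, 1, 3, 6, 2, 4)
  expect_equal(r$components$a, manual[["a"]])
  expect_equal(r$weighted_fst, manual[["a"]] / sum(manual))
})

test_that("Balding-Nichols divergence is recovered within 0.02", {
  for (Ftrue in c(0.05, 0.2)) {
    sim <- simulate_populations(4000, c(a = 300, b = 300), F = Ftrue,
                                seed = 1000 + round(100 * Ftrue))
    r <- suppressMessages(weighted_fst(sim$cohorts$a, sim$cohorts$b))
    expect_lt(abs(r$weighted_fst - Ftrue), 0.02)
  }
})

test_that("fst_matrix is symmetric with zero diagonal and order-invariant", {
  sim <- simulate_populations(600, c(a = 25, b = 25, c = 25), F = 0.1,
                              seed = 77)
  m <- suppressMessages(fst_matrix(sim$cohorts))
  expect_identical(m$matrix, t(m$matrix))
  expect_identical(unname(diag(m$matrix)), c(0, 0, 0))
  expect_identical(nrow(m$pairs), 3L)
  perm <- sim$cohorts[c("c", "a", "b")]
  m2 <- suppressMessages(fst_matrix(perm))
  expect_equal(m2$matrix[rownames(m$matrix), colnames(m$matrix)],
               m$matrix)
})
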