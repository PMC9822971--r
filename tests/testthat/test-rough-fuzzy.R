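hand_table <- function() {
  tab <- vec_table(c(10, 10, 20, 20), c(0, 0, 1, 1), 2)
  u <- fixed_membership(cbind(c(0.9, 0.9, 0.2, 0.2), c(0.1, 0.1, 0.8, 0.8)))
  cb <- extract_candidate_breakpoints(tab)
  list(tab = tab, u = u, cb = cb)
}

test_that("interval index counts selected cuts strictly below the value", {
  s1 <- discretization_scheme(10, TRUE)
  expect_identical(interval_index(10, s1), 0L)
  expect_identical(interval_index(11, s1), 1L)
  s3 <- discretization_scheme(c(10, 20, 30), rep(TRUE, 3))
  expect_identical(interval_index(25, s3), 2L)
  expect_identical(interval_index(c(5, 10, 15, 20, 35), s3), c(0L, 0L, 1L, 1L, 3L))
  ## selecting k cuts yields k+1 interval labels on a spanning grid
  expect_identical(sort(unique(interval_index(0:40, s3))), 0:3)
})

test_that("hand-worked approximation: precisions, eta_bar, and cut recovery", {
  h <- hand_table()
  ap <- approximate_rough_fuzzy(h$u, h$tab, discretization_scheme(h$cb, c(FALSE, FALSE)))
  expect_equal(ap$precision, c(0.8 / 3.6, 0.4 / 3.2), tolerance = 1e-12)
  expect_equal(ap$eta_bar, mean(c(0.8 / 3.6, 0.4 / 3.2)), tolerance = 1e-12)
  ## one cut at 10 separates the groups exactly: inf == sup everywhere
  ap2 <- approximate_rough_fuzzy(h$u, h$tab, discretization_scheme(h$cb, c(TRUE, FALSE)))
  expect_equal(ap2$lower, ap2$upper)
  expect_equal(ap2$eta_bar, 1)
})

test_that("all-selected scheme gives eta_bar exactly 1", {
  for (seed in 1:3) {
    inst <- random_instance(seed, N = 80, n_values = 10, M = 3)
    s <- discretization_scheme(inst$candidates, rep(TRUE, inst$candidates$n))
    expect_identical(eta_bar(inst$u, inst$table, s), 1)
  }
})

test_that("the fuzzy set lies between its approximations", {
  inst <- random_instance(4, N = 120, n_values = 9, M = 3)
  s <- discretization_scheme(inst$candidates,
                             runif(inst$candidates$n) < 0.4)
  ap <- approximate_rough_fuzzy(inst$u, inst$table, s)
  A <- t(inst$u$u)
  expect_true(all(ap$lower <= A + 1e-12))
  expect_true(all(A <= ap$upper + 1e-12))
  expect_true(all(ap$card_lower <= ap$card_upper))
})

test_that("grouped computation matches the pairwise-relation oracle", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 100, N = sample(40:200, 1),
                            n_values = sample(5:12, 1), M = sample(2:3, 1))
    sel <- runif(inst$candidates$n) < 0.5
    s <- discretization_scheme(inst$candidates, sel)
    ap <- approximate_rough_fuzzy(inst$u, inst$table, s)
    o <- naive_rough_fuzzy(inst$u$u, inst$table, s)
    expect_equal(ap$lower, o$lower, tolerance = 1e-12)
    expect_equal(ap$upper, o$upper, tolerance = 1e-12)
    expect_equal(ap$eta_bar, o$eta, tolerance = 1e-12)
    expect_equal(eta_bar(inst$u, inst$table, s), o$eta, tolerance = 1e-12)
  }
})

test_that("per-slice equivalence classes do not cross slices", {
  ## two slices with identical brightness but different memberships would be
  ## mixed by a pooled relation; the per-slice eta must treat them apart
  b <- c(10, 20, 10, 20)
  tab <- vec_table(b, c(0, 1, 0, 1), 2, per_slice = TRUE,
                   slice_id = c(1L, 1L, 2L, 2L))
  u <- fixed_membership(cbind(c(0.9, 0.2, 0.9, 0.2), c(0.1, 0.8, 0.1, 0.8)))
  s <- discretization_scheme(extract_candidate_breakpoints(tab), c(TRUE, FALSE))
  expect_equal(eta_bar(u, tab, s), 1)
  o <- naive_rough_fuzzy(u$u, tab, s)
  expect_equal(o$eta, 1)
})

test_that("refinement monotonicity: more cuts never hurt the approximation", {
  set.seed(99)
  inst <- random_instance(77, N = 150, n_values = 10, M = 3)
  n <- inst$candidates$n
  for (rep in 1:25) {
    s1_bits <- runif(n) < 0.4
    s2_bits <- s1_bits | (runif(n) < 0.4)   # superset of cuts
    s1 <- discretization_scheme(inst$candidates, s1_bits)
    s2 <- discretization_scheme(inst$candidates, s2_bits)
    ap1 <- approximate_rough_fuzzy(inst$u, inst$table, s1)
    ap2 <- approximate_rough_fuzzy(inst$u, inst$table, s2)
    expect_true(all(ap2$lower >= ap1$lower - 1e-12))
    expect_true(all(ap2$upper <= ap1$upper + 1e-12))
    expect_gte(ap2$eta_bar, ap1$eta_bar - 1e-12)
    expect_lte(data_inconsistency(inst$table, s2),
               data_inconsistency(inst$table, s1) + 1e-12)
  }
})

test_that("data inconsistency counts pixels in label-mixed classes", {
  tab <- vec_table(c(10, 10, 20, 20), c(0, 0, 1, 1), 2)
  cb <- extract_candidate_breakpoints(tab)
  expect_equal(data_inconsistency(tab, discretization_scheme(cb, c(TRUE, FALSE))), 0)
  expect_equal(data_inconsistency(tab, discretization_scheme(cb, c(FALSE, FALSE))), 1)
  ## identical brightness, different labels: irreducible under any scheme
  tab2 <- vec_table(c(10, 10), c(0, 1), 2)
  cb2 <- extract_candidate_breakpoints(tab2)
  expect_equal(data_inconsistency(tab2, discretization_scheme(cb2, TRUE)), 1)
})
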