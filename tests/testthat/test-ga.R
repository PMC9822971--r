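worked_example <- function() {
  tab <- vec_table(c(10, 10, 20, 20), c(0, 0, 1, 1), 2)
  u <- fixed_membership(cbind(c(0.9, 0.9, 0.2, 0.2), c(0.1, 0.1, 0.8, 0.8)))
  list(tab = tab, u = u, cb = extract_candidate_breakpoints(tab))
}

test_that("fitness trades breakpoint parsimony against precision", {
  w <- worked_example()
  s10 <- discretization_scheme(w$cb, c(TRUE, FALSE))
  s_empty <- discretization_scheme(w$cb, c(FALSE, FALSE))
  s_full <- discretization_scheme(w$cb, c(TRUE, TRUE))
  expect_equal(scheme_fitness(s10, w$u, w$tab), 0.75, tolerance = 1e-12)
  expect_equal(scheme_fitness(s_empty, w$u, w$tab),
               0.5 + 0.5 * mean(c(0.8 / 3.6, 0.4 / 3.2)), tolerance = 1e-12)
  expect_equal(scheme_fitness(s_full, w$u, w$tab), 0.5, tolerance = 1e-12)
  expect_error(scheme_fitness(s10, w$u, w$tab, alpha = 0.7, beta = 0.5),
               class = "rfdseg_validation_error")
})

test_that("fitness of the all-selected scheme is exactly beta", {
  for (seed in 1:3) {
    inst <- random_instance(seed + 30, N = 60, n_values = 7, M = 2)
    s <- discretization_scheme(inst$candidates, rep(TRUE, inst$candidates$n))
    for (beta in c(0.3, 0.5, 0.9))
      expect_equal(scheme_fitness(s, inst$u, inst$table, 1 - beta, beta), beta,
                   tolerance = 1e-12)
  }
})

test_that("the GA recovers the enumerated optimum on the worked example", {
  w <- worked_example()
  ex <- exhaustive_discretize(w$tab, w$u)
  expect_equal(ex$best_fitness, 0.75, tolerance = 1e-12)
  expect_identical(ex$best_scheme$selected, c(TRUE, FALSE))
  for (seed in c(1, 7, 99)) {
    r <- ga_discretize(w$tab, w$u, w$cb,
                       ga_config(population_size = 10, generations = 8, seed = seed))
    expect_equal(r$best_fitness, 0.75, tolerance = 1e-12)
    expect_identical(r$best_scheme$selected, c(TRUE, FALSE))
  }
})

test_that("beta = 0 reduces the search to breakpoint parsimony", {
  inst <- random_instance(55, N = 80, n_values = 9, M = 2)
  r <- ga_discretize(inst$table, inst$u, inst$candidates,
                     ga_config(alpha = 1, beta = 0, population_size = 12,
                               generations = 10, seed = 2))
  expect_identical(sum(r$best_scheme$selected), 0L)
  expect_equal(r$best_fitness, 1)
})

test_that("GA matches exhaustive search on small instances, never exceeding it", {
  hits <- 0
  for (seed in 1:10) {
    inst <- random_instance(seed + 500, N = sample(40:120, 1),
                            n_values = sample(4:9, 1), M = sample(2:3, 1))
    ex <- exhaustive_discretize(inst$table, inst$u)
    r <- ga_discretize(inst$table, inst$u, inst$candidates,
                       ga_config(population_size = 24, generations = 25, seed = seed))
    expect_lte(r$best_fitness, ex$best_fitness + 1e-12)
    if (abs(r$best_fitness - ex$best_fitness) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("elitist history is monotone and reruns are bit-identical", {
  inst <- random_instance(21, N = 100, n_values = 10, M = 3)
  cfg <- ga_config(population_size = 16, generations = 15, seed = 13)
  r1 <- ga_discretize(inst$table, inst$u, inst$candidates, cfg)
  r2 <- ga_discretize(inst$table, inst$u, inst$candidates, cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$history) >= 0))
  expect_equal(r1$best_fitness, r1$history[length(r1$history)])
  ## never below the injected empty/full baselines
  base <- max(scheme_fitness(discretization_scheme(inst$candidates,
                                                   rep(FALSE, inst$candidates$n)),
                             inst$u, inst$table),
              scheme_fitness(discretization_scheme(inst$candidates,
                                                   rep(TRUE, inst$candidates$n)),
                             inst$u, inst$table))
  expect_gte(r1$best_fitness, base - 1e-12)
})

test_that("early stop triggers on reaching the fitness target", {
  w <- worked_example()
  r <- ga_discretize(w$tab, w$u, w$cb,
                     ga_config(population_size = 10, generations = 50,
                               fitness_target = 0.75, seed = 5))
  expect_true(r$stopped_early)
  expect_lt(r$generations_run, 50L)
})

test_that("scheme application replaces pixels by interval representatives", {
  s <- discretization_scheme(10, TRUE)
  expect_equal(apply_scheme(matrix(c(5, 10, 15), 1), s, encoding = "index"),
               matrix(c(0, 0, 1), 1))
  ## all-selected scheme with interval means reproduces the input (rescaled)
  tab <- vec_table(c(10, 10, 20, 20, 40), c(0, 0, 1, 1, 1), 2)
  cb <- extract_candidate_breakpoints(tab)
  s_all <- discretization_scheme(cb, rep(TRUE, cb$n))
  img <- matrix(c(10, 20, 40, 10), 2)
  out <- apply_scheme(img, s_all, encoding = "interval_mean", table = tab,
                      rescale = FALSE)
  expect_equal(out, img)
  ## empty scheme collapses everything to the grand mean
  s_none <- discretization_scheme(cb, rep(FALSE, cb$n))
  out2 <- apply_scheme(matrix(c(10, 10, 20, 20), 2), s_none,
                       encoding = "interval_mean", table = tab, rescale = FALSE)
  expect_equal(unique(as.numeric(out2)), mean(c(10, 10, 20, 20, 40)))
  expect_error(apply_scheme(img, s_all, encoding = "interval_mean"),
               class = "rfdseg_validation_error")
})
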