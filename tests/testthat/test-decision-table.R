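test_that("tables flatten pixels in row-major order with aligned labels", {
  img <- matrix(c(10, 10, 20, 20), 2, 2, byrow = TRUE)
  msk <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  tab <- build_decision_table(img, msk, num_classes = 2)
  expect_identical(tab$brightness, c(10, 10, 20, 20))
  expect_identical(tab$labels, c(0L, 0L, 1L, 1L))
  expect_identical(tab$value_range, c(0, 255))

  ## rebuilding from the same inputs is bit-identical (no RNG anywhere)
  expect_identical(tab, build_decision_table(img, msk, num_classes = 2))
})

test_that("contract violations are rejected with typed errors", {
  img <- matrix(0, 2, 2)
  expect_error(build_decision_table(img, matrix(0, 3, 2), 2),
               class = "rfdseg_structural_error")
  expect_error(build_decision_table(img, matrix(2, 2, 2), 2),
               class = "rfdseg_validation_error")  # label == M
  expect_error(build_decision_table(array(0, c(0, 2, 2)), array(0, c(0, 2, 2)), 2),
               class = "rfdseg_validation_error")
  expect_error(build_decision_table(img, matrix(0.5, 2, 2), 2),
               class = "rfdseg_validation_error")
})

test_that("per-slice tables record slice ids for every pixel", {
  vol <- array(seq_len(48), c(3, 4, 4))
  msk <- array(0L, c(3, 4, 4))
  tab <- build_decision_table(vol, msk, 2, mode = "per_slice")
  expect_length(tab$brightness, 48)
  expect_identical(sort(unique(tab$slice_id)), 1:3)
  expect_identical(as.integer(table(tab$slice_id)), rep(16L, 3))
  ## slice scoping picks exactly that slice's values
  expect_setequal(tab$brightness[tab$slice_id == 2], as.numeric(vol[2, , ]))
})

test_that("candidate breakpoints are the sorted unique observed values", {
  tab <- vec_table(c(20, 10, 20, 10, 30), c(0, 0, 1, 1, 1), 2)
  cb <- extract_candidate_breakpoints(tab)
  expect_identical(cb$values, c(10, 20, 30))
  expect_identical(cb$n, 3L)

  ## constant slice: one candidate
  tab1 <- vec_table(rep(37, 9), rep(0, 9), 2)
  expect_identical(extract_candidate_breakpoints(tab1)$values, 37)

  ## full-dynamic-range 8-bit slice: 256 candidates
  img <- matrix(rep(0:255, length.out = 1024), 32, 32)
  tab256 <- build_decision_table(img, img * 0L, 2)
  expect_identical(extract_candidate_breakpoints(tab256)$n, 256L)
})

test_that("candidate extraction is idempotent and permutation-invariant", {
  set.seed(42)
  b <- sample(0:50, 200, replace = TRUE)
  tab <- vec_table(b, rep(0, 200), 2)
  perm <- sample(200)
  tabp <- vec_table(b[perm], rep(0, 200), 2)
  expect_identical(extract_candidate_breakpoints(tab)$values,
                   extract_candidate_breakpoints(tabp)$values)
})

test_that("per-slice totals follow the per-slice accounting", {
  ## slices with identical value sets still count separately per slice
  vol <- array(0, c(4, 4, 4))
  for (s in 1:4) vol[s, , ] <- matrix(0:15, 4, 4)
  tab <- build_decision_table(vol, array(0L, dim(vol)), 2, mode = "per_slice")
  acct <- count_candidates_per_slice(tab)
  expect_identical(unname(acct$per_slice), rep(16L, 4))
  expect_identical(acct$total, 64L)
  ## pooled whole-volume count collapses shared values
  tabw <- build_decision_table(vol, array(0L, dim(vol)), 2, mode = "whole_volume")
  expect_identical(extract_candidate_breakpoints(tabw)$n, 16L)

  ## disjoint per-slice values: per-slice total equals the pooled count
  vol2 <- vol
  for (s in 1:4) vol2[s, , ] <- matrix(0:15 + 16 * (s - 1), 4, 4)
  tab2 <- build_decision_table(vol2, array(0L, dim(vol2)), 2, mode = "per_slice")
  expect_identical(count_candidates_per_slice(tab2)$total, 64L)
  tab2w <- build_decision_table(vol2, array(0L, dim(vol2)), 2, mode = "whole_volume")
  expect_identical(extract_candidate_breakpoints(tab2w)$n, 64L)
})
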