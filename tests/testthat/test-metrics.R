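test_that("DSC overlap arithmetic and conventions", {
  a <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2)
  b <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 2)
  expect_equal(dsc(a, b), 0.5)          # |P|=|T|=4, overlap 2
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, 1 - a), 0)        # disjoint
  expect_equal(dsc(a * 0, a * 0), 1)    # both empty
  expect_equal(dsc(a, b), dsc(b, a))
  expect_error(dsc(a, matrix(0, 3, 3)), class = "rfdseg_structural_error")
})

test_that("growing the symmetric difference never increases DSC", {
  truth <- matrix(0, 10, 10); truth[3:7, 3:7] <- 1
  pred <- truth
  prev <- dsc(pred, truth)
  flip <- which(pred == truth)
  set.seed(1)
  for (i in sample(flip, 20)) {
    pred[i] <- 1 - pred[i]
    cur <- dsc(pred, truth)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("surface extraction keeps border and boundary voxels only", {
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
  sp <- surface_points(m)
  expect_identical(nrow(sp), 8L)                 # ring, centre excluded
  expect_false(any(sp[, 1] == 3 & sp[, 2] == 3))
  ## a region reaching the border is surface there; the centre of a full
  ## 3x3 block is the only non-surface voxel
  m2 <- matrix(1, 3, 3)
  sp2 <- surface_points(m2)
  expect_identical(nrow(sp2), 8L)
  expect_false(any(sp2[, 1] == 2 & sp2[, 2] == 2))
  ## 3D: 6-connectivity surface of a solid 3x3x3 cube leaves no interior
  a <- array(0, c(5, 5, 5)); a[2:4, 2:4, 2:4] <- 1
  expect_identical(nrow(surface_points(a)), 26L)
})

test_that("HD95 follows both the scaled-max and percentile conventions", {
  X <- rbind(c(0, 0)); Y <- rbind(c(0, 3))
  expect_equal(hd95(X, Y, mode = "paper"), 2.85)
  expect_equal(hd95(X, Y, mode = "percentile"), 3)
  expect_equal(hd95(X, X, mode = "paper"), 0)
  expect_equal(hd95(X, X, mode = "percentile"), 0)
  ## 1-voxel-thick segment translated by 4 along its axis: both directed
  ## maxima are 4, so the scaled-max form gives 3.8
  seg <- cbind(0, 0:6)
  expect_equal(hd95(seg, cbind(0, 0:6 + 4), mode = "paper"), 3.8)
  expect_error(hd95(matrix(numeric(0), 0, 2), Y),
               class = "rfdseg_validation_error")
})

test_that("ASD averages both directed distance sums", {
  X <- rbind(c(0, 0)); Y <- rbind(c(0, 3))
  expect_equal(asd(X, Y), 3)
  expect_equal(asd(X, X), 0)
  expect_equal(asd(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0))), 1 / 3)
  expect_equal(asd(X, Y), asd(Y, X))
})

test_that("blocked nearest-neighbour search matches the double-loop oracle", {
  set.seed(5)
  for (d in 2:3) {
    A <- matrix(sample(0:30, 500 * d, replace = TRUE), ncol = d)
    B <- matrix(sample(0:30, 400 * d, replace = TRUE), ncol = d)
    expect_equal(rfdseg:::nearest_distances(A, B), brute_nn(A, B),
                 tolerance = 1e-12)
    ## hd95/asd built on it agree with oracle-composed values
    dxy <- brute_nn(A, B); dyx <- brute_nn(B, A)
    expect_equal(hd95(A, B, mode = "paper"), 0.95 * max(max(dxy), max(dyx)))
    expect_equal(asd(A, B), (sum(dxy) + sum(dyx)) / (nrow(A) + nrow(B)))
  }
})

test_that("full evaluation: identity, shift, and absent-class handling", {
  truth <- matrix(0L, 8, 8); truth[3:5, 3:6] <- 1L
  rep0 <- evaluate_segmentation(truth, truth, 2)
  expect_equal(rep0$macro$dsc, 1)
  expect_equal(rep0$macro$hd95, 0)
  expect_equal(rep0$macro$asd, 0)
  expect_equal(rep0$macro$sensitivity, 1)
  expect_equal(rep0$macro$specificity, 1)

  ## one-voxel shift: DSC from overlap counts, surfaces enumerable by hand
  pred <- matrix(0L, 8, 8); pred[4:6, 3:6] <- 1L
  r <- evaluate_segmentation(pred, truth, 2)
  expect_equal(r$per_class$dsc[2], 2 * 8 / (12 + 12))
  ## every surface point of either rectangle is within 1 of the other
  sx <- surface_points(truth == 1L); sy <- surface_points(pred == 1L)
  expect_equal(r$per_class$asd[2],
               (sum(brute_nn(sx, sy)) + sum(brute_nn(sy, sx))) /
                 (nrow(sx) + nrow(sy)))
  expect_equal(r$per_class$hd95[2], 0.95 * 1)
  expect_equal(r$per_class$sensitivity[2], 8 / 12)

  ## class absent everywhere is skipped; background still perfect
  r2 <- evaluate_segmentation(matrix(0L, 4, 4), matrix(0L, 4, 4), 2)
  expect_identical(as.character(r2$skipped), "class1")
  expect_equal(r2$per_class$dsc[1], 1)
  expect_equal(r2$macro$dsc, 1)
})

test_that("physical spacing scales surface distances", {
  X <- rbind(c(0, 0)); Y <- rbind(c(0, 3))
  expect_equal(asd(X, Y, spacing = c(1, 0.5)), 1.5)
  expect_equal(hd95(X, Y, mode = "paper", spacing = c(2, 2)), 5.7)
})
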