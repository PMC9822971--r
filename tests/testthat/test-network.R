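tiny_config <- function(...) {
  network_config(num_classes = 3, depth = 2L, base_channels = 4L,
                 patch_size = c(4L, 4L, 4L), attention_feature_maps = 4L, ...)
}

test_that("encoder channels double per stage and clamp at max_channels", {
  cfg <- network_config(num_classes = 4, depth = 4L, base_channels = 16L,
                        max_channels = 128L, patch_size = c(64L, 64L, 64L))
  expect_identical(vapply(1:4, function(d) rfdseg:::stage_channels(cfg, d),
                          integer(1)), c(16L, 32L, 64L, 128L))
  cfg5 <- network_config(num_classes = 4, depth = 5L, base_channels = 16L,
                         max_channels = 128L, patch_size = c(16L, 16L, 16L))
  expect_identical(rfdseg:::stage_channels(cfg5, 5L), 128L)  # clamped
  ## parameter shapes follow the channel plan without any forward pass
  model <- build_network(cfg, seed = 1)
  expect_identical(dim(model$params[["enc4.c2.W"]]), c(27L * 128L, 128L))
  expect_identical(dim(model$params[["enc1.c1.W"]]), c(27L, 16L))
  expect_error(network_config(num_classes = 4, depth = 4L,
                              patch_size = c(60L, 64L, 64L)),
               class = "rfdseg_validation_error")
})

test_that("forward pass yields per-voxel probabilities summing to one", {
  model <- build_network(tiny_config(), seed = 2)
  x <- array(runif(64), c(4, 4, 4))
  out <- network_forward(model, x)
  expect_identical(dim(out$probs), c(64L, 3L))
  expect_true(all(is.finite(out$probs)))
  expect_equal(rowSums(out$probs), rep(1, 64), tolerance = 1e-12)
  expect_identical(dim(out$label), c(4L, 4L, 4L))
  expect_length(out$ds_probs, 1L)              # one decoder stage at depth 2
  expect_equal(rowSums(out$ds_probs[[1]]), rep(1, 64), tolerance = 1e-12)
  ## fixed seed, fixed input: bit-identical reruns
  model2 <- build_network(tiny_config(), seed = 2)
  out2 <- network_forward(model2, x)
  expect_identical(out$probs, out2$probs)
})

test_that("ablation flags reduce to a plain residual U-shape, same shapes", {
  cfg <- tiny_config(use_dual_attention = FALSE,
                     use_attention_refinement = FALSE,
                     use_deep_supervision = FALSE)
  model <- build_network(cfg, seed = 3)
  expect_false(any(grepl("^(dab|arb|ds)", ls(model$params))))
  out <- network_forward(model, array(runif(64), c(4, 4, 4)))
  expect_identical(dim(out$probs), c(64L, 3L))
  expect_length(out$ds_probs, 0L)
  expect_equal(rowSums(out$probs), rep(1, 64), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through every block", {
  set.seed(4)
  model <- build_network(tiny_config(), seed = 5)
  x <- array(runif(64), c(4, 4, 4))
  lab <- sample(0:2, 64, replace = TRUE)
  G <- rfdseg:::one_hot(lab, 3)
  lw <- loss_weights()
  cw <- inverse_frequency_weights(lab, 3)
  lossfun <- function() {
    fw <- rfdseg:::net_forward(model, matrix(as.numeric(x), ncol = 1), c(4L, 4L, 4L))
    list(fw = fw, cl = rfdseg:::composite_loss_grads(fw, G, lw, cw))
  }
  r <- lossfun()
  rfdseg:::ag_backward(r$fw$tape, r$cl$seeds)
  grads <- as.list(r$fw$tape$pgrads)
  eps <- 1e-6
  for (nm in c("enc1.c1.W", "dec1.c2.W", "dab1.fc2.W", "dab1.sp.W",
               "arb.k5.W", "head.n1.g", "ds1.W", "cls.b")) {
    p <- model$params[[nm]]
    for (j in sample(length(p), 2)) {
      orig <- p[j]
      model$params[[nm]][j] <- orig + eps; lp <- lossfun()$cl$loss
      model$params[[nm]][j] <- orig - eps; lm <- lossfun()$cl$loss
      model$params[[nm]][j] <- orig
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic and the lr schedule steps down", {
  ph <- suppressWarnings(generate_phantom(
    phantom_spec(shape = c(8L, 16L, 16L), seed = 3)))
  cfg <- network_config(num_classes = 4, depth = 2L, base_channels = 4L,
                        patch_size = c(8L, 8L, 8L), attention_feature_maps = 4L)
  tc <- train_config(lr = 0.01, grad_clip = Inf, lr_drop_points = c(2L, 4L),
                     iterations = 6L, seed = 9)
  r1 <- train_network(build_network(cfg, seed = 1), ph$volume, ph$mask, tc = tc)
  r2 <- train_network(build_network(cfg, seed = 1), ph$volume, ph$mask, tc = tc)
  expect_identical(r1$history, r2$history)
  expect_equal(r1$history$lr, 0.01 * c(1, 1, 0.1, 0.1, 0.01, 0.01))
  expect_true(all(is.finite(r1$history$loss)))
})

test_that("sliding-window prediction keeps probabilities normalized", {
  cfg <- network_config(num_classes = 3, depth = 2L, base_channels = 4L,
                        patch_size = c(8L, 8L, 8L), attention_feature_maps = 4L)
  model <- build_network(cfg, seed = 6)
  vol <- array(runif(12 * 12 * 12, 0, 255), c(12, 12, 12))  # overlapping windows
  p1 <- predict_volume(model, vol)
  expect_identical(dim(p1$probs), c(12L, 12L, 12L, 3L))
  sums <- apply(p1$probs, 1:3, sum)
  expect_equal(as.numeric(sums), rep(1, 12^3), tolerance = 1e-9)
  expect_true(all(p1$label %in% 0:2))
  ## deterministic for a fixed (untrained) model, even on constant input
  p2 <- predict_volume(model, vol)
  expect_identical(p1$probs, p2$probs)
  z <- predict_volume(model, array(0, c(8, 8, 8)))
  expect_identical(z$probs, predict_volume(model, array(0, c(8, 8, 8)))$probs)
})
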