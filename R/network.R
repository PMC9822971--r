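#' Network architecture configuration
#'
#' A compact 3D encoder-decoder: residual double-convolution blocks
#' (3x3x3 conv + batch norm + ReLU, residual shortcut), 2x2x2 max-pool
#' downsampling, nearest-neighbour upsampling, skip fusion through an
#' optional dual attention block (channel squeeze-gate + spatial gate),
#' an optional attention refinement block (parallel 3x3x3 and 5x5x5
#' "hybrid kernel" convolutions concatenated into `attention_feature_maps`
#' maps) before the two-convolution classifier head, and optional
#' deep-supervision heads (1x1x1 conv + upsampling to full resolution) at
#' every decoder stage. Encoder channels double per stage from
#' `base_channels`, clamped at `max_channels` (defaults 16 -> 128).
#'
#' @param num_classes number of output classes k.
#' @param in_channels input channels (1 for grayscale OCT).
#' @param base_channels first-stage channel count.
#' @param max_channels channel clamp.
#' @param depth number of encoder stages.
#' @param patch_size integer triple; must be divisible by `2^(depth-1)`.
#' @param use_dual_attention,use_attention_refinement,use_deep_supervision
#'   ablation toggles.
#' @param attention_feature_maps channels produced by the attention
#'   refinement block.
#' @return list of class `network_config`.
#' @export
network_config <- function(num_classes, in_channels = 1L, base_channels = 16L,
                           max_channels = 128L, depth = 4L,
                           patch_size = c(64L, 64L, 64L),
                           use_dual_attention = TRUE,
                           use_attention_refinement = TRUE,
                           use_deep_supervision = TRUE,
                           attention_feature_maps = 16L) {
  if (!is_count(num_classes) || num_classes < 2)
    stop_validation("num_classes must be an integer >= 2")
  if (!is_count(depth)) stop_validation("depth must be a positive integer")
  patch_size <- as.integer(patch_size)
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  if (any(patch_size %% 2L^(depth - 1L) != 0L))
    stop_validation("patch_size must be divisible by 2^(depth-1) = ", 2L^(depth - 1L))
  if (attention_feature_maps %% 2L != 0L)
    stop_validation("attention_feature_maps must be even")
  structure(list(num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 depth = as.integer(depth),
                 patch_size = patch_size,
                 use_dual_attention = use_dual_attention,
                 use_attention_refinement = use_attention_refinement,
                 use_deep_supervision = use_deep_supervision,
                 attention_feature_maps = as.integer(attention_feature_maps)),
            class = "network_config")
}

stage_channels <- function(config, d) {
  as.integer(min(config$base_channels * 2L^(d - 1L), config$max_channels))
}

#' Build (initialize) a segmentation network
#'
#' Allocates and He-initializes all parameters for the architecture
#' described in [network_config()]. The forward pass outputs a per-voxel
#' probability field over `num_classes` summing to 1.
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `rfdseg_network` (config + parameter list +
#'   geometry cache).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  params <- new.env(parent = emptyenv())
  with_seed(seed, {
    add_conv <- function(nm, cin, cout, k) {
      fan_in <- k^3 * cin
      params[[paste0(nm, ".W")]] <-
        matrix(rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)), k^3 * cin, cout)
      params[[paste0(nm, ".b")]] <- numeric(cout)
    }
    add_bn <- function(nm, c) {
      params[[paste0(nm, ".g")]] <- rep(1, c)
      params[[paste0(nm, ".b")]] <- numeric(c)
    }
    add_dense <- function(nm, cin, cout) {
      params[[paste0(nm, ".W")]] <-
        matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
      params[[paste0(nm, ".b")]] <- numeric(cout)
    }
    add_res <- function(nm, cin, cout) {
      add_conv(paste0(nm, ".c1"), cin, cout, 3L); add_bn(paste0(nm, ".n1"), cout)
      add_conv(paste0(nm, ".c2"), cout, cout, 3L); add_bn(paste0(nm, ".n2"), cout)
      if (cin != cout) add_conv(paste0(nm, ".proj"), cin, cout, 1L)
    }

    D <- config$depth
    add_res("enc1", config$in_channels, stage_channels(config, 1L))
    for (d in seq_len(D)[-1])
      add_res(paste0("enc", d), stage_channels(config, d - 1L), stage_channels(config, d))
    for (d in rev(seq_len(D - 1L))) {
      cs <- stage_channels(config, d)
      if (config$use_dual_attention) {
        hid <- max(cs %/% 4L, 4L)
        add_dense(paste0("dab", d, ".fc1"), cs, hid)
        add_dense(paste0("dab", d, ".fc2"), hid, cs)
        add_conv(paste0("dab", d, ".sp"), cs, 1L, 1L)
      }
      add_res(paste0("dec", d), cs + stage_channels(config, d + 1L), cs)
      if (config$use_deep_supervision)
        add_conv(paste0("ds", d), cs, config$num_classes, 1L)
    }
    c1 <- stage_channels(config, 1L)
    m <- if (config$use_attention_refinement) config$attention_feature_maps else c1
    if (config$use_attention_refinement) {
      add_conv("arb.k3", c1, m %/% 2L, 3L)
      add_conv("arb.k5", c1, m %/% 2L, 5L)
    }
    add_conv("head.c1", m, m, 3L); add_bn("head.n1", m)
    add_conv("head.c2", m, m, 3L); add_bn("head.n2", m)
    add_conv("cls", m, config$num_classes, 1L)
  })
  structure(list(config = config, params = params,
                 geom = new.env(parent = emptyenv()), seed = as.integer(seed)),
            class = "rfdseg_network")
}

#' @export
print.rfdseg_network <- function(x, ...) {
  np <- sum(vapply(ls(x$params), function(nm) length(x$params[[nm]]), numeric(1)))
  cfg <- x$config
  cat(sprintf("rfdseg_network: depth %d, channels %s, k = %d, %s parameters\n",
              cfg$depth,
              paste(vapply(seq_len(cfg$depth), function(d) stage_channels(cfg, d),
                           integer(1)), collapse = "-"),
              cfg$num_classes, format(np, big.mark = ",")))
  cat(sprintf("  dual attention: %s, attention refinement: %s, deep supervision: %s\n",
              cfg$use_dual_attention, cfg$use_attention_refinement,
              cfg$use_deep_supervision))
  invisible(x)
}

res_block <- function(tape, nm, x, dims, cin, cout) {
  y <- ag_conv3d(tape, x, paste0(nm, ".c1.W"), paste0(nm, ".c1.b"), dims, 3L)
  y <- ag_bn(tape, y, paste0(nm, ".n1.g"), paste0(nm, ".n1.b"))
  y <- ag_relu(tape, y)
  y <- ag_conv3d(tape, y, paste0(nm, ".c2.W"), paste0(nm, ".c2.b"), dims, 3L)
  y <- ag_bn(tape, y, paste0(nm, ".n2.g"), paste0(nm, ".n2.b"))
  sc <- if (cin != cout)
    ag_conv3d(tape, x, paste0(nm, ".proj.W"), paste0(nm, ".proj.b"), dims, 1L)
  else x
  ag_relu(tape, ag_add(tape, y, sc))
}

dual_attention_block <- function(tape, nm, s, dims) {
  g <- ag_gap(tape, s)
  g <- ag_relu(tape, ag_dense(tape, g, paste0(nm, ".fc1.W"), paste0(nm, ".fc1.b")))
  g <- ag_sigmoid(tape, ag_dense(tape, g, paste0(nm, ".fc2.W"), paste0(nm, ".fc2.b")))
  out <- ag_scale_channels(tape, s, g)
  sp <- ag_sigmoid(tape, ag_conv3d(tape, s, paste0(nm, ".sp.W"), paste0(nm, ".sp.b"),
                                   dims, 1L))
  ag_scale_spatial(tape, out, sp)
}

## Full forward pass on one patch. x_mat: N x in_channels matrix in
## column-major voxel order; dims: patch dims. Returns logits values
## (main + deep supervision heads) plus the tape.
net_forward <- function(model, x_mat, dims) {
  cfg <- model$config
  tape <- new_tape(model$params, model$geom)
  x <- ag_value(tape, x_mat)
  D <- cfg$depth
  dims_d <- lapply(seq_len(D), function(d) dims %/% (2L^(d - 1L)))

  enc <- vector("list", D)
  enc[[1]] <- res_block(tape, "enc1", x, dims_d[[1]],
                        cfg$in_channels, stage_channels(cfg, 1L))
  for (d in seq_len(D)[-1]) {
    pooled <- ag_maxpool(tape, enc[[d - 1L]], dims_d[[d - 1L]])
    enc[[d]] <- res_block(tape, paste0("enc", d), pooled, dims_d[[d]],
                          stage_channels(cfg, d - 1L), stage_channels(cfg, d))
  }

  cur <- enc[[D]]
  ds_logits <- list()
  for (d in rev(seq_len(D - 1L))) {
    cur <- ag_upsample(tape, cur, dims_d[[d + 1L]])
    s <- enc[[d]]
    if (cfg$use_dual_attention)
      s <- dual_attention_block(tape, paste0("dab", d), s, dims_d[[d]])
    cur <- res_block(tape, paste0("dec", d), ag_concat(tape, s, cur), dims_d[[d]],
                     stage_channels(cfg, d) + stage_channels(cfg, d + 1L),
                     stage_channels(cfg, d))
    if (cfg$use_deep_supervision) {
      h <- ag_conv3d(tape, cur, paste0("ds", d, ".W"), paste0("ds", d, ".b"),
                     dims_d[[d]], 1L)
      for (dd in seq_len(d - 1L)) h <- ag_upsample(tape, h, dims_d[[d - dd + 1L]])
      ds_logits[[length(ds_logits) + 1L]] <- h
    }
  }

  f <- cur
  if (cfg$use_attention_refinement) {
    a3 <- ag_conv3d(tape, f, "arb.k3.W", "arb.k3.b", dims_d[[1]], 3L)
    a5 <- ag_conv3d(tape, f, "arb.k5.W", "arb.k5.b", dims_d[[1]], 5L)
    f <- ag_concat(tape, a3, a5)
  }
  f <- ag_relu(tape, ag_bn(tape, ag_conv3d(tape, f, "head.c1.W", "head.c1.b",
                                           dims_d[[1]], 3L), "head.n1.g", "head.n1.b"))
  f <- ag_relu(tape, ag_bn(tape, ag_conv3d(tape, f, "head.c2.W", "head.c2.b",
                                           dims_d[[1]], 3L), "head.n2.g", "head.n2.b"))
  logits <- ag_conv3d(tape, f, "cls.W", "cls.b", dims_d[[1]], 1L)
  list(logits = logits, ds_logits = ds_logits, tape = tape)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the network on a single patch
#'
#' @param model a [build_network()] result.
#' @param patch numeric 3D array matching the model's input channels = 1.
#' @return list with `probs` (N x k matrix, rows sum to 1, column-major
#'   voxel order), `label` (integer array of argmax labels, ties to the
#'   lower index), and `ds_probs` (deep-supervision probabilities).
#' @export
network_forward <- function(model, patch) {
  stopifnot(inherits(model, "rfdseg_network"))
  dims <- dim(patch)
  if (length(dims) != 3L) stop_validation("patch must be a 3D array")
  fw <- net_forward(model, matrix(as.numeric(patch), ncol = 1L), dims)
  probs <- softmax_rows(fw$logits$mat)
  lab <- array(max.col(probs, ties.method = "first") - 1L, dims)
  list(probs = probs,
       label = lab,
       ds_probs = lapply(fw$ds_logits, function(v) softmax_rows(v$mat)))
}

## dZ (gradient wrt logits) of the composite loss, plus its value
composite_loss_grads <- function(fw, gold_onehot, lw, class_w) {
  P <- softmax_rows(fw$logits$mat)
  n <- nrow(P); k <- ncol(P)
  G <- gold_onehot
  eps <- lw$epsilon

  ## soft-Dice term
  S <- colSums(G * P); Q <- colSums(G + P)
  dLdp <- -(1 / k) * (sweep(2 * G, 2, Q + eps, `*`) -
                        matrix(2 * S + eps, n, k, byrow = TRUE)) /
    matrix((Q + eps)^2, n, k, byrow = TRUE)
  dZ_dsc <- P * (dLdp - rowSums(dLdp * P))
  l_dsc <- 1 - mean((2 * S + eps) / (Q + eps))

  ## plain CE on the main head
  dZ_ce <- (P - G) / n
  l_ce <- -sum(G * log(pmax(P, 1e-12))) / n

  seeds <- list()
  seeds[[as.character(fw$logits$id)]] <- lw$kappa * dZ_dsc + lw$gamma * dZ_ce
  total <- lw$kappa * l_dsc + lw$gamma * l_ce

  nh <- length(fw$ds_logits)
  if (lw$lambda > 0 && nh > 0) {
    l_max <- 0
    for (h in fw$ds_logits) {
      Ph <- softmax_rows(h$mat)
      s_v <- as.numeric(G %*% class_w)             # per-voxel gold weight
      dZ <- (Ph * s_v - sweep(G, 2, class_w, `*`)) / n
      seeds[[as.character(h$id)]] <- (lw$lambda / nh) * dZ
      l_max <- l_max - sum(sweep(G, 2, class_w, `*`) * log(pmax(Ph, 1e-12))) / n
    }
    total <- total + lw$lambda * l_max / nh
  }
  list(seeds = seeds, loss = total,
       parts = c(dsc = l_dsc, ce = l_ce))
}
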