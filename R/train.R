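#' Training configuration
#'
#' Mini-batch stochastic gradient descent with momentum, L2 weight decay,
#' global gradient-norm clipping and a step learning-rate schedule. The
#' defaults follow the reference optimizer settings (momentum 0.9, weight
#' decay 1e-4, gradient norm threshold 0.005, initial learning rate 1e-3,
#' x0.1 decay at the listed iterations); for desk-scale overfitting runs a
#' larger learning rate and a relaxed clip are appropriate, see
#' `toy_train_config()`.
#'
#' @param lr initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty on convolution/dense weights.
#' @param grad_clip global gradient-norm threshold (`Inf` disables).
#' @param lr_drop_points iterations after which lr is multiplied by 0.1.
#' @param batch_size patches per iteration.
#' @param iterations number of SGD iterations.
#' @param seed RNG seed for patch sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, momentum = 0.9, weight_decay = 1e-4,
                         grad_clip = 0.005, lr_drop_points = c(1000L, 2500L),
                         batch_size = 1L, iterations = 300L, seed = 1L) {
  if (lr <= 0 || momentum < 0 || momentum >= 1 || weight_decay < 0 || grad_clip <= 0)
    stop_validation("invalid optimizer settings")
  if (!is_count(batch_size) || !is_count(iterations))
    stop_validation("batch_size and iterations must be positive integers")
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 grad_clip = grad_clip, lr_drop_points = as.integer(lr_drop_points),
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "train_config")
}

#' Toy training configuration for desk-scale overfitting
#'
#' Single-phantom capacity checks on a CPU need larger steps than the
#' full-scale reference settings; this profile uses lr = 0.05 with no
#' gradient clipping and no lr drops.
#'
#' @param iterations,seed as in [train_config()].
#' @return a `train_config`.
#' @export
toy_train_config <- function(iterations = 300L, seed = 1L) {
  train_config(lr = 0.05, grad_clip = Inf, lr_drop_points = integer(0),
               iterations = iterations, seed = seed)
}

one_hot <- function(labels, k) {
  n <- length(labels)
  G <- matrix(0, n, k)
  G[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  G
}

## decay weights only (not BN scales/offsets or biases)
is_decayed <- function(nm) grepl("\\.W$", nm)

sgd_step <- function(model, pgrads, velocity, lr, tc) {
  nms <- ls(pgrads)
  ## global gradient norm over all parameter gradients
  sq <- 0
  for (nm in nms) sq <- sq + sum(pgrads[[nm]]^2)
  gnorm <- sqrt(sq)
  scale <- if (is.finite(tc$grad_clip) && gnorm > tc$grad_clip)
    tc$grad_clip / gnorm else 1
  for (nm in nms) {
    g <- pgrads[[nm]] * scale
    if (tc$weight_decay > 0 && is_decayed(nm))
      g <- g + tc$weight_decay * model$params[[nm]]
    v <- velocity[[nm]]
    if (is.null(v)) v <- 0 * g
    v <- tc$momentum * v - lr * g
    velocity[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] + v
  }
  gnorm
}

#' Train the segmentation network
#'
#' SGD with momentum on the composite loss. Each iteration samples a random
#' patch position from a random volume (volumes equal to the patch size are
#' used whole). When a discretization scheme is supplied the inputs pass
#' through [apply_scheme()] (interval-mean encoding rescaled to `[0, 1]`)
#' before entering the network, mirroring the discretization pre-module;
#' otherwise raw intensities are rescaled to `[0, 1]`.
#'
#' @param model a [build_network()] result (updated in place and returned).
#' @param volumes list of 3D arrays (or a single array).
#' @param masks matching list of integer label arrays.
#' @param scheme optional [discretization_scheme()].
#' @param table decision table used to fit `scheme` (required with it).
#' @param tc a [train_config()].
#' @param lw a [loss_weights()]; `class_weights = NULL` means
#'   inverse-frequency weights computed per batch.
#' @return list of class `training_run`: `model`, `history` (data frame of
#'   iteration, loss, lr, grad_norm), `tc`, `lw`.
#' @export
train_network <- function(model, volumes, masks, scheme = NULL, table = NULL,
                          tc = train_config(), lw = loss_weights()) {
  stopifnot(inherits(model, "rfdseg_network"), inherits(tc, "train_config"),
            inherits(lw, "loss_weights"))
  if (is.array(volumes) || is.matrix(volumes)) volumes <- list(volumes)
  if (is.array(masks) || is.matrix(masks)) masks <- list(masks)
  if (length(volumes) == 0L) stop_validation("empty dataset")
  if (length(volumes) != length(masks)) stop_structural("volumes/masks length mismatch")
  if (!is.null(scheme) && is.null(table))
    stop_validation("a fitting table is required with a scheme")
  cfg <- model$config
  ps <- cfg$patch_size
  k <- cfg$num_classes

  prep <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    if (any(dim(v) < ps)) stop_validation("volume ", i, " smaller than patch size")
    x <- if (!is.null(scheme))
      apply_scheme(v, scheme, encoding = "interval_mean", table = table)
    else v / 255
    list(x = x, m = masks[[i]])
  })

  velocity <- new.env(parent = emptyenv())
  hist <- data.frame(iteration = integer(0), loss = numeric(0),
                     lr = numeric(0), grad_norm = numeric(0))

  with_seed(tc$seed, {
    lr <- tc$lr
    for (it in seq_len(tc$iterations)) {
      if (it %in% (tc$lr_drop_points + 1L)) lr <- lr * 0.1
      acc <- new.env(parent = emptyenv())
      loss_acc <- 0
      for (b in seq_len(tc$batch_size)) {
        i <- if (length(prep) == 1L) 1L else sample.int(length(prep), 1L)
        dmv <- dim(prep[[i]]$x)
        off <- vapply(1:3, function(a)
          if (dmv[a] == ps[a]) 0L else sample.int(dmv[a] - ps[a] + 1L, 1L) - 1L,
          integer(1))
        sel <- lapply(1:3, function(a) (off[a] + 1L):(off[a] + ps[a]))
        xp <- prep[[i]]$x[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
        mp <- prep[[i]]$m[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
        G <- one_hot(as.integer(mp), k)
        cw <- lw$class_weights %||% inverse_frequency_weights(as.integer(mp), k)

        fw <- net_forward(model, matrix(as.numeric(xp), ncol = 1L), ps)
        cl <- composite_loss_grads(fw, G, lw, cw)
        loss_acc <- loss_acc + cl$loss
        ag_backward(fw$tape, cl$seeds)
        for (nm in ls(fw$tape$pgrads)) {
          cur <- acc[[nm]]
          g <- fw$tape$pgrads[[nm]] / tc$batch_size
          acc[[nm]] <- if (is.null(cur)) g else cur + g
        }
      }
      gnorm <- sgd_step(model, acc, velocity, lr, tc)
      hist[nrow(hist) + 1L, ] <- list(it, loss_acc / tc$batch_size, lr, gnorm)
    }
  })
  structure(list(model = model, history = hist, tc = tc, lw = lw),
            class = "training_run")
}

#' Predict a full volume by sliding-window inference
#'
#' Patches of the model's patch size are tiled with 50% overlap;
#' probabilities are averaged in overlaps (and therefore still sum to 1 per
#' voxel). Volumes smaller than the patch are zero-padded and cropped back.
#' The label mask is the per-voxel argmax with ties broken toward the lower
#' class index.
#'
#' @param model trained [build_network()] model.
#' @param volume 3D array of raw brightness (0-255).
#' @param scheme,table optional discretization pre-module as in
#'   [train_network()].
#' @return list with `probs` (4D array D x H x W x k) and `label` (integer
#'   array).
#' @export
predict_volume <- function(model, volume, scheme = NULL, table = NULL) {
  stopifnot(inherits(model, "rfdseg_network"))
  if (!is.null(scheme) && is.null(table))
    stop_validation("a fitting table is required with a scheme")
  x <- if (!is.null(scheme))
    apply_scheme(volume, scheme, encoding = "interval_mean", table = table)
  else volume / 255
  dims <- dim(x)
  ps <- model$config$patch_size
  k <- model$config$num_classes

  padded <- pmax(dims, ps)
  xp <- array(0, padded)
  xp[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- x

  starts <- function(total, p) {
    if (total == p) return(1L)
    s <- seq(1L, total - p + 1L, by = max(p %/% 2L, 1L))
    if (s[length(s)] != total - p + 1L) s <- c(s, total - p + 1L)
    unique(s)
  }
  acc <- array(0, c(padded, k))
  cnt <- array(0, padded)
  for (sd in starts(padded[1], ps[1]))
    for (sh in starts(padded[2], ps[2]))
      for (sw in starts(padded[3], ps[3])) {
        sel <- list(sd:(sd + ps[1] - 1L), sh:(sh + ps[2] - 1L), sw:(sw + ps[3] - 1L))
        patch <- xp[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
        fw <- net_forward(model, matrix(as.numeric(patch), ncol = 1L), ps)
        pr <- softmax_rows(fw$logits$mat)
        for (j in seq_len(k))
          acc[sel[[1]], sel[[2]], sel[[3]], j] <-
            acc[sel[[1]], sel[[2]], sel[[3]], j] + array(pr[, j], ps)
        cnt[sel[[1]], sel[[2]], sel[[3]]] <- cnt[sel[[1]], sel[[2]], sel[[3]]] + 1
      }
  for (j in seq_len(k)) acc[, , , j] <- acc[, , , j] / cnt
  probs <- acc[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), , drop = FALSE]
  flat <- matrix(probs, prod(dims), k)
  label <- array(max.col(flat, ties.method = "first") - 1L, dims)
  list(probs = probs, label = label)
}
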