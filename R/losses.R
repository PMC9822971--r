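#' Loss weighting hyperparameters
#'
#' `kappa`, `gamma`, `lambda` balance the Dice, cross-entropy and
#' deep-supervision terms of the composite loss (defaults 1, 1, 0.5);
#' `class_weights` enter only the deep-supervision cross-entropy; `epsilon`
#' guards the Dice ratios against empty classes.
#'
#' @param kappa,gamma,lambda non-negative term weights.
#' @param class_weights optional k-vector of class weights for the
#'   deep-supervision branch; `NULL` means inverse-frequency weights
#'   computed per batch (normalized to mean 1 over present classes).
#' @param epsilon small positive Dice stabilizer.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(kappa = 1, gamma = 1, lambda = 0.5,
                         class_weights = NULL, epsilon = 1e-5) {
  if (any(c(kappa, gamma, lambda) < 0)) stop_validation("loss weights must be non-negative")
  if (epsilon <= 0) stop_validation("epsilon must be > 0")
  structure(list(kappa = kappa, gamma = gamma, lambda = lambda,
                 class_weights = class_weights, epsilon = epsilon),
            class = "loss_weights")
}

## coerce probability/one-hot inputs (N x k matrices or k-vectors) and check
as_prob_matrix <- function(x, name) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.matrix(x)) x <- matrix(x, ncol = dim(x)[length(dim(x))])
  storage.mode(x) <- "double"
  x
}

check_aligned <- function(probs, gold) {
  if (!all(dim(probs) == dim(gold)))
    stop_structural("probability and gold shapes differ")
}

#' Weighted cross-entropy (deep-supervision branch loss)
#'
#' `-sum_i w_i g_i log(p_i)` per voxel, averaged over voxels; probabilities
#' are floored at 1e-12 before the log.
#'
#' @param probs N x k matrix of class probabilities (rows sum to 1) or a
#'   single k-vector.
#' @param gold matching one-hot gold standard.
#' @param weights k class weights (default all 1).
#' @return scalar loss.
#' @examples
#' weighted_ce(c(0.8, 0.2), c(1, 0), c(1, 2))  # -log 0.8
#' @export
weighted_ce <- function(probs, gold, weights = NULL) {
  probs <- as_prob_matrix(probs); gold <- as_prob_matrix(gold)
  check_aligned(probs, gold)
  w <- weights %||% rep(1, ncol(probs))
  p <- pmax(probs, 1e-12)
  -sum(t(gold * log(p)) * w) / nrow(probs)
}

#' Soft Dice loss
#'
#' `1 - (1/k) sum_j (2 S_j + eps) / (Q_j + eps)` with `S_j = sum_v g p` and
#' `Q_j = sum_v (g + p)` aggregated over the spatial domain per class; empty
#' classes contribute eps/eps = 1 (no penalty).
#'
#' @inheritParams weighted_ce
#' @param epsilon stabilizer.
#' @return scalar in `[0, 1]`.
#' @export
dsc_loss <- function(probs, gold, epsilon = 1e-5) {
  probs <- as_prob_matrix(probs); gold <- as_prob_matrix(gold)
  check_aligned(probs, gold)
  S <- colSums(gold * probs)
  Q <- colSums(gold + probs)
  1 - mean((2 * S + epsilon) / (Q + epsilon))
}

#' Composite segmentation loss
#'
#' `kappa * L_DSC(main) + gamma * L_CE(main) + lambda * L_max(supervision)`
#' where `L_CE` is unweighted cross-entropy on the main head and `L_max` is
#' class-weighted cross-entropy averaged over the deep-supervision heads.
#'
#' @param probs main-head probabilities (N x k).
#' @param ds_probs list of deep-supervision probability matrices at the gold
#'   resolution (may be empty; a single matrix is accepted).
#' @param gold one-hot gold standard.
#' @param lw a [loss_weights()].
#' @return scalar total loss.
#' @export
total_loss <- function(probs, ds_probs, gold, lw = loss_weights()) {
  stopifnot(inherits(lw, "loss_weights"))
  if (is.matrix(ds_probs) || (is.numeric(ds_probs) && is.null(dim(ds_probs))))
    ds_probs <- list(ds_probs)
  gold_m <- as_prob_matrix(gold)
  w <- lw$class_weights %||% rep(1, ncol(gold_m))
  l <- lw$kappa * dsc_loss(probs, gold, lw$epsilon) +
    lw$gamma * weighted_ce(probs, gold)
  if (lw$lambda > 0 && length(ds_probs) > 0) {
    lmax <- mean(vapply(ds_probs, weighted_ce, numeric(1), gold = gold, weights = w))
    l <- l + lw$lambda * lmax
  }
  l
}

#' Inverse-frequency class weights
#'
#' Weights proportional to inverse class frequency in a label field,
#' normalized to mean 1 over present classes; absent classes get weight 0
#' (their gold indicator is identically zero).
#'
#' @param labels integer labels `0..k-1`.
#' @param k number of classes.
#' @return numeric k-vector.
#' @export
inverse_frequency_weights <- function(labels, k) {
  cnt <- tabulate(as.integer(labels) + 1L, nbins = k)
  w <- numeric(k)
  present <- cnt > 0
  w[present] <- 1 / cnt[present]
  w[present] <- w[present] / mean(w[present])
  w
}
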