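## Independent brute-force oracles and fixture builders used across tests.

## decision table straight from vectors (single slice)
vec_table <- function(brightness, labels, M = max(labels) + 1L,
                      per_slice = FALSE, slice_id = NULL) {
  tab <- build_decision_table(matrix(brightness, nrow = 1),
                              matrix(labels, nrow = 1), M,
                              mode = "whole_volume")
  if (per_slice) {
    tab$slice_id <- slice_id %||% rep.int(1L, length(brightness))
    tab$mode <- "per_slice"
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## membership container with fixed rows (bypasses FCM)
fixed_membership <- function(u) {
  structure(list(u = u), class = "membership_matrix")
}

## random table with value-dependent random memberships: membership rows are
## drawn per unique brightness value and broadcast to pixels
random_instance <- function(seed, N = 100, n_values = 8, M = 2) {
  set.seed(seed)
  pool <- sort(sample(0:255, n_values))
  brightness <- sample(pool, N, replace = TRUE)
  ## make sure every pool value is observed
  brightness[seq_len(n_values)] <- pool
  labels <- sample(0:(M - 1), N, replace = TRUE)
  tab <- vec_table(brightness, labels, M)
  uv <- sort(unique(brightness))
  uu <- matrix(runif(length(uv) * M), length(uv), M)
  uu <- uu / rowSums(uu)
  u <- fixed_membership(uu[match(brightness, uv), , drop = FALSE])
  list(table = tab, u = u, candidates = extract_candidate_breakpoints(tab))
}

## naive per-pixel FCM (fuzzifier 2), iterated exactly `iters` times from
## the given initial centers; written independently of the package
naive_fcm <- function(x, centers, iters) {
  mem <- function(x, cc) {
    u <- matrix(0, length(x), length(cc))
    for (i in seq_along(x)) {
      d2 <- (x[i] - cc)^2
      if (any(d2 == 0)) u[i, ] <- (d2 == 0) / sum(d2 == 0)
      else u[i, ] <- (1 / d2) / sum(1 / d2)
    }
    u
  }
  u <- mem(x, centers)
  for (t in seq_len(iters)) {
    centers <- vapply(seq_along(centers), function(j)
      sum(u[, j]^2 * x) / sum(u[, j]^2), numeric(1))
    u <- mem(x, centers)
  }
  list(u = u, centers = centers)
}

## naive pairwise rough-fuzzy oracle: scans all pixel pairs under the
## equivalence relation (same interval, same slice)
naive_rough_fuzzy <- function(u_mat, table, scheme) {
  N <- length(table$brightness)
  M <- ncol(u_mat)
  slice <- table$slice_id %||% rep.int(1L, N)
  iv <- interval_index(table$brightness, scheme)
  lower <- matrix(0, M, N); upper <- matrix(0, M, N)
  for (x in seq_len(N)) {
    cls <- which(slice == slice[x] & iv == iv[x])
    for (j in seq_len(M)) {
      lower[j, x] <- min(u_mat[cls, j])
      upper[j, x] <- max(u_mat[cls, j])
    }
  }
  ## sigma-counts pooled per slice, eta as pixel-weighted mean over slices
  etas <- c(); ns <- c()
  for (s in unique(slice)) {
    px <- which(slice == s)
    prec <- vapply(seq_len(M), function(j) {
      cu <- sum(upper[j, px])
      if (cu == 0) 1 else sum(lower[j, px]) / cu
    }, numeric(1))
    etas <- c(etas, mean(prec)); ns <- c(ns, length(px))
  }
  list(lower = lower, upper = upper, eta = sum(etas * ns) / N)
}

## plain double-loop nearest-neighbour distances
brute_nn <- function(A, B) {
  apply(A, 1, function(a) min(sqrt(colSums((t(B) - a)^2))))
}
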