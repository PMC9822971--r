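#' Fuzzy c-means configuration
#'
#' @param epsilon termination threshold on the largest absolute membership
#'   change between consecutive iterations.
#' @param max_iter iteration cap.
#' @param init `"quantile"` places initial centers at the (j+0.5)/M quantiles
#'   of the brightness distribution (deterministic); `"random"` draws M
#'   distinct observed values under `seed`.
#' @param seed RNG seed, used only by random init.
#' @return list of class `fcm_config`.
#' @export
fcm_config <- function(epsilon = 1e-5, max_iter = 300L,
                       init = c("quantile", "random"), seed = 1L) {
  init <- match.arg(init)
  if (!is.numeric(epsilon) || epsilon <= 0) stop_validation("epsilon must be > 0")
  if (!is_count(max_iter)) stop_validation("max_iter must be a positive integer")
  structure(list(epsilon = epsilon, max_iter = as.integer(max_iter),
                 init = init, seed = as.integer(seed)),
            class = "fcm_config")
}

#' Membership of values to class centers (fuzzifier m = 2)
#'
#' For pixel brightness x and centers c_j the membership is
#' `u_ij = 1 / sum_k ((x_i - c_j) / (x_i - c_k))^2`, i.e. inverse squared
#' distance normalized across centers. A value coinciding with one or more
#' centers gets membership 1 split equally among the coincident centers
#' (the FCM singularity convention, keeping rows stochastic).
#'
#' @param values numeric vector of brightness values.
#' @param centers numeric vector of M pairwise-distinct class centers.
#' @return N x M row-stochastic matrix of memberships in `[0, 1]`.
#' @examples
#' compute_memberships(1, c(0, 3))  # (0.8, 0.2)
#' @export
compute_memberships <- function(values, centers) {
  if (length(values) == 0L) stop_validation("empty values")
  if (anyDuplicated(centers)) stop_validation("centers must be pairwise distinct")
  M <- length(centers)
  if (M < 2) stop_validation("need at least 2 centers")
  d2 <- outer(values, centers, `-`)^2          # N x M
  sing <- d2 == 0
  inv <- 1 / d2
  u <- inv / rowSums(inv)
  bad <- rowSums(sing) > 0
  if (any(bad)) {
    u[bad, ] <- sing[bad, , drop = FALSE] / rowSums(sing[bad, , drop = FALSE])
  }
  u
}

#' Update class centers from memberships (m = 2)
#'
#' `c_j = sum_i u_ij^2 x_i / sum_i u_ij^2`, optionally with per-value counts
#' when operating on unique brightness values.
#'
#' @param values numeric vector.
#' @param u row-stochastic membership matrix aligned with `values`.
#' @param weights optional non-negative per-value multiplicities.
#' @return numeric vector of M updated centers.
#' @export
update_centers <- function(values, u, weights = NULL) {
  if (!is.matrix(u) || nrow(u) != length(values))
    stop_structural("u must be an N x M matrix aligned with values")
  w <- if (is.null(weights)) rep(1, length(values)) else weights
  u2 <- u^2 * w
  denom <- colSums(u2)
  zero <- which(denom == 0)
  if (length(zero))
    stop_validation("degenerate cluster: column ", zero[1],
                    " has all-zero membership")
  colSums(u2 * values) / denom
}

#' Run fuzzy c-means on a decision table
#'
#' Alternates membership and center updates until the largest membership
#' change falls below `epsilon` or `max_iter` is reached. Because membership
#' depends on brightness only, the iteration runs on the unique brightness
#' values weighted by their pixel counts and the final rows are broadcast
#' back to pixels; this is exactly the per-pixel computation (same
#' arithmetic on the same reals) at a fraction of the cost.
#'
#' @param table a [build_decision_table()] result (M taken from it).
#' @param config an [fcm_config()].
#' @return object of class `membership_matrix`: `u` (N x M, pixel order of
#'   the table), `centers`, `iterations`, `converged`, `unique_values`,
#'   `unique_u` (per-unique-value rows used internally).
#' @export
run_fcm <- function(table, config = fcm_config()) {
  stopifnot(inherits(table, "decision_table"), inherits(config, "fcm_config"))
  M <- table$num_classes
  x <- table$brightness
  uv <- sort(unique(x))
  cnt <- as.numeric(tabulate(match(x, uv), nbins = length(uv)))
  if (length(uv) < M)
    stop_validation("degenerate input: ", length(uv),
                    " distinct brightness values < M = ", M)

  centers <- init_centers(x, uv, M, config)
  u <- compute_memberships(uv, centers)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    centers <- update_centers(uv, u, weights = cnt)
    ## coincident updated centers can only arise in pathological ties; nudge
    if (anyDuplicated(centers)) centers <- centers + seq_len(M) * 1e-9
    u_new <- compute_memberships(uv, centers)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < config$epsilon) { converged <- TRUE; break }
  }

  rows <- match(x, uv)
  structure(list(
    u = u[rows, , drop = FALSE],
    centers = centers,
    iterations = iter,
    converged = converged,
    unique_values = uv,
    unique_u = u,
    counts = cnt
  ), class = "membership_matrix")
}

init_centers <- function(x, uv, M, config) {
  if (config$init == "quantile") {
    c0 <- unname(quantile(x, probs = (seq_len(M) - 0.5) / M, type = 7))
    if (anyDuplicated(c0)) {
      ## heavily tied data: fall back to evenly spaced unique values
      idx <- unique(round(seq(1, length(uv), length.out = M)))
      c0 <- uv[idx]
    }
  } else {
    c0 <- with_seed(config$seed, sample(uv, M))
  }
  sort(c0)
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("membership_matrix: %d pixels x %d classes, %d iterations (%s)\n",
              nrow(x$u), ncol(x$u), x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat("  centers:", paste(signif(x$centers, 6), collapse = ", "), "\n")
  invisible(x)
}

#' FCM objective (m = 2)
#'
#' `sum_ij u_ij^2 (x_i - c_j)^2`; non-increasing across full FCM iterations.
#' @param values,u,centers as in [update_centers()].
#' @param weights optional multiplicities.
#' @return scalar objective value.
#' @export
fcm_objective <- function(values, u, centers, weights = NULL) {
  w <- if (is.null(weights)) rep(1, length(values)) else weights
  d2 <- outer(values, centers, `-`)^2
  sum(w * u^2 * d2)
}
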