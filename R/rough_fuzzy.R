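#' Discretization scheme over a candidate breakpoint set
#'
#' A scheme is a binary selection over the candidate breakpoints: selecting
#' k cuts partitions the brightness axis into k+1 half-open intervals
#' `(-Inf, s1], (s1, s2], ..., (sk, Inf)`. The intervals induce the
#' equivalence relation on pixels used by the rough-fuzzy approximations.
#'
#' @param candidates a [extract_candidate_breakpoints()] result (or a sorted
#'   numeric vector of candidate values).
#' @param selected logical/0-1 vector of the same length, TRUE = cut kept.
#' @return object of class `discretization_scheme` with `candidates`,
#'   `selected` (logical), `cuts` (selected breakpoint values).
#' @export
discretization_scheme <- function(candidates, selected) {
  if (is.numeric(candidates) && !inherits(candidates, "candidate_breakpoints"))
    candidates <- structure(list(values = as.numeric(candidates),
                                 n = length(candidates)),
                            class = "candidate_breakpoints")
  stopifnot(inherits(candidates, "candidate_breakpoints"))
  selected <- as.logical(selected)
  if (length(selected) != candidates$n)
    stop_structural("selected has length ", length(selected),
                    " but there are ", candidates$n, " candidates")
  structure(list(candidates = candidates,
                 selected = selected,
                 cuts = candidates$values[selected]),
            class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat(sprintf("discretization_scheme: %d/%d breakpoints selected (%d intervals)\n",
              sum(x$selected), x$candidates$n, sum(x$selected) + 1L))
  invisible(x)
}

#' Interval index of brightness values under a scheme
#'
#' Returns, for each value, the number of selected breakpoints strictly
#' below it; a breakpoint s separates `v <= s` from `v > s`.
#'
#' @param values numeric vector.
#' @param scheme a [discretization_scheme()].
#' @return integer vector of 0-based interval indices.
#' @examples
#' s <- discretization_scheme(c(10, 20, 30), c(TRUE, TRUE, TRUE))
#' interval_index(c(10, 11, 25), s)  # 0 1 2
#' @export
interval_index <- function(values, scheme) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  if (length(scheme$cuts) == 0L) return(rep.int(0L, length(values)))
  findInterval(values, scheme$cuts, left.open = TRUE)
}

## Fast grouped eta-bar + per-class sigma-counts on one slice scope.
## uv/cnt/u are the unique brightness values of the scope, their pixel
## counts, and their membership rows.
eta_scope <- function(uv, cnt, u, scheme) {
  g <- interval_index(uv, scheme)
  M <- ncol(u)
  card_lower <- numeric(M); card_upper <- numeric(M)
  for (j in seq_len(M)) {
    lo <- tapply(u[, j], g, min)
    hi <- tapply(u[, j], g, max)
    n_g <- tapply(cnt, g, sum)
    card_lower[j] <- sum(lo * n_g)
    card_upper[j] <- sum(hi * n_g)
  }
  precision <- ifelse(card_upper == 0, 1, card_lower / card_upper)
  list(card_lower = card_lower, card_upper = card_upper,
       precision = precision, eta = mean(precision), n = sum(cnt))
}

#' Rough-fuzzy approximation of category fuzzy sets under a scheme
#'
#' Each category j is the fuzzy set `A_j(i) = u_ij`. Under the equivalence
#' relation induced by the scheme's intervals (restricted to one slice in
#' per-slice tables), the lower/upper approximations at pixel x are the
#' inf/sup of A_j over x's equivalence class. Cardinalities are sigma-counts
#' (sums of membership), the per-class precision is
#' `card(lower) / card(upper)` (1 when the upper sigma-count is 0), and the
#' average approximate precision eta_bar is the mean over classes. For a
#' per-slice table the volume eta_bar is the pixel-weighted mean of
#' per-slice values. Computation is grouped per interval over unique
#' brightness values and broadcast back, never a pairwise pixel scan.
#'
#' @param u a [run_fcm()] result aligned with `table`.
#' @param table the decision table.
#' @param scheme a [discretization_scheme()].
#' @return object of class `rough_fuzzy_approximation`: `lower`, `upper`
#'   (M x N), `card_lower`, `card_upper`, `precision` (per class, pooled
#'   over slices for reporting), `eta_bar`, `per_slice` (data frame of
#'   per-slice eta when applicable).
#' @export
approximate_rough_fuzzy <- function(u, table, scheme) {
  stopifnot(inherits(u, "membership_matrix"), inherits(table, "decision_table"),
            inherits(scheme, "discretization_scheme"))
  if (nrow(u$u) != length(table$brightness))
    stop_structural("membership matrix and table are misaligned")
  M <- table$num_classes
  N <- length(table$brightness)
  lower <- matrix(NA_real_, M, N)
  upper <- matrix(NA_real_, M, N)

  scopes <- if (is.null(table$slice_id)) list(seq_len(N)) else
    split(seq_len(N), table$slice_id)
  per_slice <- data.frame(slice = names(scopes) %||% "all",
                          n = NA_real_, eta = NA_real_)
  card_lower <- numeric(M); card_upper <- numeric(M)
  eta_acc <- 0
  for (k in seq_along(scopes)) {
    idx <- scopes[[k]]
    x <- table$brightness[idx]
    uv <- sort(unique(x))
    rows <- match(x, uv)
    cnt <- as.numeric(tabulate(rows, nbins = length(uv)))
    uu <- u$u[idx, , drop = FALSE][match(uv, x), , drop = FALSE]
    g <- interval_index(uv, scheme)
    for (j in seq_len(M)) {
      lo_g <- tapply(uu[, j], g, min)
      hi_g <- tapply(uu[, j], g, max)
      key <- as.character(g)
      lower[j, idx] <- as.numeric(lo_g[key])[rows]
      upper[j, idx] <- as.numeric(hi_g[key])[rows]
    }
    sc <- eta_scope(uv, cnt, uu, scheme)
    card_lower <- card_lower + sc$card_lower
    card_upper <- card_upper + sc$card_upper
    per_slice$n[k] <- sc$n
    per_slice$eta[k] <- sc$eta
    eta_acc <- eta_acc + sc$eta * sc$n
  }
  eta_bar <- eta_acc / N
  precision <- ifelse(card_upper == 0, 1, card_lower / card_upper)
  structure(list(lower = lower, upper = upper,
                 card_lower = card_lower, card_upper = card_upper,
                 precision = precision, eta_bar = eta_bar,
                 per_slice = per_slice),
            class = "rough_fuzzy_approximation")
}

#' Average approximate precision of a scheme (fast path)
#'
#' Same quantity as `approximate_rough_fuzzy(...)$eta_bar` without
#' materializing the per-pixel approximation matrices; this is the form the
#' genetic-algorithm fitness evaluates.
#'
#' @inheritParams approximate_rough_fuzzy
#' @return scalar eta_bar in `[0, 1]`.
#' @export
eta_bar <- function(u, table, scheme) {
  stopifnot(inherits(u, "membership_matrix"), inherits(table, "decision_table"))
  N <- length(table$brightness)
  scopes <- if (is.null(table$slice_id)) list(seq_len(N)) else
    split(seq_len(N), table$slice_id)
  acc <- 0
  for (idx in scopes) {
    x <- table$brightness[idx]
    uv <- sort(unique(x))
    cnt <- as.numeric(tabulate(match(x, uv), nbins = length(uv)))
    uu <- u$u[idx, , drop = FALSE][match(uv, x), , drop = FALSE]
    sc <- eta_scope(uv, cnt, uu, scheme)
    acc <- acc + sc$eta * sc$n
  }
  acc / N
}

#' Fraction of pixels in label-mixed equivalence classes
#'
#' A pixel is inconsistent when its equivalence class (same interval, same
#' slice scope) contains pixels carrying more than one gold-standard label;
#' the statistic is the inconsistent-pixel fraction. A perfect supervised
#' discretization drives it to 0; identical brightness with different
#' labels is irreducibly inconsistent under every scheme.
#'
#' @param table decision table.
#' @param scheme a [discretization_scheme()].
#' @return scalar in `[0, 1]`.
#' @export
data_inconsistency <- function(table, scheme) {
  stopifnot(inherits(table, "decision_table"),
            inherits(scheme, "discretization_scheme"))
  N <- length(table$brightness)
  scopes <- if (is.null(table$slice_id)) list(seq_len(N)) else
    split(seq_len(N), table$slice_id)
  bad <- 0
  for (idx in scopes) {
    g <- interval_index(table$brightness[idx], scheme)
    lab <- table$labels[idx]
    mixed <- tapply(lab, g, function(l) length(unique(l)) > 1L)
    n_g <- tapply(lab, g, length)
    bad <- bad + sum(n_g[mixed])
  }
  bad / N
}
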