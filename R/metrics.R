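#' Dice similarity coefficient of two voxel sets
#'
#' `DSC = 2 |P  T| / (|P| + |T|)` on binary masks or voxel index sets;
#' 1 when both are empty (perfect agreement on absence), symmetric, in
#' `[0, 1]`.
#'
#' @param pred,truth logical/0-1 arrays of identical shape.
#' @return scalar DSC.
#' @export
dsc <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop_structural("pred and truth shapes differ")
  p <- as.logical(pred); t <- as.logical(truth)
  np <- sum(p); nt <- sum(t)
  if (np + nt == 0) return(1)
  2 * sum(p & t) / (np + nt)
}

#' Surface voxels of a binary region
#'
#' A foreground voxel belongs to the surface when at least one of its
#' axis-neighbours (4-connectivity in 2D, 6-connectivity in 3D) is
#' background, or the voxel touches the image border.
#'
#' @param mask logical/0-1 matrix or 3D array.
#' @return integer matrix of surface voxel coordinates (one row per voxel,
#'   `ncol = ndim`), possibly with zero rows.
#' @export
surface_points <- function(mask) {
  m <- as_numeric_grid(mask) != 0
  d <- dim(m)
  nd <- length(d)
  if (!any(m)) return(matrix(integer(0), 0, nd))
  pad <- array(FALSE, d + 2L)
  idx <- lapply(d, function(k) 2:(k + 1L))
  pad_in <- function(a) { p <- pad; do.call(`[<-`, c(list(p), idx, list(a))) }
  P <- pad_in(m)
  surf <- array(FALSE, d + 2L)
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      sh <- shift_array(P, ax, s)
      surf <- surf | (P & !sh)    # neighbour is background (or border pad)
    }
  }
  surf <- do.call(`[`, c(list(surf), idx, list(drop = FALSE)))
  dim(surf) <- d
  which(surf, arr.ind = TRUE)
}

## shift array by s along axis ax, filling with FALSE
shift_array <- function(a, ax, s) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (s == 1L) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1L) }
  else { dst[[ax]] <- 1:(d[ax] - 1L); src[[ax]] <- 2:d[ax] }
  do.call(`[<-`, c(list(out), dst,
                   list(do.call(`[`, c(list(a), src, list(drop = FALSE))))))
}

## For each row of A, the Euclidean distance to the nearest row of B.
## Blocked exact computation via the |a-b|^2 = |a|^2 + |b|^2 - 2ab identity.
nearest_distances <- function(A, B, block = 2048L) {
  if (nrow(A) == 0L) return(numeric(0))
  if (nrow(B) == 0L) stop_validation("reference point set is empty")
  A <- as.matrix(A) * 1.0; B <- as.matrix(B) * 1.0
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (start in seq(1L, nrow(A), by = block)) {
    end <- min(start + block - 1L, nrow(A))
    Ab <- A[start:end, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), b2, `+`) - 2 * Ab %*% t(B)
    out[start:end] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95% Hausdorff distance between two surface point sets
#'
#' Two conventions are provided. `mode = "paper"` is the literal scaled
#' maximum `0.95 * max(d_XY, d_YX)` with `d_XY = max_x min_y ||x - y||`;
#' `mode = "percentile"` is the conventional robust form, the 95th
#' percentile of the pooled directed point-to-set distances.
#'
#' @param X,Y coordinate matrices (rows = points) or binary masks (surfaces
#'   are extracted automatically), both non-empty.
#' @param mode `"paper"` (default) or `"percentile"`.
#' @param spacing optional per-axis physical spacing multiplying coordinates.
#' @return scalar distance (voxel units unless `spacing` given).
#' @export
hd95 <- function(X, Y, mode = c("paper", "percentile"), spacing = NULL) {
  mode <- match.arg(mode)
  ps <- as_point_sets(X, Y, spacing)
  dxy <- nearest_distances(ps$X, ps$Y)
  dyx <- nearest_distances(ps$Y, ps$X)
  if (mode == "paper") 0.95 * max(max(dxy), max(dyx))
  else as.numeric(quantile(c(dxy, dyx), 0.95, type = 7))
}

#' Average symmetric surface distance
#'
#' `(sum_x min_y ||x-y|| + sum_y min_x ||y-x||) / (|X| + |Y|)`; symmetric,
#' zero iff the two point sets are equal.
#'
#' @inheritParams hd95
#' @return scalar distance.
#' @export
asd <- function(X, Y, spacing = NULL) {
  ps <- as_point_sets(X, Y, spacing)
  dxy <- nearest_distances(ps$X, ps$Y)
  dyx <- nearest_distances(ps$Y, ps$X)
  (sum(dxy) + sum(dyx)) / (length(dxy) + length(dyx))
}

## Logical masks (2D/3D) have their surfaces extracted; numeric matrices are
## taken as coordinate rows; numeric 3D arrays are masks.
as_point_sets <- function(X, Y, spacing = NULL) {
  pts <- function(Z) {
    if (is.logical(Z) && !is.null(dim(Z))) return(surface_points(Z))
    if (is.array(Z) && length(dim(Z)) == 3L) return(surface_points(Z))
    as.matrix(Z)
  }
  Xp <- pts(X); Yp <- pts(Y)
  if (nrow(Xp) == 0L || nrow(Yp) == 0L)
    stop_validation("undefined surface distance: empty point set")
  if (ncol(Xp) != ncol(Yp)) stop_structural("point sets have different dimensionality")
  if (!is.null(spacing)) {
    Xp <- sweep(Xp, 2, spacing, `*`)
    Yp <- sweep(Yp, 2, spacing, `*`)
  }
  list(X = Xp, Y = Yp)
}

#' Full per-class segmentation evaluation
#'
#' One-vs-rest evaluation of every class: DSC on regions, HD95/ASD on
#' extracted surfaces, sensitivity `TP / (TP + FN)` and specificity
#' `TN / (TN + FP)` from confusion counts. Macro scores are unweighted means
#' over classes present in the truth; classes absent from both masks are
#' skipped and listed in `skipped`. Surface metrics are `NA` for classes
#' whose prediction or truth region is empty (the distances are undefined).
#'
#' @param pred,truth integer-label grids of identical shape.
#' @param num_classes number of classes (labels `0..num_classes-1`).
#' @param hd95_mode `"paper"` or `"percentile"`, see [hd95()].
#' @param spacing optional physical voxel spacing.
#' @param class_names optional class names (default `class0..`).
#' @return object of class `metrics_report`: data frame `per_class` and
#'   list `macro`, plus `skipped`.
#' @export
evaluate_segmentation <- function(pred, truth, num_classes,
                                  hd95_mode = c("paper", "percentile"),
                                  spacing = NULL, class_names = NULL) {
  hd95_mode <- match.arg(hd95_mode)
  pred <- as_numeric_grid(pred); truth <- as_numeric_grid(truth)
  if (!identical(dim(pred), dim(truth))) stop_structural("pred and truth shapes differ")
  if (max(pred) >= num_classes || max(truth) >= num_classes)
    stop_validation("labels must be < num_classes")
  cn <- class_names %||% paste0("class", 0:(num_classes - 1L))

  rows <- lapply(0:(num_classes - 1L), function(cl) {
    p <- pred == cl; t <- truth == cl
    if (!any(p) && !any(t))
      return(data.frame(class = cn[cl + 1L], present = FALSE, dsc = NA_real_,
                        hd95 = NA_real_, asd = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_))
    tp <- sum(p & t); fn <- sum(!p & t); fp <- sum(p & !t); tn <- sum(!p & !t)
    surf_ok <- any(p) && any(t)
    h <- if (surf_ok) hd95(p, t, mode = hd95_mode, spacing = spacing) else NA_real_
    a <- if (surf_ok) asd(p, t, spacing = spacing) else NA_real_
    data.frame(class = cn[cl + 1L], present = any(t),
               dsc = dsc(p, t), hd95 = h, asd = a,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  per_class <- do.call(rbind, rows)
  in_truth <- per_class$present & !is.na(per_class$present)
  macro <- lapply(c("dsc", "hd95", "asd", "sensitivity", "specificity"),
                  function(m) mean(per_class[[m]][in_truth], na.rm = TRUE))
  names(macro) <- c("dsc", "hd95", "asd", "sensitivity", "specificity")
  structure(list(per_class = per_class, macro = macro,
                 skipped = per_class$class[is.na(per_class$dsc)],
                 hd95_mode = hd95_mode),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report (hd95 mode:", x$hd95_mode, ")\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("macro: dsc %.4f  hd95 %.4f  asd %.4f  sens %.4f  spec %.4f\n",
              x$macro$dsc, x$macro$hd95, x$macro$asd,
              x$macro$sensitivity, x$macro$specificity))
  if (length(x$skipped)) cat("skipped (absent everywhere):",
                             paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
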