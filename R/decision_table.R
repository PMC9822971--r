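#' Build the information decision table of an image/mask pair
#'
#' An image with its gold-standard mask is represented as an information
#' decision table: one row per pixel, the condition attribute is brightness
#' and the decision attribute is the segmentation category. All downstream
#' stages (fuzzy c-means, rough-fuzzy approximation, breakpoint search)
#' operate on this table.
#'
#' @param image numeric 2D matrix or 3D array of brightness values. For 3D
#'   input the slice axis is axis 1 and pixel order is row-major within a
#'   slice.
#' @param mask integer-valued matrix/array of identical shape; categories are
#'   coded `0 .. num_classes-1`.
#' @param num_classes number of segmentation categories M (>= 2).
#' @param mode `"per_slice"` (default for 3D input) treats every 2D slice as
#'   an independent discretization unit; `"whole_volume"` pools all voxels.
#'   2D input always yields a single-slice table.
#' @param value_range length-2 numeric range of representable brightness;
#'   default `c(0, 255)` (8-bit).
#' @param provenance optional character tag recorded in the table (e.g. a
#'   source file path).
#' @return an object of class `decision_table` with elements `brightness`,
#'   `labels`, `num_classes`, `value_range`, `slice_id` (NULL in
#'   whole-volume mode), `mode`, `shape` and `provenance`.
#' @examples
#' img <- matrix(c(10, 10, 20, 20), 2, 2, byrow = TRUE)
#' msk <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
#' tab <- build_decision_table(img, msk, num_classes = 2)
#' tab$brightness
#' @export
build_decision_table <- function(image, mask, num_classes,
                                 mode = c("per_slice", "whole_volume"),
                                 value_range = c(0, 255),
                                 provenance = NULL) {
  mode <- match.arg(mode)
  image <- as_numeric_grid(image)
  mask <- as_numeric_grid(mask)
  if (!identical(dim(image), dim(mask)))
    stop_structural("image and mask shapes differ: (",
                    paste(dim(image), collapse = "x"), ") vs (",
                    paste(dim(mask), collapse = "x"), ")")
  if (length(image) == 0L) stop_validation("empty image")
  if (!is_count(num_classes) || num_classes < 2)
    stop_validation("num_classes must be an integer >= 2")
  if (any(mask != round(mask))) stop_validation("mask must be integer-valued")
  if (min(mask) < 0 || max(mask) >= num_classes)
    stop_validation("mask labels must lie in 0..", num_classes - 1L,
                    " (found range ", min(mask), "..", max(mask), ")")
  if (any(image < value_range[1] | image > value_range[2]))
    stop_validation("brightness values fall outside value_range [",
                    value_range[1], ", ", value_range[2], "]")

  nd <- length(dim(image))
  if (nd == 2L) {
    slice_id <- if (mode == "per_slice") rep.int(1L, length(image)) else NULL
    brightness <- as.vector(t(image))   # row-major pixel order
    labels <- as.integer(t(mask))
  } else {
    ## flatten slice-by-slice, row-major within each slice
    d <- dim(image)
    per <- prod(d[2:3])
    brightness <- numeric(length(image))
    labels <- integer(length(image))
    for (s in seq_len(d[1])) {
      idx <- ((s - 1L) * per + 1L):(s * per)
      brightness[idx] <- as.vector(t(image[s, , ]))
      labels[idx] <- as.integer(t(mask[s, , ]))
    }
    ## t() above flattens each slice row-major
    slice_id <- if (mode == "per_slice") rep(seq_len(d[1]), each = per) else NULL
  }

  structure(list(
    brightness = brightness,
    labels = labels,
    num_classes = as.integer(num_classes),
    value_range = as.numeric(value_range),
    slice_id = slice_id,
    mode = mode,
    shape = dim(image),
    provenance = provenance
  ), class = "decision_table")
}

as_numeric_grid <- function(x) {
  if (is.null(dim(x))) stop_structural("input must be a matrix or array, not a bare vector")
  if (length(dim(x)) < 2L || length(dim(x)) > 3L)
    stop_structural("input must be 2D or 3D (got ", length(dim(x)), "D)")
  storage.mode(x) <- "double"
  x
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("decision_table: %d pixels, M = %d classes, mode = %s\n",
              length(x$brightness), x$num_classes, x$mode))
  cat(sprintf("  brightness range observed: [%g, %g] of [%g, %g]\n",
              min(x$brightness), max(x$brightness),
              x$value_range[1], x$value_range[2]))
  if (!is.null(x$slice_id))
    cat(sprintf("  slices: %d\n", length(unique(x$slice_id))))
  invisible(x)
}

#' Extract candidate breakpoints from a decision table
#'
#' Candidate breakpoints are the sorted unique observed brightness values of
#' the scoped pixels: the pixel values are sorted and duplicates removed, so
#' a full-dynamic-range 8-bit slice yields exactly 256 candidates.
#'
#' @param table a [build_decision_table()] result.
#' @param scope optional slice id restricting extraction to one slice
#'   (per-slice tables only).
#' @return object of class `candidate_breakpoints`: list with `values`
#'   (strictly increasing numeric vector) and `n`.
#' @examples
#' tab <- build_decision_table(matrix(c(20, 10, 20, 10), 2), matrix(0L, 2, 2) ,2)
#' extract_candidate_breakpoints(tab)$values
#' @export
extract_candidate_breakpoints <- function(table, scope = NULL) {
  stopifnot(inherits(table, "decision_table"))
  v <- table$brightness
  if (!is.null(scope)) {
    if (is.null(table$slice_id))
      stop_validation("scope given but table is not in per_slice mode")
    keep <- table$slice_id == scope
    if (!any(keep)) stop_validation("scope ", scope, " not present in table")
    v <- v[keep]
  }
  vals <- sort(unique(v))
  structure(list(values = vals, n = length(vals)), class = "candidate_breakpoints")
}

#' Per-slice candidate breakpoint accounting
#'
#' Sums the per-slice candidate counts of a per-slice table, the accounting
#' under which a 128-slice stack of full-range 8-bit slices has
#' `128 * 256 = 32768` initial breakpoints.
#'
#' @param table a per-slice decision table.
#' @return named list with `per_slice` (integer vector of per-slice counts)
#'   and `total`.
#' @export
count_candidates_per_slice <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  if (is.null(table$slice_id)) stop_validation("table is not in per_slice mode")
  ids <- sort(unique(table$slice_id))
  per <- vapply(ids, function(s) extract_candidate_breakpoints(table, scope = s)$n, integer(1))
  list(per_slice = setNames(per, ids), total = sum(per))
}
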