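#' Read a grayscale image or volume
#'
#' Supports NIfTI (`.nii`, `.nii.gz`), single- or multi-page TIFF and PNG
#' (2D). PNG values are rescaled from `[0, 1]` to 0-255; TIFF is read with
#' native integer values; NIfTI values are taken as stored. Multi-channel
#' images are reduced to their first channel. 3D volumes are returned with
#' the slice axis first.
#'
#' @param path input file.
#' @return numeric matrix (2D) or 3D array.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    v <- RNifti::readNifti(path)
    a <- array(as.numeric(v), dim(v))
    if (length(dim(a)) == 3L) a <- aperm(a, c(3L, 1L, 2L))  # slices first
    return(a)
  }
  if (grepl("\\.tiff?$", low)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, drop_channels)
    if (length(pages) == 1L) return(pages[[1]])
    d <- dim(pages[[1]])
    out <- array(0, c(length(pages), d))
    for (s in seq_along(pages)) out[s, , ] <- pages[[s]]
    return(out)
  }
  if (grepl("\\.png$", low)) {
    img <- drop_channels(png::readPNG(path))
    return(round(img * 255))
  }
  stop_validation("unsupported image format: ", path)
}

drop_channels <- function(a) {
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a
}

#' Write a grayscale image or volume
#'
#' NIfTI volumes are written with an identity affine; PNG/TIFF values are
#' rescaled from 0-255 to `[0, 1]`. Multipage TIFF is used for 3D data with
#' a `.tif` extension.
#'
#' @param x numeric matrix or 3D array (slice axis first).
#' @param path output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    a <- x
    if (length(dim(a)) == 3L) a <- aperm(a, c(2L, 3L, 1L))  # undo slices-first
    RNifti::writeNifti(RNifti::asNifti(a), path)
    return(invisible(path))
  }
  if (grepl("\\.png$", low)) {
    if (length(dim(x)) != 2L) stop_validation("PNG output requires 2D data")
    png::writePNG(pmin(pmax(x / 255, 0), 1), path)
    return(invisible(path))
  }
  if (grepl("\\.tiff?$", low)) {
    if (length(dim(x)) == 2L) {
      tiff::writeTIFF(pmin(pmax(x / 255, 0), 1), path)
    } else {
      pages <- lapply(seq_len(dim(x)[1]), function(s)
        pmin(pmax(x[s, , ] / 255, 0), 1))
      tiff::writeTIFF(pages, path)
    }
    return(invisible(path))
  }
  stop_validation("unsupported image format: ", path)
}

#' Write a discretization scheme (with provenance) to JSON
#'
#' @param result a [ga_discretize()] result.
#' @param path output JSON path.
#' @param table the fitting decision table (for the data-inconsistency
#'   field and per-slice flag).
#' @return `path`, invisibly.
#' @export
write_scheme <- function(result, path, table = NULL) {
  stopifnot(inherits(result, "ga_result"))
  sc <- result$best_scheme
  obj <- list(candidates = sc$candidates$values,
              selected = as.integer(sc$selected),
              alpha = result$config$alpha,
              beta = result$config$beta,
              fitness = result$best_fitness,
              eta_bar = result$eta_bar,
              data_inconsistency = if (!is.null(table))
                data_inconsistency(table, sc) else NULL,
              seed = result$config$seed,
              per_slice = if (!is.null(table)) !is.null(table$slice_id) else NA)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a discretization scheme from JSON
#'
#' @param path a file written by [write_scheme()].
#' @return a [discretization_scheme()] with attributes `fitness`,
#'   `eta_bar`, `alpha`, `beta` attached.
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- discretization_scheme(as.numeric(obj$candidates),
                              as.integer(obj$selected) == 1L)
  attr(sc, "fitness") <- obj$fitness
  attr(sc, "eta_bar") <- obj$eta_bar
  attr(sc, "alpha") <- obj$alpha
  attr(sc, "beta") <- obj$beta
  sc
}
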