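#' Write a multispectral stack as multi-page TIFF with JSON sidecar
#'
#' One 32-bit float page per wavelength. TIFF pages store values normalized
#' to \[0, 1\]; the scale factor, wavelength grid, pixel size and seed are
#' recorded in a JSON sidecar (`<path>.json`) so the stack round-trips
#' exactly.
#'
#' @param stack 3D array (rows x cols x wavelengths) or an `"msot_scene"`.
#' @param path Output TIFF path.
#' @param wavelengths,pixel_mm,seed Metadata for a bare array input; taken
#'   from the scene otherwise.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, wavelengths = NULL, pixel_mm = NA_real_,
                        seed = NA_integer_) {
  if (inherits(stack, "msot_scene")) {
    wavelengths <- stack$wavelengths
    pixel_mm <- stack$pixel_mm
    seed <- stack$seed
    stack <- stack$stack
  }
  stopifnot(length(dim(stack)) == 3)
  if (is.null(wavelengths)) wavelengths <- seq_len(dim(stack)[3])
  scale <- max(stack, 1e-300)
  pages <- lapply(seq_len(dim(stack)[3]), function(l) stack[, , l] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(wavelengths_nm = as.numeric(wavelengths), pixel_size_mm = pixel_mm,
         seed = seed, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multispectral stack written by [write_stack()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return List with `stack` (3D array), `wavelengths`, `pixel_mm`, `seed`.
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(pages) * meta$scale
  dimnames(arr) <- list(NULL, NULL, meta$wavelengths_nm)
  list(stack = arr, wavelengths = as.numeric(meta$wavelengths_nm),
       pixel_mm = meta$pixel_size_mm, seed = meta$seed)
}

#' Write / read a binary mask as single-page 8-bit TIFF
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return `path` invisibly / logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Write per-pixel coefficient maps as multi-page TIFF
#'
#' Folds an N x K coefficient matrix back into image geometry using the
#' back-map attribute of the spectra matrix it was fitted on, one page per
#' component (pixels outside the analysis mask are 0).
#'
#' @param W N x K non-negative coefficients.
#' @param backmap Two-column (row, col) matrix, as produced by
#'   [spectra_matrix()].
#' @param dim_image c(rows, cols) of the image.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_coefficient_maps <- function(W, backmap, dim_image, path) {
  stopifnot(nrow(W) == nrow(backmap))
  arr <- array(0, dim = c(dim_image[1], dim_image[2], ncol(W)))
  idx <- (backmap[, 2] - 1) * dim_image[1] + backmap[, 1]
  for (k in seq_len(ncol(W))) {
    page <- matrix(0, dim_image[1], dim_image[2])
    page[idx] <- W[, k]
    arr[, , k] <- page
  }
  write_stack(arr, path, wavelengths = seq_len(ncol(W)))
}
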