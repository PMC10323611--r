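#' Synthetic chromophore endmember library
#'
#' Returns parametric absorption-spectrum analogues of the endogenous
#' chromophores that dominate near-infrared optoacoustic contrast in soft
#' tissue. The shapes are documented closed forms (sums of Gaussians plus
#' exponential trends), chosen to reproduce the qualitative features of the
#' real spectra while keeping the ground truth self-contained:
#'
#' * `oxyhemoglobin`: rises towards ~900 nm and flattens.
#' * `deoxyhemoglobin`: decreasing trend with the characteristic local bump
#'   near 760 nm.
#' * `lipid`: single absorption peak inside the 900-940 nm band.
#' * `water`: absorption rising to a peak at the 970 nm end of the grid.
#' * `melanin`: monotone decreasing (the common melanin/collagen slope).
#' * `collagen`: decreasing trend with a weak local maximum near 900 nm.
#'
#' All values are non-negative and in arbitrary absorption units on a common
#' scale; the rows are constructed linearly independent, so noiseless
#' mixtures can be inverted exactly by constrained least squares.
#'
#' @param grid Wavelength grid in nm (see [wavelength_grid()]).
#' @return A numeric matrix with one row per chromophore (rownames are the
#'   chromophore names) and one column per wavelength (colnames are nm
#'   values); attribute `"wavelengths"` carries the grid.
#' @examples
#' E <- endmember_library()
#' rownames(E)
#' colnames(E)[which.max(E["lipid", ])]  # peak in the 900-940 nm band
#' @export
endmember_library <- function(grid = wavelength_grid()) {
  assert_grid(grid)
  w <- as.numeric(grid)
  gauss <- function(center, width) exp(-(w - center)^2 / (2 * width^2))

  E <- rbind(
    oxyhemoglobin   = 3 + 7 / (1 + exp(-(w - 820) / 50)),
    deoxyhemoglobin = 12 * exp(-(w - 700) / 220) + 2.2 * gauss(760, 15),
    lipid           = 0.3 + 9 * gauss(925, 18),
    water           = 0.2 + 8 * gauss(975, 40),
    melanin         = 0.2 + 11 * exp(-(w - 700) / 160),
    collagen        = 0.2 + 6 * exp(-(w - 700) / 260) + 1.5 * gauss(900, 25)
  )
  colnames(E) <- w
  stopifnot(all(E >= 0))
  attr(E, "wavelengths") <- w
  E
}
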