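#' Build a uniform acquisition wavelength grid
#'
#' Multispectral optoacoustic stacks are acquired by cycling the excitation
#' laser through a uniform wavelength schedule in the NIR-I window. The
#' default grid (700 to 970 nm in 10 nm steps, 28 channels) matches common
#' handheld clinical protocols.
#'
#' @param start First wavelength in nm.
#' @param stop Last wavelength in nm; must be reachable from `start` in whole
#'   steps of `step`.
#' @param step Step size in nm, > 0.
#'
#' @return A strictly increasing numeric vector of wavelengths in nm with
#'   class `"wavelength_grid"`.
#' @examples
#' length(wavelength_grid())        # 28 channels
#' wavelength_grid(700, 730, 10)    # 700 710 720 730
#' @export
wavelength_grid <- function(start = 700, stop = 970, step = 10) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (step <= 0) stop("`step` must be > 0")
  if (start > stop) stop("`start` must be <= `stop`")
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-8) {
    stop(sprintf(
      "wavelength range [%g, %g] nm is not divisible by step %g nm",
      start, stop, step
    ))
  }
  structure(seq(start, stop, by = step), class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "wavelength grid: %d channels, %g-%g nm (step %g nm)\n",
    length(x), min(x), max(x), if (length(x) > 1) x[2] - x[1] else NA_real_
  ))
  invisible(x)
}

assert_grid <- function(grid) {
  stopifnot(is.numeric(grid), length(grid) >= 1)
  if (length(grid) > 1) {
    d <- diff(grid)
    if (any(d <= 0)) stop("wavelength grid must be strictly increasing")
    if (max(d) - min(d) > 1e-8 * max(d)) stop("wavelength grid must be uniform")
  }
  invisible(grid)
}

#' Multispectral stack acquisition rate
#'
#' A stack needs one laser pulse per wavelength, so the stack rate is the
#' pulse repetition rate divided by the number of wavelengths; at 25 Hz and
#' 28 wavelengths this gives the familiar ~0.89 Hz stack rate.
#'
#' @param pulse_rate_hz Laser pulse repetition rate in Hz.
#' @param n_wavelengths Number of wavelengths per stack.
#' @return Stack acquisition rate in Hz, rounded to two decimals.
#' @examples
#' acquisition_rate(25, 28)  # 0.89
#' @export
acquisition_rate <- function(pulse_rate_hz = 25, n_wavelengths = 28) {
  stopifnot(pulse_rate_hz > 0, n_wavelengths >= 1)
  round(pulse_rate_hz / n_wavelengths, 2)
}
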