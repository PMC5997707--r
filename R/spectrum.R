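#' Emission spectrum
#'
#' A `spectrum` holds an emission spectrum on a strictly increasing
#' wavelength grid. Intensities are nonnegative counts or normalized units.
#' The canonical internal grid is 400--700 nm at 2 nm steps (the resolution
#' of a photonic multichannel analyzer); spectra on other grids are linearly
#' interpolated onto it, extrapolation is forbidden.
#'
#' @param wavelength_nm numeric, strictly increasing wavelength grid (nm).
#' @param intensity numeric, nonnegative, same length as `wavelength_nm`.
#' @param meta named list of free-form labels (`construct`, `condition`,
#'   `mode` in `c("fluorescence", "bioluminescence")`).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, intensity, meta = list()) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength and intensity must have the same length")
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least two grid points")
  if (any(!is.finite(wavelength_nm)))
    stop("non-finite wavelengths")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop("non-finite intensities")
  if (any(intensity < 0))
    stop("intensities must be nonnegative")
  structure(
    list(wavelength_nm = wavelength_nm, intensity = intensity,
         meta = as.list(meta)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelength_nm)
  cat(sprintf("<spectrum> %d points, %.0f-%.0f nm, area %.4g\n",
              length(x$wavelength_nm), rng[1], rng[2], spectrum_area(x)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Default wavelength grid (400--700 nm, 2 nm step)
#'
#' @param from,to,by grid limits and step in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(from = 400, to = 700, by = 2) seq(from, to, by = by)

#' Trapezoidal area of a spectrum
#'
#' @param x a `spectrum`.
#' @return The trapezoidal integral of intensity over wavelength.
#' @export
spectrum_area <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  pracma::trapz(x$wavelength_nm, x$intensity)
}

#' Area-normalize a spectrum to unit integral
#'
#' @param x a `spectrum`.
#' @return A `spectrum` with trapezoidal area 1.
#' @export
normalize_area <- function(x) {
  a <- spectrum_area(x)
  if (a <= 0) stop("spectrum area must be positive to normalize")
  spectrum(x$wavelength_nm, x$intensity / a, x$meta)
}

#' Interpolate a spectrum onto a new grid
#'
#' Linear interpolation; requesting wavelengths outside the support of the
#' source spectrum is an error (no extrapolation).
#'
#' @param x a `spectrum`.
#' @param grid target wavelength grid (nm), strictly increasing.
#' @return A `spectrum` on `grid`.
#' @export
interp_spectrum <- function(x, grid) {
  stopifnot(inherits(x, "spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  if (min(grid) < min(x$wavelength_nm) || max(grid) > max(x$wavelength_nm))
    stop(sprintf(
      "grid [%g, %g] nm outside spectrum support [%g, %g] nm: extrapolation forbidden",
      min(grid), max(grid), min(x$wavelength_nm), max(x$wavelength_nm)))
  y <- stats::approx(x$wavelength_nm, x$intensity, xout = grid,
                     method = "linear")$y
  spectrum(grid, pmax(y, 0), x$meta)
}
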