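## Unit conventions used throughout:
##   time            fs
##   angular freq    rad/fs
##   wavelength      nm (vacuum)
##   wavenumber      cm^-1
## A single speed-of-light constant keeps every conversion consistent.

#' Speed of light in nm/fs
#' @keywords internal
.c_nmfs <- 299.792458

#' Convert between wavenumber, wavelength and angular frequency
#'
#' Small vectorized helpers for the spectral-axis algebra used everywhere in
#' the package: `wavenumber_to_angfreq()` maps cm^-1 to rad/fs,
#' `angfreq_to_wavenumber()` inverts it, `wavelength_to_angfreq()` maps nm to
#' rad/fs, and `wavelength_to_wavenumber()` maps nm to cm^-1.
#'
#' @param wavenumber wavenumber in cm^-1
#' @param angfreq angular frequency in rad/fs
#' @param wavelength vacuum wavelength in nm
#' @return numeric vector in the target unit
#' @examples
#' wavelength_to_wavenumber(10000)  # 10 um -> 1000 cm^-1
#' @export
wavenumber_to_angfreq <- function(wavenumber) {
  2 * pi * .c_nmfs * 1e-7 * wavenumber
}

#' @rdname wavenumber_to_angfreq
#' @export
angfreq_to_wavenumber <- function(angfreq) {
  angfreq / (2 * pi * .c_nmfs * 1e-7)
}

#' @rdname wavenumber_to_angfreq
#' @export
wavelength_to_angfreq <- function(wavelength) {
  2 * pi * .c_nmfs / wavelength
}

#' @rdname wavenumber_to_angfreq
#' @export
wavelength_to_wavenumber <- function(wavelength) {
  1e7 / wavelength
}
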