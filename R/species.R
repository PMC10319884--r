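#' Absorption line and species library constructors
#'
#' A species is a set of Lorentzian absorption lines, each described by its
#' center (cm^-1), dimensionless peak optical depth (`strength`), and FWHM
#' (cm^-1).  A species library maps species names to line tables and is the
#' input of [apply_sample()].
#'
#' @param center line center, cm^-1 (> 0)
#' @param strength peak optical depth at line center (>= 0); the intensity
#'   transmittance at center is `exp(-strength)`
#' @param fwhm full width at half maximum, cm^-1 (> 0)
#' @return `absorption_line()`: a one-row data frame; `species_library()`:
#'   an object of class `species_library`
#' @export
absorption_line <- function(center, strength, fwhm) {
  stopifnot(all(center > 0), all(strength >= 0), all(fwhm > 0))
  data.frame(center = center, strength = strength, fwhm = fwhm)
}

#' @param ... named species, each a data frame of absorption lines
#' @rdname absorption_line
#' @export
species_library <- function(...) {
  lib <- list(...)
  if (length(lib) == 0 || is.null(names(lib)) || any(names(lib) == ""))
    stop("species_library() needs named species entries")
  for (nm in names(lib)) {
    ln <- lib[[nm]]
    if (!is.data.frame(ln) ||
        !all(c("center", "strength", "fwhm") %in% names(ln)))
      stop("species '", nm, "' must be a data frame with columns ",
           "center, strength, fwhm")
    absorption_line(ln$center, ln$strength, ln$fwhm)  # validates
  }
  structure(lib, class = "species_library")
}

#' Built-in species library
#'
#' Ships the absorbers used throughout the examples and phantoms, with the
#' band positions the chemical-mapping workflows teach on: glycerin (851,
#' 920, 1030 cm^-1), glucose (1142, 1360, 1427), albumin (1542, 1658), DOPC
#' (1089, 1250), soybean oil (1463, 1747), water (1640) and CO2 (2349).
#'
#' Strengths are peak optical depths of thin (tens of um) films and
#' micro-channel fillings, giving transmittance dips of roughly 0.3-0.6;
#' widths are typical condensed-phase values (24-40 cm^-1), a broad 80 cm^-1
#' for the liquid-water bending band, and an 18 cm^-1 effective envelope for
#' the unresolved CO2 rovibrational band.
#'
#' @return a [species_library()]
#' @export
default_species_library <- function() {
  species_library(
    glycerin = absorption_line(c(851, 920, 1030),
                               c(0.40, 0.35, 0.50), c(32, 32, 32)),
    glucose = absorption_line(c(1142, 1360, 1427),
                              c(0.45, 0.35, 0.35), c(30, 30, 30)),
    albumin = absorption_line(c(1542, 1658),
                              c(0.45, 0.55), c(40, 40)),
    dopc = absorption_line(c(1089, 1250),
                           c(0.40, 0.40), c(30, 30)),
    soybean_oil = absorption_line(c(1463, 1747),
                                  c(0.40, 0.50), c(30, 24)),
    water = absorption_line(1640, 0.80, 80),
    co2 = absorption_line(2349, 0.60, 18)
  )
}

#' @export
print.species_library <- function(x, ...) {
  cat("<species_library> with", length(x), "species\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %s cm^-1\n", nm,
                paste(x[[nm]]$center, collapse = ", ")))
  invisible(x)
}

#' Complex transmission of a species mixture
#'
#' Frequency-domain transmission factor for a set of Lorentzian lines with
#' the Kramers-Kronig phase partner, so that the time-domain response is
#' causal and narrow lines ring as free-induction decay after the pulse.
#' For a line of half-width `G` (rad/fs) at `w0` the field transmission is
#' `exp(-(s/2) * G / (G + 1i*(w - w0)))`: the real part of the exponent is
#' the (s/2)-scaled unit-peak Lorentzian, the imaginary part its Hilbert
#' pair.
#'
#' @param angfreq angular frequency axis, rad/fs
#' @param mixture named numeric vector of per-species optical-depth scales
#' @param library a [species_library()]
#' @return complex vector of field transmission values
#' @keywords internal
mixture_transmission <- function(angfreq, mixture, library) {
  H <- rep(1 + 0i, length(angfreq))
  if (length(mixture) == 0) return(H)
  unknown <- setdiff(names(mixture), names(library))
  if (length(unknown))
    stop("unknown species in mixture: ", paste(unknown, collapse = ", "))
  for (nm in names(mixture)) {
    scale <- mixture[[nm]]
    if (scale == 0) next
    for (i in seq_len(nrow(library[[nm]]))) {
      ln <- library[[nm]][i, ]
      G <- wavenumber_to_angfreq(ln$fwhm) / 2
      w0 <- wavenumber_to_angfreq(ln$center)
      H <- H * exp(-(scale * ln$strength / 2) * G / (G + 1i * (angfreq - w0)))
    }
  }
  H
}

#' Exact intensity transmittance of a mixture
#'
#' The squared modulus of the complex mixture transmission on a wavenumber
#' axis; the ground truth against which retrieved spectra are compared.
#'
#' @param wavenumber wavenumber axis, cm^-1
#' @inheritParams mixture_transmission
#' @return numeric vector of intensity transmittance values
#' @export
true_transmittance <- function(wavenumber, mixture, library) {
  Mod(mixture_transmission(wavenumber_to_angfreq(wavenumber),
                           mixture, library))^2
}
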