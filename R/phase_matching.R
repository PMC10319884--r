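## Type-I (o + o -> e) sum-frequency phase matching in GaSe.
##
## Sellmeier coefficients are the standard published GaSe set (lambda in
## um, nominal validity ~0.65-18 um; the guard below allows a slight
## extrapolation to 0.62 um so the visible sum-frequency edge at 638 nm,
## inside the GaSe transparency range, can be evaluated):
##   n_o^2 = 7.443 + 0.4050/L^2 + 0.0186/L^4 + 0.0061/L^6
##           + 3.1485 L^2/(L^2 - 2193.8)
##   n_e^2 = 5.76  + 0.3879/L^2 - 0.2288/L^4 + 0.1223/L^6
##           + 1.8550 L^2/(L^2 - 1780.3)
## Tests assert self-consistency of the model (sign-change scans, sinc
## zeros, L^2 scaling), not absolute literature accuracy.

.gase_sellmeier <- list(
  o = c(A = 7.443, B2 = 0.4050, B4 = 0.0186, B6 = 0.0061,
        C = 3.1485, D = 2193.8),
  e = c(A = 5.76, B2 = 0.3879, B4 = -0.2288, B6 = 0.1223,
        C = 1.8550, D = 1780.3),
  validity_um = c(0.62, 18)
)

#' GaSe crystal model
#'
#' A uniaxial GaSe film described by embedded Sellmeier sets for the
#' ordinary and principal extraordinary indices, a thickness, and an
#' internal propagation angle from the optic axis.  The default angle
#' (26.5 degrees) near-maximizes the minimum in-band type-I conversion
#' efficiency of a 4.4 um film over 640-3015 cm^-1 with a 790 nm gate.
#'
#' @param thickness_um film thickness in um (> 0)
#' @param theta_deg internal propagation angle from the optic axis, degrees
#' @return an object of class `crystal_model`
#' @export
gase_crystal <- function(thickness_um = 4.4, theta_deg = 26.5) {
  stopifnot(thickness_um > 0, theta_deg >= 0, theta_deg <= 90)
  structure(list(name = "GaSe", sellmeier = .gase_sellmeier,
                 thickness_um = thickness_um, theta_deg = theta_deg),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat(sprintf("<crystal_model %s> L = %g um, theta = %g deg\n",
              x$name, x$thickness_um, x$theta_deg))
  invisible(x)
}

.sellmeier_n <- function(coef, lam_um) {
  L2 <- lam_um^2
  sqrt(coef["A"] + coef["B2"] / L2 + coef["B4"] / L2^2 + coef["B6"] / L2^3 +
       coef["C"] * L2 / (L2 - coef["D"]))
}

#' Refractive index of the crystal model
#'
#' `polarization = "o"` returns the ordinary index; `"e"` returns the
#' angle-tuned extraordinary index from the uniaxial index ellipse,
#' `1/n^2 = cos^2(theta)/n_o^2 + sin^2(theta)/n_e^2`.
#'
#' @param crystal a [gase_crystal()]
#' @param wavelength_nm vacuum wavelength in nm
#' @param polarization `"o"` or `"e"`
#' @return refractive index (vectorized over wavelength)
#' @export
refractive_index <- function(crystal, wavelength_nm,
                             polarization = c("o", "e")) {
  polarization <- match.arg(polarization)
  lam <- wavelength_nm / 1000
  v <- crystal$sellmeier$validity_um
  if (any(lam < v[1] | lam > v[2]))
    stop(sprintf("wavelength outside Sellmeier validity range %g-%g um",
                 v[1], v[2]))
  n_o <- .sellmeier_n(crystal$sellmeier$o, lam)
  if (polarization == "o") return(unname(n_o))
  n_e <- .sellmeier_n(crystal$sellmeier$e, lam)
  th <- crystal$theta_deg * pi / 180
  unname(1 / sqrt(cos(th)^2 / n_o^2 + sin(th)^2 / n_e^2))
}

#' Collinear phase mismatch for type-I sum-frequency generation
#'
#' `Delta k = k_e(SFG) - k_o(CP) - k_o(MIR)` in rad/um, with
#' `1/lambda_SFG = 1/lambda_CP + nu_MIR`.
#'
#' @param crystal a [gase_crystal()]
#' @param mir_wavenumber MIR wavenumber, cm^-1 (vectorized)
#' @param cp_wavelength chirped-pulse wavelength, nm
#' @return phase mismatch in rad/um
#' @export
delta_k <- function(crystal, mir_wavenumber, cp_wavelength = 790) {
  stopifnot(all(mir_wavenumber > 0), cp_wavelength > 0)
  lam_mir <- 1e7 / mir_wavenumber                       # nm
  lam_sfg <- 1 / (1 / cp_wavelength + mir_wavenumber * 1e-7)
  k <- function(n, lam_nm) 2 * pi * n / (lam_nm / 1000) # rad/um
  k(refractive_index(crystal, lam_sfg, "e"), lam_sfg) -
    k(refractive_index(crystal, cp_wavelength, "o"), cp_wavelength) -
    k(refractive_index(crystal, lam_mir, "o"), lam_mir)
}

#' Relative conversion efficiency
#'
#' `eta ~ L^2 sinc^2(Delta k L / 2)`; with `normalize = TRUE` the curve is
#' scaled to its maximum over the supplied wavenumbers.
#'
#' @inheritParams delta_k
#' @param normalize scale to the band maximum
#' @return efficiency (vectorized over `mir_wavenumber`)
#' @export
conversion_efficiency <- function(crystal, mir_wavenumber,
                                  cp_wavelength = 790, normalize = TRUE) {
  dk <- delta_k(crystal, mir_wavenumber, cp_wavelength)
  x <- dk * crystal$thickness_um / 2
  s <- ifelse(x == 0, 1, sin(x) / x)
  eta <- crystal$thickness_um^2 * s^2
  if (normalize) eta <- eta / max(eta)
  eta
}

#' Minimum in-band efficiency and coverage verdict
#'
#' Scans the normalized efficiency on a grid no coarser than `step` cm^-1
#' and reports the in-band minimum and whether it exceeds `threshold`.
#'
#' @inheritParams delta_k
#' @param band `c(lo, hi)` wavenumber band, cm^-1 (lo <= hi)
#' @param threshold coverage threshold on normalized efficiency
#' @param step scan step, cm^-1 (<= 1 enforced)
#' @return list: `min_efficiency`, `at_wavenumber`, `covered`, `band`
#' @export
band_coverage <- function(crystal, band = c(640, 3015), threshold = 0,
                          cp_wavelength = 790, step = 1) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  step <- min(step, 1)
  wn <- if (band[1] == band[2]) band[1] else seq(band[1], band[2], by = step)
  eta <- conversion_efficiency(crystal, wn, cp_wavelength, normalize = TRUE)
  i <- which.min(eta)
  min_eff <- eta[i]
  at <- wn[i]
  if (length(wn) > 1) {
    ## exact sinc zeros can fall between grid points: the phase
    ## Delta_k L / 2 crossing a non-zero multiple of pi pins efficiency
    ## to zero there
    x <- delta_k(crystal, wn, cp_wavelength) * crystal$thickness_um / 2
    m <- floor(x / pi)
    crossed <- which(diff(m) != 0)
    for (j in crossed) {
      ks <- setdiff(seq(min(m[j], m[j + 1]) + 1, max(m[j], m[j + 1])), 0)
      if (length(ks)) {
        frac <- (ks[1] * pi - x[j]) / (x[j + 1] - x[j])
        min_eff <- 0
        at <- wn[j] + frac * step
        break
      }
    }
  }
  list(min_efficiency = min_eff, at_wavenumber = at,
       covered = min_eff > threshold, band = band)
}

#' Phase-matching amplitude transfer function
#'
#' Tabulates the normalized conversion efficiency over a wavenumber band
#' and returns a vectorized lookup, zero outside the tabulated band, for
#' use as the `pm` argument of [sfg_and_measure()] and [simulate_cube()].
#'
#' @inheritParams delta_k
#' @param band tabulation band, cm^-1 (kept inside Sellmeier validity)
#' @param step tabulation step, cm^-1
#' @return function(mir_wavenumber) -> relative efficiency
#' @export
pm_transfer <- function(crystal, cp_wavelength = 790,
                        band = c(600, 3100), step = 1) {
  wn <- seq(band[1], band[2], by = step)
  eta <- conversion_efficiency(crystal, wn, cp_wavelength, normalize = TRUE)
  stats::approxfun(wn, eta, yleft = 0, yright = 0)
}
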