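## Retrieval: measured SFG spectra -> calibrated MIR transmittance.
##
## The cross-phase-modulation (XPM) artifact arises because the chirped
## gate maps the free-induction decay of narrow lines into a chirped
## spectral oscillation.  In the delay domain (Fourier transform of the
## measured spectrum, i.e. the field autocorrelation) the artifact carries
## a parabolic phase a*tau^2/2 set by the chirp rate a.  The correction
## removes that phase, deconvolves the known gate envelope, discards the
## doubly-chirped mirror half of the delay axis, and rebuilds the complex
## effective field transmission, whose squared modulus is the
## transmittance.  Weighting by the background field amplitude before the
## transform makes the regathering exact to first order even where the
## source envelope slopes.

#' Map the SFG detection axis to the MIR axis
#'
#' Photon-energy conservation: `1/lambda_MIR = 1/lambda_SFG - 1/lambda_CP`.
#'
#' @param sfg_wavelength_nm SFG wavelength(s), nm (must be `< cp`)
#' @param cp_wavelength_nm chirped-pulse wavelength, nm
#' @return list: `wavelength_nm` and `wavenumber_cm1` of the MIR photon
#' @examples
#' sfg_to_mir_axis(638, 790)$wavelength_nm  # ~3316 nm
#' sfg_to_mir_axis(752, 790)$wavenumber_cm1 # ~640 cm^-1
#' @export
sfg_to_mir_axis <- function(sfg_wavelength_nm, cp_wavelength_nm = 790) {
  if (any(sfg_wavelength_nm >= cp_wavelength_nm))
    stop("non-physical axis mapping: SFG wavelength must be shorter ",
         "than the chirped-pulse wavelength")
  inv <- 1 / sfg_wavelength_nm - 1 / cp_wavelength_nm
  list(wavelength_nm = 1 / inv, wavenumber_cm1 = 1e7 * inv)
}

#' Wavenumber resolution of a wavelength sampling step
#'
#' `d(nu) = 1e7 * d(lambda) / lambda^2` with lambda in nm and the result in
#' cm^-1.
#'
#' @param wavelength_nm wavelength, nm
#' @param sampling_nm wavelength sampling step, nm
#' @return resolution in cm^-1
#' @examples
#' wavenumber_resolution(638, 0.15)  # ~3.7 cm^-1
#' wavenumber_resolution(752, 0.15)  # ~2.7 cm^-1
#' @export
wavenumber_resolution <- function(wavelength_nm, sampling_nm) {
  stopifnot(all(wavelength_nm > 0), all(sampling_nm >= 0))
  1e7 * sampling_nm / wavelength_nm^2
}

#' Fit the chirp rate from a cross-correlation map
#'
#' Computes the intensity-weighted spectral centroid of every delay slice
#' of a spectrally resolved cross-correlation -- the instantaneous
#' sum-frequency versus delay -- and fits it against delay by weighted
#' least squares.  The slope is the chirp rate (rad/fs^2).  (The
#' transposed construction, a centroid delay per frequency, is biased by
#' the spectral envelope of a broadband source; the per-delay centroid is
#' envelope-shape independent as long as the envelope stays inside the
#' detection window.)
#'
#' @param xc map from [simulate_cross_correlation()] (or a compatible list
#'   with `intensity`, `angfreq`, `delay_fs`)
#' @param min_slice_weight drop delay slices dimmer than this fraction of
#'   the brightest slice
#' @return a `chirp_calibration`: `chirp_rate`, `center_angfreq` (frequency
#'   at zero delay), `residual` (weighted RMS of the fit, rad/fs), and
#'   `monotone` flag (FALSE triggers a warning)
#' @export
instantaneous_frequency <- function(xc, min_slice_weight = 0.05) {
  I <- xc$intensity
  wts <- rowSums(I)
  keep <- wts > min_slice_weight * max(wts)
  if (sum(keep) < 4)
    stop("cross-correlation map has too few usable delay slices")
  tau <- xc$delay_fs[keep]
  om <- xc$angfreq
  o <- order(om)
  ## Instantaneous frequency per delay slice.  A plain spectral centroid
  ## is biased when the detection window clips the broad source envelope,
  ## so the centroid is taken inside a sub-window that translates with the
  ## current rate estimate and the fit is iterated: at the fixed point the
  ## clipped mass is delay-independent and the slope is unbiased to first
  ## order.
  S <- t(I[keep, o, drop = FALSE])
  nb <- nrow(S)
  om_u <- seq(om[o][1], om[o][nb], length.out = nb)
  S <- .interp_apply(.interp_op(om[o], om_u), S)
  margin <- 0.15 * diff(range(om_u))
  rate <- 0
  for (it in 1:15) {
    omc <- vapply(seq_along(tau), function(j) {
      shift <- rate * (tau[j] - stats::median(tau))
      shift <- max(min(shift, margin), -margin)
      sel2 <- om_u >= om_u[1] + margin + shift &
              om_u <= om_u[nb] - margin + shift
      sum(S[sel2, j] * om_u[sel2]) / sum(S[sel2, j])
    }, 1)
    fit <- stats::lm(omc ~ tau, weights = wts[keep])
    new_rate <- unname(stats::coef(fit)[2])
    conv <- is.finite(new_rate) &&
      abs(new_rate - rate) < 1e-4 * max(abs(new_rate), 1e-12)
    rate <- new_rate
    if (conv) break
  }
  slope <- unname(stats::coef(fit)[2])
  ## degenerate if the fitted sweep over the scan stays within a few
  ## frequency-grid steps, or if delay explains almost none of the
  ## centroid variance (an unchirped pulse gives an uncorrelated trace)
  sweep_tot <- abs(slope) * diff(range(tau))
  wres <- stats::residuals(fit)
  wk <- wts[keep]
  r2 <- 1 - sum(wk * wres^2) /
    sum(wk * (omc - stats::weighted.mean(omc, wk))^2)
  if (!is.finite(slope) || sweep_tot < 5 * (om_u[2] - om_u[1]) ||
      !is.finite(r2) || r2 < 0.8)
    stop("degenerate fit: spectral centroid does not sweep with delay ",
         "(unchirped pulse?)")
  d <- diff(omc[order(tau)])
  mono <- all(d <= 0) || all(d >= 0)
  if (!mono)
    warning("centroid trace is not monotone; chirp fit may be biased")
  res <- sqrt(stats::weighted.mean(stats::residuals(fit)^2, wts[keep]))
  cal <- list(chirp_rate = slope,
              center_angfreq = unname(stats::coef(fit)[1]),
              cp_duration_fs = NA_real_,
              phi2 = NA_real_,
              residual = res,
              monotone = mono)
  class(cal) <- "chirp_calibration"
  cal
}

## Linear-interpolation operator from axis x (ascending) onto grid xg,
## constant extrapolation.  Returns index/weight vectors applied as
## y[lo]*(1-f) + y[hi]*f, vectorized over matrix columns.
.interp_op <- function(x, xg) {
  i <- findInterval(xg, x, all.inside = TRUE)
  f <- (xg - x[i]) / (x[i + 1] - x[i])
  f <- pmin(pmax(f, 0), 1)
  list(lo = i, hi = i + 1, f = f)
}

.interp_apply <- function(op, Y) {
  if (is.matrix(Y)) {
    Y[op$lo, , drop = FALSE] * (1 - op$f) + Y[op$hi, , drop = FALSE] * op$f
  } else {
    Y[op$lo] * (1 - op$f) + Y[op$hi] * op$f
  }
}

#' Correct the cross-phase-modulation artifact of ratioed spectra
#'
#' Takes one or more background-ratioed spectra on a common MIR wavenumber
#' axis and removes the chirp-induced XPM artifact: resample to a uniform
#' angular-frequency grid (tapered zero-padding), Fourier transform to the
#' delay domain, multiply by the conjugate parabolic phase
#' `exp(-i a tau^2 / 2)`, deconvolve the chirped-pulse gate envelope
#' (capped), keep the causal half of the delay axis (the mirror half holds
#' the doubly-chirped image), and return the squared modulus of the
#' reconstructed effective field transmission.  A second-order iteration
#' subtracts the re-chirped `|F|^2` self-term, which matters for deep
#' lines.
#'
#' @param ratio numeric vector, or matrix with one spectrum per column
#' @param wavenumber MIR wavenumber axis, cm^-1 (any order, monotone)
#' @param calibration a `chirp_calibration` (needs `chirp_rate`; uses
#'   `cp_duration_fs` for the gate if present)
#' @param bg_amplitude optional background field amplitude (e.g.
#'   `sqrt(background counts)`) on the same axis; weights the artifact
#'   regathering by the source envelope
#' @param n_iter self-term iterations (1 = linear correction)
#' @param sign `"physical"` derives the parabolic-phase branch from the
#'   sign of the calibrated chirp rate (the delay-domain transform
#'   convention is fixed inside this function, so the branch follows);
#'   `"flipped"` forces the opposite branch for diagnostics
#' @param gate_cap cap on the inverse gate-envelope gain
#' @param pad_frac zero-padding fraction of the band span on each side
#' @param grid_size uniform grid length (power of two)
#' @return corrected transmittance, same shape and order as `ratio`
#' @export
xpm_correct <- function(ratio, wavenumber, calibration,
                        bg_amplitude = NULL, n_iter = 3,
                        sign = c("physical", "flipped"),
                        gate_cap = 20, pad_frac = 0.4, grid_size = 4096) {
  sign <- match.arg(sign)
  if (is.null(calibration$chirp_rate) || !is.finite(calibration$chirp_rate))
    stop("missing or invalid chirp calibration")
  if (calibration$chirp_rate == 0) return(ratio)   # no chirp, no artifact
  vec_in <- !is.matrix(ratio)
  Y <- if (vec_in) matrix(ratio, ncol = 1) else ratio
  if (nrow(Y) != length(wavenumber))
    stop("ratio and wavenumber axis lengths differ")
  o <- order(wavenumber)
  x <- wavenumber_to_angfreq(wavenumber[o])
  Y <- Y[o, , drop = FALSE]
  B <- if (is.null(bg_amplitude)) rep(1, length(x)) else {
    b <- bg_amplitude[o]
    b / max(b)
  }

  M <- grid_size
  pad <- (x[length(x)] - x[1]) * pad_frac
  xg <- seq(x[1] - pad, x[length(x)] + pad, length.out = M)
  dwg <- xg[2] - xg[1]
  op_fwd <- .interp_op(x, xg)
  op_bwd <- .interp_op(xg, x)
  ramp <- function(z) 0.5 * (1 + cos(pi * pmin(z, 1)))
  wtap <- rep(1, M)
  lo_e <- xg < x[1]; hi_e <- xg > x[length(x)]
  wtap[lo_e] <- ramp((x[1] - xg[lo_e]) / (pad * 0.8))
  wtap[hi_e] <- ramp((xg[hi_e] - x[length(x)]) / (pad * 0.8))

  Bg <- pmax(.interp_apply(op_fwd, B), 0.05)
  Rg <- .interp_apply(op_fwd, (Y - 1) * B) * wtap

  tau <- c(0:(M / 2 - 1), -(M / 2):-1) * 2 * pi / (M * dwg)
  cpT <- calibration$cp_duration_fs
  ginv <- if (is.finite(cpT) && !is.na(cpT)) {
    pmin(exp(2 * log(2) * (tau / cpT)^2), gate_cap)
  } else rep(1, M)
  keep <- tau >= 0

  run_branch <- function(a) {
    phase <- exp(-1i * a * tau^2 / 2) * ginv
    onesided <- function(V) {
      G <- stats::mvfft(V) * phase
      G[!keep, ] <- 0
      G[1, ] <- G[1, ] / 2
      stats::mvfft(G, inverse = TRUE) / M
    }
    rechirp_sq <- function(Fh) {
      g <- stats::mvfft(Fh) / M
      g <- g * (exp(1i * a * tau^2 / 2) / ginv)
      Mod(stats::mvfft(g, inverse = TRUE))^2
    }
    Fh <- onesided(Rg)
    if (n_iter > 1)
      for (i in seq_len(n_iter - 1))
        Fh <- onesided(Rg - rechirp_sq(Fh) / Bg)
    Mod(1 + Fh / Bg)^2
  }

  ## With the ascending-frequency forward FFT used here, the causal FID
  ## image on the kept delay half carries the phase +r*tau^2/2 (r the
  ## signed chirp rate), so the cancelling multiplier uses a = -r.
  a_eff <- -calibration$chirp_rate
  Tc <- switch(sign,
    "physical" = run_branch(a_eff),
    "flipped" = run_branch(-a_eff))

  out <- .interp_apply(op_bwd, Tc)
  out <- out[order(o), , drop = FALSE]
  if (vec_in) as.vector(out) else out
}

#' Transmittance spectrum from a sample/background pair
#'
#' Ratios the two measured spectra, maps the detection axis to MIR
#' wavenumber, applies [xpm_correct()], and reports a per-band wavenumber
#' resolution.  Bands whose background falls below `floor_frac` of the
#' background maximum are masked (`NA`).
#'
#' @param sample,background `measured_spectrum` objects on one axis
#' @param calibration a `chirp_calibration`
#' @param config the [optical_config()] used for the measurement (for the
#'   sampling-resolution bookkeeping and CP wavelength)
#' @param xpm apply the XPM correction
#' @param floor_frac background masking floor (fraction of max)
#' @param ... passed to [xpm_correct()]
#' @return a `transmittance_spectrum`: ascending `wavenumber_cm1`,
#'   `transmittance` (NA where masked), `resolution_cm1`, `mask`
#' @export
compute_transmittance <- function(sample, background, calibration, config,
                                  xpm = TRUE, floor_frac = 0.01, ...) {
  if (length(sample$counts) != length(background$counts) ||
      max(abs(sample$wavelength_nm - background$wavelength_nm)) > 1e-9)
    stop("sample and background axes differ")
  bad <- background$counts < floor_frac * max(background$counts)
  ratio <- ifelse(bad, 1, sample$counts / pmax(background$counts, 1e-12))
  wn <- sample$wavenumber_cm1
  Tr <- if (xpm) {
    xpm_correct(ratio, wn, calibration,
                bg_amplitude = sqrt(pmax(background$counts, 0)), ...)
  } else ratio
  o <- order(wn)
  res <- wavenumber_resolution(sample$wavelength_nm, config$spectral_sampling)
  structure(list(wavenumber_cm1 = wn[o],
                 transmittance = ifelse(bad[o], NA_real_, Tr[o]),
                 resolution_cm1 = res[o],
                 mask = !bad[o]),
            class = "transmittance_spectrum")
}

#' @export
print.transmittance_spectrum <- function(x, ...) {
  cat(sprintf(
    "<transmittance_spectrum> %d bands, %.0f-%.0f cm^-1, res %.2g-%.2g cm^-1\n",
    length(x$wavenumber_cm1), min(x$wavenumber_cm1), max(x$wavenumber_cm1),
    min(x$resolution_cm1), max(x$resolution_cm1)))
  invisible(x)
}

#' Rigid wavenumber calibration against the CO2 band
#'
#' Finds the absorption centroid inside `window` and shifts the axis so the
#' centroid lands on `reference`.  The instrument resolution cannot
#' separate individual rovibrational lines, so a single rigid offset (no
#' stretch) is applied.
#'
#' @param spectrum a `transmittance_spectrum`
#' @param reference reference centroid, cm^-1
#' @param window search window, cm^-1
#' @param min_depth minimum absorption depth to accept a dip
#' @return the spectrum with a shifted axis plus an `offset_cm1` field
#' @export
calibrate_wavenumber <- function(spectrum, reference = 2349,
                                 window = c(2300, 2400), min_depth = 0.02) {
  wn <- spectrum$wavenumber_cm1
  sel <- which(wn >= window[1] & wn <= window[2] & spectrum$mask)
  A <- pmax(1 - spectrum$transmittance[sel], 0)
  if (length(sel) == 0 || max(A, na.rm = TRUE) < min_depth)
    stop("no detectable absorption dip in the calibration window; ",
         "spectrum left unshifted")
  ## second pass: centroid over a window centered on the dip, so the
  ## Lorentzian wings are clipped symmetrically
  dip <- wn[sel][which.max(A)]
  sel <- which(abs(wn - dip) <= 30 & spectrum$mask)
  A <- pmax(1 - spectrum$transmittance[sel], 0)
  centroid <- sum(A * wn[sel], na.rm = TRUE) / sum(A, na.rm = TRUE)
  offset <- reference - centroid
  spectrum$wavenumber_cm1 <- wn + offset
  spectrum$offset_cm1 <- offset
  spectrum
}
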