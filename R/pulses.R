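## Field traces are complex analytic signals on a shared uniform time grid.
## Time axis is centered (t = 0 at the pulse); spectra use the FFT pairing
## E(t) = sum_k A(w_k) exp(+i w_k t), so fft(field) evaluates the spectrum
## and fft(A, inverse = TRUE)/n synthesizes the field.

#' Construct a field trace
#'
#' @param t uniform time axis, fs
#' @param field complex field samples
#' @param label which pulse this is ("MIR", "CP", "SFG", ...)
#' @return an object of class `field_trace`
#' @export
field_trace <- function(t, field, label = "field") {
  stopifnot(length(t) == length(field), length(t) >= 2)
  dt <- diff(t[1:2])
  if (max(abs(diff(t) - dt)) > 1e-9 * dt)
    stop("field_trace requires a uniform time grid")
  structure(list(t = t, field = field, dt = dt, label = label),
            class = "field_trace")
}

#' @export
print.field_trace <- function(x, ...) {
  cat(sprintf("<field_trace '%s'> %d samples, dt = %g fs, span %g ps\n",
              x$label, length(x$t), x$dt, diff(range(x$t)) / 1000))
  invisible(x)
}

#' Angular-frequency axis matching a field trace
#'
#' Frequencies are the non-negative FFT bins `2*pi*k/(n*dt)`; all physical
#' field content in this package lies well below the 2*pi/dt wrap.
#'
#' @param trace a [field_trace()]
#' @return numeric vector of angular frequencies, rad/fs
#' @export
trace_angfreq <- function(trace) {
  n <- length(trace$t)
  2 * pi * (seq_len(n) - 1) / (n * trace$dt)
}

## Synthesize a centered time field from a spectral amplitude defined on
## the trace_angfreq axis.  The n/2 roll places the pulse at t = 0 of the
## centered axis.
.field_from_spectrum <- function(A, t, dt) {
  n <- length(A)
  f <- stats::fft(A, inverse = TRUE) / n
  c(f[(n / 2 + 1):n], f[1:(n / 2)])
}

#' Intensity-envelope FWHM of a field trace
#'
#' Linear interpolation of the half-maximum crossings of `|field|^2`,
#' accurate to well below one time step for smooth envelopes.
#'
#' @param trace a [field_trace()]
#' @return FWHM in fs
#' @export
envelope_fwhm <- function(trace) {
  I <- Mod(trace$field)^2
  I <- I / max(I)
  ip <- which.max(I)
  half <- 0.5
  left <- which(I[1:ip] < half)
  right <- which(I[ip:length(I)] < half) + ip - 1
  if (length(left) == 0 || length(right) == 0)
    stop("envelope does not fall below half maximum inside the grid")
  i1 <- max(left)
  t1 <- trace$t[i1] + trace$dt * (half - I[i1]) / (I[i1 + 1] - I[i1])
  i2 <- min(right)
  t2 <- trace$t[i2 - 1] + trace$dt * (half - I[i2 - 1]) / (I[i2] - I[i2 - 1])
  t2 - t1
}

#' Total energy of a trace (arbitrary units)
#' @param trace a [field_trace()]
#' @return `sum(|field|^2) * dt`
#' @export
trace_energy <- function(trace) sum(Mod(trace$field)^2) * trace$dt

#' Generate the broadband MIR source pulse
#'
#' The spectral amplitude is a smooth super-Gaussian (4th-power exponent)
#' centered on the MIR band, with its width solved numerically so the
#' intensity-envelope FWHM equals `config$mir_pulse_fwhm` within one time
#' step.  Only relative spectral shape matters downstream because every
#' retrieved quantity is ratioed against a background measurement.
#'
#' @param config an [optical_config()]
#' @param grid optional grid from [make_time_grid()]
#' @return a [field_trace()] labelled "MIR"
#' @export
generate_mir_pulse <- function(config, grid = NULL) {
  if (is.null(grid)) grid <- make_time_grid(config)
  n <- grid$n; dt <- grid$dt
  if (2 * pi / dt <= 2 * wavenumber_to_angfreq(config$mir_band_hi))
    stop("invalid configuration: time grid too coarse for the MIR band")
  w <- 2 * pi * (seq_len(n) - 1) / (n * dt)
  w_lo <- wavenumber_to_angfreq(config$mir_band_lo)
  w_hi <- wavenumber_to_angfreq(config$mir_band_hi)
  wc <- (w_lo + w_hi) / 2
  mk <- function(width) {
    A <- exp(-log(2) / 2 * ((w - wc) / width)^4)
    field_trace(grid$t, .field_from_spectrum(A, grid$t, dt), "MIR")
  }
  target <- config$mir_pulse_fwhm
  f <- function(width) envelope_fwhm(mk(width)) - target
  lo <- 2 * pi / target / 50; hi <- 2 * pi / target * 2
  width <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  tr <- mk(width)
  attr(tr, "spectral_width") <- width
  attr(tr, "spectral_center") <- wc
  tr
}

#' Generate the stretched chirped gate pulse
#'
#' A Gaussian spectrum at `cp_center_wavelength` whose transform limit is
#' `cp_tl_fwhm` receives the quadratic spectral phase that stretches its
#' intensity envelope to `cp_duration`.  The returned calibration carries
#' the true chirp rate (d instantaneous angular frequency / d time,
#' rad/fs^2), measured from the synthesized field's phase so that it is the
#' same quantity a cross-correlation measurement estimates.
#'
#' @inheritParams generate_mir_pulse
#' @return list with `trace` (a [field_trace()] labelled "CP") and
#'   `calibration` (a `chirp_calibration`: chirp rate, center frequency,
#'   actual duration, spectral phase coefficient)
#' @export
generate_chirped_pulse <- function(config, grid = NULL) {
  if (is.null(grid)) grid <- make_time_grid(config)
  n <- grid$n; dt <- grid$dt
  T_tl <- config$cp_tl_fwhm
  T_out <- config$cp_duration * 1000
  if (T_out < T_tl)
    stop("requested cp_duration is below the transform limit")
  w <- 2 * pi * (seq_len(n) - 1) / (n * dt)
  w0 <- wavelength_to_angfreq(config$cp_center_wavelength)
  ## TL Gaussian: intensity I(t) ~ exp(-4 ln2 t^2 / T_tl^2)
  ##  -> spectral amplitude exp(-Omega^2 T_tl^2 / (8 ln2))
  ## quadratic phase phi2 stretches the envelope to
  ##  T_out = T_tl * sqrt(1 + (4 ln2 phi2 / T_tl^2)^2)
  phi2 <- if (T_out > T_tl) {
    T_tl^2 / (4 * log(2)) * sqrt((T_out / T_tl)^2 - 1)
  } else 0
  Om <- w - w0
  A <- exp(-Om^2 * T_tl^2 / (8 * log(2))) * exp(1i * phi2 * Om^2 / 2)
  tr <- field_trace(grid$t, .field_from_spectrum(A, grid$t, dt), "CP")
  dur <- envelope_fwhm(tr)
  cal <- list(
    chirp_rate = .fit_chirp_rate(tr, w0),
    center_angfreq = w0,
    cp_duration_fs = dur,
    phi2 = phi2,
    residual = 0
  )
  class(cal) <- "chirp_calibration"
  list(trace = tr, calibration = cal)
}

## Instantaneous-frequency slope of a trace, by linear fit of the unwrapped
## phase derivative over the bright part of the envelope.
.fit_chirp_rate <- function(trace, w0) {
  ph <- Arg(trace$field)
  dph <- diff(ph)
  dph <- atan2(sin(dph), cos(dph))          # unwrap increments
  winst <- dph / trace$dt
  tm <- (trace$t[-1] + trace$t[-length(trace$t)]) / 2
  I <- Mod(trace$field)^2
  Im <- (I[-1] + I[-length(I)]) / 2
  sel <- Im > 0.25 * max(Im)
  if (sum(sel) < 8) return(0)
  fit <- stats::lm(winst[sel] ~ tm[sel], weights = Im[sel])
  unname(stats::coef(fit)[2])
}

#' @export
print.chirp_calibration <- function(x, ...) {
  cat(sprintf(
    "<chirp_calibration> rate %.4g rad/fs^2, center %.4g rad/fs, duration %.0f fs\n",
    x$chirp_rate, x$center_angfreq, x$cp_duration_fs))
  invisible(x)
}

#' Transmit the MIR field through a sample
#'
#' Frequency-domain multiplication by the complex Lorentzian transmission of
#' a species mixture (Beer-Lambert in intensity, Kramers-Kronig-consistent
#' in phase).  Narrow lines leave a causal free-induction-decay tail after
#' the main pulse; composition of two passes equals one pass with summed
#' optical depths.
#'
#' @param mir a [field_trace()] (typically from [generate_mir_pulse()])
#' @param mixture named numeric vector: species name -> optical-depth scale
#' @param library a [species_library()]
#' @return a [field_trace()] of the transmitted field
#' @export
apply_sample <- function(mir, mixture, library) {
  if (length(mixture) == 0) return(mir)
  w <- trace_angfreq(mir)
  H <- mixture_transmission(w, mixture, library)
  spec <- stats::fft(mir$field) * H
  out <- stats::fft(spec, inverse = TRUE) / length(spec)
  field_trace(mir$t, out, mir$label)
}
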