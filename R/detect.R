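## The detection chain: product field -> spectrum -> camera.
## A `detector` object pre-computes the band-binning operator (a Gaussian
## resolution kernel in wavelength, one row per stored band) so that cube
## simulations pay the setup cost once.

#' Build the hyperspectral-camera detection operator
#'
#' @param config an [optical_config()]
#' @param grid time grid the fields live on (from [make_time_grid()])
#' @return a `detector` list: band wavelengths (nm), derived MIR wavenumbers
#'   (cm^-1), the selected FFT bins, and the resolution-kernel weight matrix
#' @export
make_detector <- function(config, grid) {
  n <- grid$n; dt <- grid$dt
  w <- 2 * pi * (seq_len(n) - 1) / (n * dt)
  win <- config$detection_window
  pad <- 4 * config$spectral_sampling
  sel <- which(w >= wavelength_to_angfreq(win[2] + pad) &
               w <= wavelength_to_angfreq(win[1] - pad))
  if (length(sel) < 8)
    stop("detection window lies outside the simulated spectral grid")
  lam_sel <- 2 * pi * .c_nmfs / w[sel]
  lam_b <- seq(win[1], win[2], length.out = config$n_bands)
  sigma <- config$spectral_sampling / (2 * sqrt(2 * log(2)))
  W <- outer(lam_b, lam_sel,
             function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
  W <- W / rowSums(W)
  mir <- sfg_to_mir_axis(lam_b, config$cp_center_wavelength)
  structure(list(wavelength_nm = lam_b,
                 wavenumber_cm1 = mir$wavenumber_cm1,
                 sel = sel, weights = W, config = config),
            class = "detector")
}

#' Draw multiplicative frame factors
#'
#' Log-normal factors with unit mean and RMS fractional deviation `rms`,
#' the frame-to-frame intensity fluctuation of the source.
#'
#' @param n number of factors
#' @param rms target RMS fractional deviation
#' @return numeric vector of length `n`
#' @export
draw_frame_factors <- function(n, rms) {
  if (rms <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rms^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Shot-noise sd (in counts) for a mean count level, scaled so that a
## full-scale signal has SNR = max_snr.
.shot_sd <- function(counts, full_scale, max_snr) {
  sqrt(pmax(counts, 0) * full_scale) / max_snr
}

#' Upconvert a MIR field with the chirped pulse and measure the spectrum
#'
#' Forms the product field `E_CP(t) * E_MIR(t)`, optionally applies the
#' phase-matching amplitude transfer to the MIR spectrum first, takes the
#' magnitude-squared spectrum, convolves it with the camera's wavelength
#' resolution kernel, samples the detection window at `n_bands` points,
#' applies one multiplicative frame factor plus per-band shot-like noise,
#' and clips/quantizes to the camera bit depth.
#'
#' @param mir transmitted MIR [field_trace()]
#' @param cp chirped-pulse [field_trace()] on the same grid
#' @param pm `NULL`, or a function of MIR wavenumber (cm^-1) returning
#'   relative conversion efficiency (see [pm_transfer()])
#' @param config an [optical_config()]
#' @param detector optional pre-built [make_detector()] operator
#' @param gain counts per spectral unit; `NULL` scales this spectrum's peak
#'   to 85% of full scale (use a common gain for sample/background pairs)
#' @param noise logical; apply frame + shot noise
#' @param quantize logical; clip and round to integer counts
#' @return a `measured_spectrum`: wavelength axis (nm), counts, gain, role
#' @export
sfg_and_measure <- function(mir, cp, pm = NULL, config,
                            detector = NULL, gain = NULL,
                            noise = TRUE, quantize = TRUE) {
  if (length(mir$t) != length(cp$t) || abs(mir$dt - cp$dt) > 1e-12)
    stop("MIR and chirped pulse must share one time grid")
  if (is.null(detector))
    detector <- make_detector(config, list(n = length(mir$t), dt = mir$dt))
  mir_field <- mir$field
  if (!is.null(pm)) {
    w <- trace_angfreq(mir)
    eff <- pm(angfreq_to_wavenumber(w))
    eff[!is.finite(eff) | eff < 0] <- 0
    spec <- stats::fft(mir_field) * sqrt(eff)
    mir_field <- stats::fft(spec, inverse = TRUE) / length(spec)
  }
  S <- Mod(stats::fft(mir_field * cp$field))^2
  bands <- as.vector(detector$weights %*% S[detector$sel])
  full_scale <- 2^config$bit_depth - 1
  if (is.null(gain)) gain <- 0.85 * full_scale / max(bands)
  counts <- bands * gain
  if (noise) {
    counts <- counts * draw_frame_factors(1, config$frame_noise_rms)
    counts <- counts + stats::rnorm(length(counts)) *
      .shot_sd(counts, full_scale, config$max_snr)
  }
  if (quantize) counts <- pmin(pmax(round(counts), 0), full_scale)
  structure(list(wavelength_nm = detector$wavelength_nm,
                 wavenumber_cm1 = detector$wavenumber_cm1,
                 counts = counts, gain = gain, role = "sample"),
            class = "measured_spectrum")
}

#' @export
print.measured_spectrum <- function(x, ...) {
  cat(sprintf("<measured_spectrum '%s'> %d bands, %g-%g nm, max %g counts\n",
              x$role, length(x$counts), min(x$wavelength_nm),
              max(x$wavelength_nm), max(x$counts)))
  invisible(x)
}

#' Spectrally resolved cross-correlation map
#'
#' Simulates the chirp-calibration measurement: the upconverted spectrum as
#' a function of the delay of the MIR pulse relative to the chirped pulse.
#' The intensity centroid of each spectral band traces the chirp, which
#' [instantaneous_frequency()] turns into a chirp rate.  With this delay
#' convention the fitted rate equals the chirped pulse's own
#' d(instantaneous frequency)/dt.
#'
#' @param mir,cp [field_trace()] objects on a common grid
#' @param config an [optical_config()]
#' @param delays delay axis in fs (default spans the stretched pulse)
#' @param detector optional [make_detector()] operator
#' @return list: `delay_fs`, `wavelength_nm`, `angfreq`, and `intensity`
#'   (matrix delays x bands)
#' @export
simulate_cross_correlation <- function(mir, cp, config, delays = NULL,
                                       detector = NULL) {
  if (is.null(delays)) {
    half <- 0.75 * config$cp_duration * 1000
    delays <- seq(-half, half, length.out = 49)
  }
  if (is.null(detector))
    detector <- make_detector(config, list(n = length(mir$t), dt = mir$dt))
  w <- trace_angfreq(mir)
  mir_spec <- stats::fft(mir$field)
  out <- matrix(0, length(delays), length(detector$wavelength_nm))
  for (i in seq_along(delays)) {
    mir_del <- stats::fft(mir_spec * exp(-1i * w * delays[i]),
                          inverse = TRUE) / length(w)
    S <- Mod(stats::fft(mir_del * cp$field))^2
    out[i, ] <- as.vector(detector$weights %*% S[detector$sel])
  }
  list(delay_fs = delays,
       wavelength_nm = detector$wavelength_nm,
       angfreq = wavelength_to_angfreq(detector$wavelength_nm),
       intensity = out)
}
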