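#' Optical configuration of the simulated imaging instrument
#'
#' Bundles every instrument parameter the forward model needs: the MIR
#' source band and pulse duration, the chirped near-IR gate pulse, the
#' visible detection window of the hyperspectral camera, digitization and
#' noise figures, and the laser repetition rate.
#'
#' Defaults describe the instrument this package emulates: a 13.6 fs
#' sub-cycle MIR pulse spanning 3-30 um (333-3333 cm^-1), a 1.8 ps chirped
#' gate at 790 nm stretched from a 35 fs transform limit, detection over
#' 638-752 nm sampled at 0.15 nm, 12-bit digitization, 2.77% RMS
#' frame-to-frame intensity fluctuation, a maximum single-frame
#' signal-to-noise ratio of 1365, and a 5 kHz repetition rate.  `n_bands`
#' defaults to a desk-scale 256 bands; `full_scale = TRUE` selects the
#' instrument's 1069 bands.
#'
#' @param mir_band_lo,mir_band_hi MIR source support, cm^-1
#' @param mir_pulse_fwhm MIR intensity-envelope FWHM, fs
#' @param cp_center_wavelength chirped-pulse center wavelength, nm
#' @param cp_duration chirped-pulse stretched intensity FWHM, ps
#' @param cp_tl_fwhm chirped-pulse transform-limited intensity FWHM, fs
#' @param detection_window camera wavelength window, nm (length 2, lo < hi)
#' @param spectral_sampling camera wavelength sampling/resolution, nm
#' @param n_bands number of spectral bands stored in a cube
#' @param bit_depth camera bit depth (full scale is `2^bit_depth - 1`)
#' @param frame_noise_rms RMS of the multiplicative frame factor (fraction)
#' @param max_snr maximum shot-noise-limited SNR at full scale
#' @param repetition_rate laser repetition rate, Hz
#' @param psf_sigma_um Gaussian spatial PSF sigma at the sample plane, um.
#'   The default (15 um / 2.5631) makes an ideal opaque edge show a 15 um
#'   10-90% edge response.
#' @param full_scale logical; use the full 1069-band instrument scale
#' @return an object of class `optical_config`
#' @examples
#' cfg <- optical_config()
#' cfg$n_bands
#' @export
optical_config <- function(mir_band_lo = 333,
                           mir_band_hi = 3333,
                           mir_pulse_fwhm = 13.6,
                           cp_center_wavelength = 790,
                           cp_duration = 1.8,
                           cp_tl_fwhm = 35,
                           detection_window = c(638, 752),
                           spectral_sampling = 0.15,
                           n_bands = if (full_scale) 1069L else 256L,
                           bit_depth = 12L,
                           frame_noise_rms = 0.0277,
                           max_snr = 1365,
                           repetition_rate = 5000,
                           psf_sigma_um = 15 / 2.5631,
                           full_scale = FALSE) {
  cfg <- list(
    mir_band_lo = mir_band_lo, mir_band_hi = mir_band_hi,
    mir_pulse_fwhm = mir_pulse_fwhm,
    cp_center_wavelength = cp_center_wavelength,
    cp_duration = cp_duration, cp_tl_fwhm = cp_tl_fwhm,
    detection_window = detection_window,
    spectral_sampling = spectral_sampling,
    n_bands = as.integer(n_bands), bit_depth = as.integer(bit_depth),
    frame_noise_rms = frame_noise_rms, max_snr = max_snr,
    repetition_rate = repetition_rate,
    psf_sigma_um = psf_sigma_um
  )
  class(cfg) <- "optical_config"
  validate_optical_config(cfg)
  cfg
}

#' @keywords internal
validate_optical_config <- function(cfg) {
  stopifnot(
    cfg$mir_band_lo > 0, cfg$mir_band_hi > cfg$mir_band_lo,
    cfg$mir_pulse_fwhm > 0,
    cfg$cp_center_wavelength > 0,
    length(cfg$detection_window) == 2,
    cfg$spectral_sampling > 0,
    cfg$n_bands >= 2, cfg$bit_depth >= 1,
    cfg$frame_noise_rms >= 0, cfg$max_snr > 0,
    cfg$repetition_rate > 0, cfg$psf_sigma_um >= 0
  )
  if (cfg$detection_window[1] >= cfg$detection_window[2])
    stop("detection_window must satisfy lo < hi")
  if (cfg$cp_duration * 1000 < cfg$cp_tl_fwhm)
    stop("cp_duration is shorter than the transform limit cp_tl_fwhm")
  invisible(cfg)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  MIR source    : %g-%g cm^-1, %g fs pulse\n",
              x$mir_band_lo, x$mir_band_hi, x$mir_pulse_fwhm))
  cat(sprintf("  chirped pulse : %g nm, %g ps (TL %g fs)\n",
              x$cp_center_wavelength, x$cp_duration, x$cp_tl_fwhm))
  cat(sprintf("  detection     : %g-%g nm @ %g nm, %d bands, %d bit\n",
              x$detection_window[1], x$detection_window[2],
              x$spectral_sampling, x$n_bands, x$bit_depth))
  cat(sprintf("  noise         : frame RMS %.2f%%, max SNR %g\n",
              100 * x$frame_noise_rms, x$max_snr))
  cat(sprintf("  repetition    : %g Hz\n", x$repetition_rate))
  invisible(x)
}

#' Time grid for field simulation
#'
#' Builds the uniform time grid shared by every field in a simulation.  The
#' step must resolve the highest sum-frequency component (Nyquist for the
#' complex field); the span must contain at least four chirped-pulse
#' durations and let the free-induction-decay tail of the narrowest
#' absorption line decay below 1e-6 of its initial amplitude.
#'
#' @param config an [optical_config()]
#' @param dt time step in fs (default 1)
#' @param min_linewidth narrowest Lorentzian FWHM (cm^-1) the grid must
#'   contain; sets the FID containment span
#' @return list with `n` (power of two), `dt` (fs), and `t` (time axis, fs,
#'   centered on zero)
#' @export
make_time_grid <- function(config, dt = 1, min_linewidth = 12) {
  w_max <- wavelength_to_angfreq(config$detection_window[1]) * 1.05
  if (2 * pi / dt <= 2 * w_max)
    stop("invalid configuration: time step too coarse to resolve the ",
         "sum-frequency field (need dt < ", signif(pi / w_max, 3), " fs)")
  gamma_min <- wavenumber_to_angfreq(min_linewidth) / 2
  span_fid <- log(1e6) / gamma_min + 2000
  span_cp <- 4 * config$cp_duration * 1000
  n <- 2^ceiling(log2(max(span_fid, span_cp) / dt))
  n <- max(n, 4096L)
  list(n = n, dt = dt, t = (seq_len(n) - 1 - n / 2) * dt)
}

#' Frame interval of discrete-frequency imaging
#'
#' Discrete-frequency imaging is clocked by the laser: one frame per shot.
#'
#' @param config an [optical_config()] (or a repetition rate in Hz)
#' @return frame spacing in seconds
#' @examples
#' frame_interval(optical_config())  # 2e-4 s at 5 kHz
#' @export
frame_interval <- function(config) {
  rate <- if (inherits(config, "optical_config")) config$repetition_rate
          else config
  stopifnot(rate > 0)
  1 / rate
}
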