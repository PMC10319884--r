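#' Hyperspectral cube container
#'
#' A `rows x cols x bands` intensity array with its wavelength axis, the
#' derived MIR wavenumber axis, the acquisition configuration, and the RNG
#' seed that produced it.
#'
#' @param data numeric or integer array `rows x cols x bands`
#' @param wavelength_nm per-band wavelength, nm (strictly monotone)
#' @param wavenumber_cm1 per-band MIR wavenumber, cm^-1
#' @param config the [optical_config()] snapshot
#' @param seed RNG seed used (or `NA`)
#' @return an object of class `hyperspec_cube`
#' @export
hyperspec_cube <- function(data, wavelength_nm, wavenumber_cm1 = NULL,
                           config = NULL, seed = NA_integer_) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[3] == length(wavelength_nm))
  d <- diff(wavelength_nm)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavelength axis must be strictly monotone")
  structure(list(data = data,
                 wavelength_nm = wavelength_nm,
                 wavenumber_cm1 = wavenumber_cm1,
                 config = config, seed = seed),
            class = "hyperspec_cube")
}

#' @export
print.hyperspec_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyperspec_cube> %d x %d px, %d bands (%g-%g nm), seed %s\n",
              d[1], d[2], d[3], min(x$wavelength_nm), max(x$wavelength_nm),
              as.character(x$seed)))
  invisible(x)
}

#' @export
dim.hyperspec_cube <- function(x) dim(x$data)

#' Pixel spectra of a cube as a matrix
#'
#' @param cube a [hyperspec_cube()]
#' @return matrix `pixels x bands`; pixels run down columns first (R array
#'   order), so pixel `(r, c)` is row `r + (c-1)*rows`
#' @export
cube_spectra <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

#' Index of the band nearest a MIR wavenumber
#'
#' @param cube a [hyperspec_cube()]
#' @param wavenumber target wavenumber(s), cm^-1
#' @return integer band indices
#' @export
band_index <- function(cube, wavenumber) {
  if (is.null(cube$wavenumber_cm1)) stop("cube has no wavenumber axis")
  vapply(wavenumber,
         function(v) which.min(abs(cube$wavenumber_cm1 - v)), 1L)
}

## Gaussian blur of each band image, replicate boundary.
.blur_bands <- function(arr, sigma_px) {
  if (sigma_px < 0.05) return(arr)
  sz <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  brush <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = sigma_px)
  img <- EBImage::Image(arr)
  out <- EBImage::filter2(img, brush, boundary = "replicate")
  array(EBImage::imageData(out), dim = dim(arr))
}

#' Simulate a hyperspectral cube from a phantom
#'
#' Runs the full forward model for every pixel of a phantom: MIR pulse ->
#' sample transmission (per-pixel species mixture) -> optional
#' phase-matching transfer -> chirped-pulse upconversion -> hyperspectral
#' camera.  Pixels sharing a mixture reuse one spectrum; the broadband
#' transmission factor, spatial PSF blur, per-frame and shot noise, and
#' quantization are then applied per pixel.  A paired background cube
#' (empty sample) is simulated with the same gain.  Identical seeds give
#' bit-identical cubes.
#'
#' @param phantom a [phantom_map()]
#' @param library a [species_library()]
#' @param config an [optical_config()]
#' @param seed integer seed controlling all randomness
#' @param noise apply frame + shot noise
#' @param pm optional phase-matching transfer from [pm_transfer()]
#' @param blur apply the Gaussian spatial PSF (`config$psf_sigma_um`)
#' @return a `cube_sim` list: `sample` and `background`
#'   [hyperspec_cube()]s, ground-truth `labels` + `legend`, the chirp
#'   `calibration`, `gain`, and the `phantom`
#' @export
simulate_cube <- function(phantom, library = default_species_library(),
                          config = optical_config(), seed = 1L,
                          noise = TRUE, pm = NULL, blur = TRUE) {
  stopifnot(inherits(phantom, "phantom_map"))
  min_fwhm <- if (length(library)) {
    min(vapply(library, function(s) min(s$fwhm), 1))
  } else 12
  grid <- make_time_grid(config, min_linewidth = min(min_fwhm, 12))
  mir <- generate_mir_pulse(config, grid)
  cpg <- generate_chirped_pulse(config, grid)
  detector <- make_detector(config, grid)
  full_scale <- 2^config$bit_depth - 1

  nS <- length(phantom$species_names)
  px_mix <- matrix(phantom$mixture, ncol = nS)
  colnames(px_mix) <- phantom$species_names
  sig <- if (nS > 0) apply(px_mix, 1, paste, collapse = "|")
         else rep("", phantom$rows * phantom$cols)
  usig <- unique(sig)
  idx <- match(sig, usig)

  bg_spec <- sfg_and_measure(mir, cpg$trace, pm = pm, config = config,
                             detector = detector, gain = 1,
                             noise = FALSE, quantize = FALSE)
  gain <- 0.85 * full_scale / max(bg_spec$counts)

  uspec <- matrix(0, length(usig), config$n_bands)
  for (u in seq_along(usig)) {
    mixrow <- if (nS > 0) px_mix[match(usig[u], sig), ] else numeric(0)
    mixture <- mixrow[mixrow > 0]
    tr <- apply_sample(mir, mixture, library)
    uspec[u, ] <- sfg_and_measure(tr, cpg$trace, pm = pm, config = config,
                                  detector = detector, gain = gain,
                                  noise = FALSE, quantize = FALSE)$counts
  }

  r <- phantom$rows; cc <- phantom$cols; B <- config$n_bands
  samp <- array(uspec[idx, ], c(r, cc, B)) *
    as.vector(phantom$transmission)
  bg <- array(rep(bg_spec$counts * gain, each = r * cc), c(r, cc, B))

  if (blur) {
    sigma_px <- config$psf_sigma_um / phantom$pixel_pitch_um
    samp <- .blur_bands(samp, sigma_px)
  }

  finish <- function(arr) {
    if (noise) {
      ff <- draw_frame_factors(B, config$frame_noise_rms)
      arr <- sweep(arr, 3, ff, `*`)
      arr <- arr + array(stats::rnorm(length(arr)), dim(arr)) *
        .shot_sd(arr, full_scale, config$max_snr)
    }
    array(as.integer(pmin(pmax(round(arr), 0), full_scale)), dim(arr))
  }
  withr::with_seed(seed, {
    samp <- finish(samp)
    bg <- finish(bg)
  })

  structure(list(
    sample = hyperspec_cube(samp, detector$wavelength_nm,
                            detector$wavenumber_cm1, config, seed),
    background = hyperspec_cube(bg, detector$wavelength_nm,
                                detector$wavenumber_cm1, config, seed),
    labels = phantom$labels, legend = phantom$legend,
    calibration = cpg$calibration, gain = gain, phantom = phantom),
    class = "cube_sim")
}

#' Per-pixel transmittance cube
#'
#' Ratios the sample cube against its background, maps bands to the MIR
#' wavenumber axis, and optionally applies the XPM correction to every
#' pixel spectrum (vectorized over pixels).  Bands with background below
#' `floor_frac` of its maximum are masked to `NA`.
#'
#' @param sim a `cube_sim` from [simulate_cube()] (or a list with `sample`,
#'   `background`, `calibration`)
#' @param xpm apply [xpm_correct()] per pixel
#' @param floor_frac background masking floor
#' @param n_iter XPM self-term iterations (cube default 2)
#' @param ... further arguments to [xpm_correct()]
#' @return a [hyperspec_cube()] holding transmittance values
#' @export
retrieve_cube <- function(sim, xpm = FALSE, floor_frac = 0.01,
                          n_iter = 2, ...) {
  s <- cube_spectra(sim$sample)
  b <- cube_spectra(sim$background)
  bg_mean <- colMeans(b)
  bad <- bg_mean < floor_frac * max(bg_mean)
  Tr <- s / pmax(b, 1)
  Tr[, bad] <- 1
  if (xpm) {
    Y <- t(Tr)                                    # bands x pixels
    Yc <- xpm_correct(Y, sim$sample$wavenumber_cm1, sim$calibration,
                      bg_amplitude = sqrt(pmax(bg_mean, 0)),
                      n_iter = n_iter, ...)
    Tr <- t(Yc)
  }
  Tr[, bad] <- NA_real_
  d <- dim(sim$sample$data)
  hyperspec_cube(array(Tr, d), sim$sample$wavelength_nm,
                 sim$sample$wavenumber_cm1, sim$sample$config,
                 sim$sample$seed)
}
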