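test_that("photon-energy conservation maps the detection window", {
  lo <- sfg_to_mir_axis(638, 790)
  hi <- sfg_to_mir_axis(752, 790)
  expect_equal(round(lo$wavelength_nm), 3316)
  expect_equal(round(hi$wavelength_nm), 15634)
  expect_equal(round(hi$wavenumber_cm1), 640)
  ## exact identity at every band: nu_SFG - nu_CP = nu_MIR
  lam <- seq(638, 752, length.out = 101)
  m <- sfg_to_mir_axis(lam, 790)
  expect_equal(1e7 / lam - 1e7 / 790, m$wavenumber_cm1, tolerance = 1e-12)
  ## degenerate symmetric case
  expect_equal(sfg_to_mir_axis(395, 790)$wavelength_nm, 790)
  expect_error(sfg_to_mir_axis(800, 790), "non-physical")
})

test_that("wavenumber resolution bookkeeping matches the sampling", {
  expect_equal(wavenumber_resolution(638, 0.15), 3.685, tolerance = 1e-3)
  expect_equal(wavenumber_resolution(752, 0.15), 2.652, tolerance = 1e-3)
  expect_equal(wavenumber_resolution(700, 0), 0)
})

test_that("sample equal to background retrieves unit transmittance", {
  rig <- full_rig()
  tv <- compute_transmittance(rig$background, rig$background,
                              rig$calibration, rig$config)
  expect_lt(max(abs(tv$transmittance - 1), na.rm = TRUE), 1e-9)
  expect_true(all(diff(tv$wavenumber_cm1) > 0))   # monotone axis out
})

test_that("zero-count background bands are masked, others unaffected", {
  rig <- full_rig()
  bg2 <- rig$background
  kill <- 100:110
  bg2$counts[kill] <- 0
  sm <- measure_mixture(c(glycerin = 1))
  tv <- compute_transmittance(sm, bg2, rig$calibration, rig$config)
  o <- order(sm$wavenumber_cm1)
  expect_true(all(is.na(tv$transmittance[which(o %in% kill)])))
  tv_ref <- compute_transmittance(sm, rig$background, rig$calibration,
                                  rig$config)
  keep <- !is.na(tv$transmittance)
  expect_lt(max(abs(tv$transmittance[keep] - tv_ref$transmittance[keep])),
            0.02)
})

test_that("axis mismatch between sample and background errors", {
  rig <- full_rig()
  sm <- rig$background
  sm$wavelength_nm <- sm$wavelength_nm + 0.01
  expect_error(compute_transmittance(sm, rig$background, rig$calibration,
                                     rig$config), "axes differ")
})

test_that("XPM correction removes the chirp artifact by >= 10x", {
  tv <- retrieve_mixture(c(co2 = 1))
  tv_raw <- retrieve_mixture(c(co2 = 1), xpm = FALSE)
  wn <- tv$wavenumber_cm1
  rng <- wn > 1200 & wn < 2250      # oscillation region below the band
  rms <- function(x) sqrt(mean(x^2, na.rm = TRUE))
  raw_art <- rms((tv_raw$transmittance - tv_raw$truth)[rng])
  cor_art <- rms((tv$transmittance - tv$truth)[rng])
  expect_gt(raw_art / cor_art, 10)
  ## dips stay confined to the CO2 band
  outside <- wn > 600 & wn < 2200
  expect_gt(min(tv$transmittance[outside], na.rm = TRUE), 0.93)
})

test_that("zero chirp rate makes the correction the identity", {
  cal0 <- list(chirp_rate = 0, cp_duration_fs = 1800)
  class(cal0) <- "chirp_calibration"
  x <- 1 + 0.1 * sin(seq(0, 6, length.out = 200))
  wn <- seq(700, 2900, length.out = 200)
  expect_identical(xpm_correct(x, wn, cal0), x)
  expect_error(xpm_correct(x, wn, list(chirp_rate = NULL)), "calibration")
})

test_that("the correction is stable once the artifact is removed", {
  tv <- retrieve_mixture(c(co2 = 1))
  rig <- full_rig()
  ## re-applying with a negligible residual rate changes nothing
  cal_eps <- rig$calibration
  cal_eps$chirp_rate <- rig$calibration$chirp_rate * 1e-6
  cal_eps$cp_duration_fs <- NA_real_
  again <- xpm_correct(tv$transmittance, tv$wavenumber_cm1, cal_eps,
                       n_iter = 3)
  expect_lt(max(abs(again - tv$transmittance), na.rm = TRUE), 0.01)
})

test_that("single lines across the band are recovered to specification", {
  ## round-trip property: noiseless forward model -> retrieval recovers
  ## transmittance within 0.02 and line centers within one resolution
  ## element, for lines across the fingerprint and functional-group bands
  ## (from ~200 cm^-1 above the low window edge, where the chirp artifact
  ## no longer runs off the detection window, up to the high edge)
  lib <- default_species_library()
  for (wn0 in c(850, 1100, 1500, 1900, 2300, 2700, 2900)) {
    lib_t <- species_library(probe = absorption_line(wn0, 0.4, 32))
    rig <- full_rig()
    sm <- measure_mixture(c(probe = 1), lib_t)
    tv <- compute_transmittance(sm, rig$background, rig$calibration,
                                rig$config)
    truth <- true_transmittance(tv$wavenumber_cm1, c(probe = 1), lib_t)
    expect_lt(max(abs(tv$transmittance - truth), na.rm = TRUE), 0.02)
    i_t <- which.min(truth)
    i_c <- which.min(tv$transmittance)
    expect_lte(abs(tv$wavenumber_cm1[i_c] - tv$wavenumber_cm1[i_t]),
               max(tv$resolution_cm1[i_t], diff(tv$wavenumber_cm1)[i_t]))
  }
})

test_that("CO2 wavenumber calibration recovers an injected axis offset", {
  tv <- retrieve_mixture(c(co2 = 1))
  shifted <- tv
  shifted$wavenumber_cm1 <- tv$wavenumber_cm1 + 5
  cal <- calibrate_wavenumber(shifted)
  expect_equal(cal$offset_cm1, -5, tolerance = 0.75)
  aligned <- calibrate_wavenumber(tv)
  expect_lt(abs(aligned$offset_cm1), 0.75)
  flat <- tv
  flat$transmittance[] <- 1
  expect_error(calibrate_wavenumber(flat), "no detectable")
})
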