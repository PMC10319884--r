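test_that("MIR pulse envelope matches the configured duration", {
  rig <- desk_rig()
  fw <- envelope_fwhm(rig$mir)
  expect_lt(abs(fw - 13.6), rig$grid$dt)

  cfg2 <- optical_config(mir_pulse_fwhm = 27.2)
  mir2 <- generate_mir_pulse(cfg2, rig$grid)
  expect_lt(abs(envelope_fwhm(mir2) - 27.2), rig$grid$dt)

  ## sub-cycle: shorter than one optical period at 10 um
  cycle_10um <- 10000 / (299.792458)         # lambda/c in fs
  expect_lt(fw, cycle_10um)
  expect_equal(round(cycle_10um, 1), 33.4, tolerance = 1e-3)
})

test_that("MIR spectral support covers the configured band", {
  rig <- desk_rig()
  S <- Mod(stats::fft(rig$mir$field))^2
  w <- trace_angfreq(rig$mir)
  lo <- wavenumber_to_angfreq(rig$config$mir_band_lo)
  hi <- wavenumber_to_angfreq(rig$config$mir_band_hi)
  inband <- w >= lo & w <= hi
  expect_gt(min(S[inband]), 1e-4 * max(S))
  ## and decays far outside the band
  far <- w > 1.5 * hi & w < 2 * hi
  expect_lt(max(S[far]), 1e-8 * max(S))
})

test_that("time grid validation rejects a grid too coarse for the band", {
  expect_error(make_time_grid(optical_config(), dt = 4),
               "too coarse")
  expect_error(generate_mir_pulse(optical_config(),
                                  grid = list(n = 4096, dt = 8,
                                              t = (1:4096 - 2048) * 8)),
               "too coarse")
})

test_that("chirped pulse stretches to the configured duration", {
  rig <- desk_rig()
  expect_lt(abs(rig$calibration$cp_duration_fs - 1800), 5)
  ## zero added chirp: duration equals the transform limit
  cfg_tl <- optical_config(cp_duration = 35 / 1000)
  tl <- generate_chirped_pulse(cfg_tl, rig$grid)
  expect_lt(abs(envelope_fwhm(tl$trace) - 35), 1.5)
  expect_equal(tl$calibration$phi2, 0)
  ## shorter than the transform limit is rejected
  expect_error(optical_config(cp_duration = 0.020),
               "transform limit")
})

test_that("generator chirp rate matches the cross-correlation slope fit", {
  rig <- desk_rig()
  xc <- simulate_cross_correlation(rig$mir, rig$cp, rig$config,
                                   detector = rig$detector)
  cal <- instantaneous_frequency(xc)
  expect_lt(abs(cal$chirp_rate - rig$calibration$chirp_rate) /
              abs(rig$calibration$chirp_rate), 0.01)
})

test_that("doubling the chirped-pulse duration halves the chirp rate", {
  rig <- desk_rig()
  cfg2 <- optical_config(cp_duration = 3.6)
  cp2 <- generate_chirped_pulse(cfg2, rig$grid)
  cal1 <- instantaneous_frequency(
    simulate_cross_correlation(rig$mir, rig$cp, rig$config,
                               detector = rig$detector))
  cal2 <- instantaneous_frequency(
    simulate_cross_correlation(rig$mir, cp2$trace, cfg2,
                               detector = rig$detector))
  expect_equal(cal2$chirp_rate / cal1$chirp_rate, 0.5, tolerance = 0.01)
})

test_that("an unchirped pulse gives a degenerate calibration fit", {
  rig <- desk_rig()
  cfg_tl <- optical_config(cp_duration = 36 / 1000)
  tl <- generate_chirped_pulse(cfg_tl, rig$grid)
  ## scanned over the instrument's standard picosecond delay range
  xc <- simulate_cross_correlation(rig$mir, tl$trace, cfg_tl,
                                   delays = seq(-1350, 1350,
                                                length.out = 49),
                                   detector = rig$detector)
  expect_error(instantaneous_frequency(xc),
               "degenerate|sweep|too few")
})

test_that("Parseval holds at every field transformation before detection", {
  rig <- desk_rig()
  lib <- default_species_library()
  parseval_ok <- function(trace) {
    et <- sum(Mod(trace$field)^2) * trace$dt
    sp <- stats::fft(trace$field)
    n <- length(sp)
    ef <- sum(Mod(sp)^2) * trace$dt / n
    abs(et - ef) / et
  }
  expect_lt(parseval_ok(rig$mir), 1e-9)
  expect_lt(parseval_ok(rig$cp), 1e-9)
  tr <- apply_sample(rig$mir, c(glycerin = 1, water = 0.5), lib)
  expect_lt(parseval_ok(tr), 1e-9)
  prod <- field_trace(tr$t, tr$field * rig$cp$field, "SFG")
  expect_lt(parseval_ok(prod), 1e-9)
})
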