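test_that("quantized counts respect the bit-depth clipping contract", {
  rig <- desk_rig()
  sp <- sfg_and_measure(rig$mir, rig$cp, config = rig$config,
                        detector = rig$detector, noise = FALSE)
  expect_true(is.numeric(sp$counts))
  expect_true(all(sp$counts == round(sp$counts)))
  expect_true(all(sp$counts >= 0))
  expect_true(all(sp$counts <= 2^12 - 1))
  ## noise on: still clipped after quantization
  sp2 <- withr::with_seed(1, sfg_and_measure(rig$mir, rig$cp,
                                             config = rig$config,
                                             detector = rig$detector,
                                             noise = TRUE))
  expect_true(all(sp2$counts >= 0 & sp2$counts <= 4095))
})

test_that("noise-off empty-sample spectrum is a smooth background", {
  rig <- desk_rig()
  sp <- sfg_and_measure(rig$mir, rig$cp, config = rig$config,
                        detector = rig$detector, noise = FALSE,
                        quantize = FALSE)
  bright <- sp$counts > 0.2 * max(sp$counts)
  rel_rough <- abs(diff(sp$counts, differences = 2)) / max(sp$counts)
  expect_lt(max(rel_rough[bright[-c(1, length(bright))]]), 5e-3)
})

test_that("a CO2 sample produces transmittance dips in its band", {
  rig <- desk_rig()
  lib <- default_species_library()
  bg <- sfg_and_measure(rig$mir, rig$cp, config = rig$config,
                        detector = rig$detector, gain = 1,
                        noise = FALSE, quantize = FALSE)
  sm <- sfg_and_measure(apply_sample(rig$mir, c(co2 = 1), lib), rig$cp,
                        config = rig$config, detector = rig$detector,
                        gain = 1, noise = FALSE, quantize = FALSE)
  ratio <- sm$counts / bg$counts
  wn <- bg$wavenumber_cm1
  in_band <- wn >= 2300 & wn <= 2400
  out_band <- wn >= 1400 & wn <= 1800
  ## the raw (uncorrected) dip is chirp-smeared but clearly present
  expect_lt(min(ratio[in_band]), 0.85)
  expect_gt(min(ratio[out_band]), 0.95)
  expect_lt(min(ratio[in_band]), min(ratio[out_band]) - 0.1)
})

test_that("frame factors recover the configured RMS within 3 SE", {
  r <- 0.0277
  n <- 2e4
  f <- withr::with_seed(42, draw_frame_factors(n, r))
  rms <- sqrt(mean((f - 1)^2))
  se <- r / sqrt(2 * n)       # SE of an RMS estimate
  expect_lt(abs(rms - r), 3 * se)
  expect_identical(draw_frame_factors(5, 0), rep(1, 5))
})

test_that("a detection window outside the simulated grid errors", {
  rig <- desk_rig()
  bad <- optical_config(detection_window = c(180, 190))
  expect_error(make_detector(bad, rig$grid), "outside")
})

test_that("measurement requires a shared time grid", {
  rig <- desk_rig()
  g2 <- make_time_grid(rig$config, dt = 0.5)
  mir2 <- generate_mir_pulse(rig$config, g2)
  expect_error(sfg_and_measure(mir2, rig$cp, config = rig$config),
               "share")
})
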