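## Shared simulation fixtures, built lazily and cached for the whole run.
## Everything is generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## Desk-scale instrument (256 bands) with its pulses and detector.
desk_rig <- function() .cached("desk", function() {
  config <- optical_config()
  grid <- make_time_grid(config)
  mir <- generate_mir_pulse(config, grid)
  cpg <- generate_chirped_pulse(config, grid)
  list(config = config, grid = grid, mir = mir,
       cp = cpg$trace, calibration = cpg$calibration,
       detector = make_detector(config, grid))
})

## Full-scale spectral sampling (1069 bands) for retrieval-quality checks.
full_rig <- function() .cached("full", function() {
  config <- optical_config(full_scale = TRUE)
  grid <- make_time_grid(config)
  mir <- generate_mir_pulse(config, grid)
  cpg <- generate_chirped_pulse(config, grid)
  det <- make_detector(config, grid)
  bg <- sfg_and_measure(mir, cpg$trace, config = config, detector = det,
                        gain = 1, noise = FALSE, quantize = FALSE)
  list(config = config, grid = grid, mir = mir,
       cp = cpg$trace, calibration = cpg$calibration,
       detector = det, background = bg)
})

## Noiseless measurement of a mixture on the full-scale rig.
measure_mixture <- function(mixture, library = default_species_library()) {
  rig <- full_rig()
  tr <- apply_sample(rig$mir, mixture, library)
  sfg_and_measure(tr, rig$cp, config = rig$config, detector = rig$detector,
                  gain = 1, noise = FALSE, quantize = FALSE)
}

## Retrieved vs true transmittance for a mixture (noiseless, full scale).
retrieve_mixture <- function(mixture,
                             library = default_species_library(), ...) {
  rig <- full_rig()
  sm <- measure_mixture(mixture, library)
  tv <- compute_transmittance(sm, rig$background, rig$calibration,
                              rig$config, ...)
  tv$truth <- true_transmittance(tv$wavenumber_cm1, mixture, library)
  tv
}

## Microchannel simulation cached per (seed, noise).
channel_sim <- function(seed, noise) {
  key <- sprintf("chan_%d_%d", seed, noise)
  .cached(key, function() {
    simulate_cube(make_phantom("microchannel5"),
                  default_species_library(), optical_config(),
                  seed = seed, noise = noise)
  })
}

## Teaching constraint that fits the desk-scale channels.
channel_constraint <- function(n_regions = 8) {
  region_constraint(x_min = 1, x_max = 6, y_min = 2, y_max = 9,
                    area_min = 3, area_max = 36, n_regions = n_regions)
}

## The teaching-peak wavenumbers used in the channel mapping workflow.
teaching_peaks <- function() {
  c(851, 920, 1030, 1142, 1360, 1427, 1542, 1658, 1089, 1250, 1463, 1747)
}
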