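#!/usr/bin/env Rscript
## Stage 4: chemometric mapping.
##
## Loads (or regenerates) the microchannel cubes, converts them to
## per-pixel transmittance, samples constrained non-overlapping teaching
## regions inside each channel, and maps the five species by spectral
## angle mapper and by Fisher LDA on the teaching-peak bands.  Also
## derives the spatial resolution from a simulated copper-mesh image and
## the timing of a discrete-frequency water-flow sequence.

suppressMessages(library(chirpmir))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- optical_config()
lib <- default_species_library()
phantom <- make_phantom("microchannel5")

sample_path <- file.path(out_dir, "microchannel_sample")
sim <- if (file.exists(paste0(sample_path, ".hdr"))) {
  list(sample = read_envi_cube(sample_path),
       background = read_envi_cube(file.path(out_dir,
                                             "microchannel_background")),
       labels = phantom$labels, legend = phantom$legend,
       calibration = generate_chirped_pulse(config)$calibration)
} else {
  simulate_cube(phantom, lib, config, seed = seed, noise = TRUE,
                pm = pm_transfer(gase_crystal()))
}

tr <- retrieve_cube(sim, xpm = FALSE)

## teaching: 8 non-overlapping rectangles per channel, then class means
rc <- region_constraint(x_min = 1, x_max = 6, y_min = 2, y_max = 9,
                        area_min = 3, area_max = 36, n_regions = 8)
teach <- sample_teaching_regions(tr, rc, seed = seed + 2,
                                 label_map = sim$labels,
                                 legend = sim$legend)
utils::write.csv(teach$regions,
                 file.path(out_dir, "teaching_regions.csv"),
                 row.names = FALSE)
utils::write.csv(
  data.frame(class = rownames(class_mean_spectra(teach)),
             class_mean_spectra(teach), check.names = FALSE),
  file.path(out_dir, "teaching_spectra.csv"), row.names = FALSE)

inch <- sim$labels > 0

## spectral angle mapper on full spectra
cm_sam <- sam_classify(tr, teach)
acc_sam <- mean(cm_sam[inch] == sim$labels[inch])
write_class_map(cm_sam, file.path(out_dir, "map_sam"))

## Fisher LDA on the teaching-peak bands
peaks <- c(851, 920, 1030, 1142, 1360, 1427, 1542, 1658, 1089, 1250,
           1463, 1747)
bi <- band_index(tr, peaks)
teach_pk <- teach
teach_pk$spectra <- teach$spectra[, bi]
mdl <- lda_train(teach_pk)
cm_lda <- lda_classify(tr, mdl, bands = bi)
acc_lda <- mean(cm_lda[inch] == sim$labels[inch])
write_class_map(cm_lda, file.path(out_dir, "map_lda"))

cat(sprintf("in-channel accuracy: SAM %.1f%%, teaching-peak LDA %.1f%% (J = %.3g)\n",
            100 * acc_sam, 100 * acc_lda, mdl$J))

## location information: additive averaging + NDSI masks
av <- additive_averaging(tr, wavenumber_range = c(800, 1100))
nd <- ndsi_map(tr, band_index(tr, 1030), band_index(tr, 1658))
cat(sprintf("additive-averaging map range %.2f-%.2f; NDSI range %+.2f..%+.2f\n",
            min(av$map), max(av$map), min(nd$map), max(nd$map)))

## spatial resolution from the copper-mesh image
mesh <- make_phantom("mesh_grid", rows = 48, cols = 64,
                     pixel_pitch_um = 1.25, bar_width_um = 30,
                     period_um = 160)
simM <- simulate_cube(mesh, lib, optical_config(n_bands = 32),
                      seed = seed, noise = FALSE)
avM <- additive_averaging(simM$sample, bands = 1:32)
er <- edge_response_resolution(avM$map[24, 12:45], pixel_pitch_um = 1.25)
cat(sprintf("10-90%% edge response of the mesh image: %.1f um\n", er))

## discrete-frequency flow timing
frames <- make_phantom("flow_sequence", n_frames = 3)
cat(sprintf("flow sequence frame spacing: %.1f ms at %g kHz\n",
            1000 * diff(attr(frames, "times_s"))[1],
            optical_config()$repetition_rate / 1000))

utils::write.csv(
  data.frame(metric = c("sam_accuracy_pct", "lda_accuracy_pct",
                        "edge_response_um"),
             value = c(100 * acc_sam, 100 * acc_lda, er)),
  file.path(out_dir, "chemometrics_summary.csv"), row.names = FALSE)
run_record("analyze", seed,
           outputs = file.path(out_dir, "chemometrics_summary.csv"),
           path = file.path(out_dir, "run_04_chemometrics.json"))
cat("Stage 4 maps and tables written under", out_dir, "\n")
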