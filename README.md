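# chirpmir

Simulation and chemometric mapping for scanless mid-infrared (MIR)
hyperspectral chemical imaging by chirped-pulse sum-frequency
upconversion.

## The problem and who this is for

MIR spectroscopy identifies chemical species through their molecular
vibrations: the fingerprint region (< 1500 cm⁻¹) pins down individual
compounds, the functional-group region (≥ 1500 cm⁻¹) reports bond types.
A scanless imaging instrument can cover the whole 640–3015 cm⁻¹ band at
once by mixing a broadband sub-cycle MIR pulse, transmitted through the
sample, with a long linearly chirped near-IR gate pulse in a thin GaSe
crystal placed at the image plane.  Type-I sum-frequency generation
(SFG) copies the MIR spectrum — including the picosecond free-induction
decay (FID) of narrow absorption lines — into the visible
(638–752 nm), where a silicon hyperspectral camera records a
640 × 480 × 1069 data cube.  Chemical maps then follow from per-pixel
spectral analysis.

`chirpmir` is for instrument modellers and hyperspectral-analysis
developers: it provides a physics-based forward simulator of that whole
chain, the matching spectral retrieval, and the cube chemometrics, so
every analysis stage can be developed and tested against known ground
truth without any experimental data.

## What is inside

* **Forward model** (`generate_mir_pulse`, `generate_chirped_pulse`,
  `apply_sample`, `sfg_and_measure`, `simulate_cube`, `make_phantom`) —
  complex optical fields on a common time grid; Beer–Lambert Lorentzian
  absorbers with Kramers–Kronig-consistent phase, so lines ring as
  causal FID tails; the product field `E_CP(t)·E_MIR(t)`; a 12-bit
  camera with 0.15 nm sampling, one multiplicative frame factor
  (RMS 2.77 %) and shot-like noise (max SNR 1365); microchannel, copper
  mesh, water-flow and blob phantoms.
* **Phase matching** (`gase_crystal`, `delta_k`,
  `conversion_efficiency`, `band_coverage`) — GaSe Sellmeier indices,
  collinear type-I (o + o → e) mismatch, `η ∝ L² sinc²(ΔkL/2)`: a 4.4 µm
  film covers 640–3015 cm⁻¹ with strictly positive efficiency while a
  100 µm crystal fringes to zero.
* **Retrieval** (`sfg_to_mir_axis`, `instantaneous_frequency`,
  `xpm_correct`, `compute_transmittance`, `calibrate_wavenumber`,
  `retrieve_cube`) — photon-energy axis mapping
  `1/λ_MIR = 1/λ_SFG − 1/λ_CP`; chirp calibration from a spectrally
  resolved cross-correlation; removal of the cross-phase-modulation
  (XPM) artifact by correcting the parabolic phase `a·τ²/2` of the
  delay-domain transform of the measured spectrum; rigid wavenumber
  calibration on the CO₂ band near 2349 cm⁻¹.
* **Chemometrics** (`additive_averaging`, `ndsi_map`,
  `sample_teaching_regions`, `sam_classify`, `lda_train`,
  `lda_classify`, `edge_response_resolution`) — the band mean
  `I_ave = S/n`; `NDSI = (I₁ − I₂)/(I₁ + I₂)`; constrained
  non-overlapping teaching rectangles; spectral angle mapper
  (unit-normalized inner products); Fisher LDA maximizing
  `J(w) = (wᵀS_B w)/(wᵀS_W w)` by the generalized eigenproblem; the
  10–90 % edge-response spatial resolution.

## Worked example

The numbered scripts under `analysis/` run the whole study at desk scale
(64 × 48 × 256 cubes); each is a thin driver over the package functions:

```sh
Rscript analysis/01_simulate_instrument.R   # cubes -> results/*.img
Rscript analysis/02_phase_matching.R        # GaSe efficiency curves
Rscript analysis/03_retrieval.R             # chirp cal., CO2 retrieval
Rscript analysis/04_chemometrics.R          # SAM / LDA maps, resolution
```

Representative output (seed 1):

```
MIR envelope FWHM 13.60 fs; chirped gate 1800 fs, rate -4.400e-05 rad/fs^2
GaSe   4.4 um: min in-band efficiency 0.701 at 3015 cm^-1 -> covers 640-3015 cm^-1
GaSe 100.0 um: min in-band efficiency 0.000 at 695 cm^-1 -> fringes to zero in band
chirp rate: generator -4.40010e-05, cross-correlation fit -4.39972e-05 rad/fs^2 (0.01% apart)
XPM artifact RMS (1200-2250 cm^-1): raw 0.0215, corrected 0.00065 (33x reduction)
     species max_abs_error center_error_cm1
    glycerin       0.01487                0
         co2       0.00994                0
in-channel accuracy: SAM 100.0%, teaching-peak LDA 100.0% (J = 9.01e+03)
10-90% edge response of the mesh image: 14.9 um
```

Reading the numbers: the 13.6 fs source and 1.8 ps gate come out of the
synthesis at their configured values; the thin film passes the whole
band while the thick crystal does not; the chirp rate recovered from the
simulated cross-correlation matches the generator to 0.01 %; after the
XPM correction every shipped absorber's transmittance is recovered to
better than 0.015 with line centers on the correct band; all five
channel fillings (glycerin, glucose, albumin, DOPC, soybean oil) are
mapped correctly by both classifiers; and the mesh image shows the
~15 µm 10–90 % edge response set by the instrument's point-spread
function.

## Layout

```
R/                  implementation (forward model, phase matching,
                    retrieval, chemometrics, I/O)
analysis/           numbered narrative drivers writing results/
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, assumptions, choices)
```
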