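---
title: "Methods: simulating and analysing chirped-pulse upconversion MIR imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing chirped-pulse upconversion MIR imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpmir)
```

This vignette explains the physical model behind `chirpmir`, the
numerical choices it makes, and what its passing tests do and do not
demonstrate about real measurements.

## The measurement being modelled

A sub-cycle MIR pulse (13.6 fs envelope, spectral support
333–3333 cm⁻¹) irradiates the whole sample at once.  Absorption lines
imprint both an amplitude dip and — because absorption is causal — a
picosecond free-induction-decay (FID) tail on the transmitted field.  A
790 nm gate pulse, stretched to 1.8 ps by a grating pair, is mixed with
the transmitted MIR in a thin GaSe film at the image plane; type-I SFG
produces the product field $E_\mathrm{CP}(t)\,E_\mathrm{MIR}(t)$ whose
visible spectrum (638–752 nm after the long/short-pass filters) encodes
the MIR spectrum.  A 12-bit hyperspectral camera samples that window at
0.15 nm, i.e. 2.6–3.7 cm⁻¹ of MIR wavenumber per step.

All fields live on one uniform time grid (1 fs step, power-of-two
length, span at least four gate durations and long enough that the FID
of the narrowest line decays below $10^{-6}$; the default grid is
16 384 points).  Spectra use the convention
$E(t)=\sum_k A(\omega_k) e^{+i\omega_k t}$, so `fft()` evaluates
spectra and its inverse synthesizes fields.

### Source spectrum

Only the *relative* spectral shape of the source matters downstream,
because every retrieved quantity is ratioed against a background
measurement.  The MIR spectral amplitude is therefore a smooth
super-Gaussian (fourth-power exponent) over the band, with its width
solved numerically so the intensity-envelope FWHM equals the configured
13.6 fs within one time step.

### Absorbers

A species is a list of Lorentzian lines (center, peak optical depth
$s$, FWHM).  The field transmission of a line of half-width $\Gamma$
(rad/fs) at $\omega_0$ is

$$H(\omega)=\exp\!\left(-\frac{s}{2}\,
  \frac{\Gamma}{\Gamma + i(\omega-\omega_0)}\right),$$

whose real part of the exponent is the unit-peak Lorentzian scaled by
$s/2$ and whose imaginary part is its Kramers–Kronig partner: the
time-domain response is strictly causal and narrow lines ring as FID
with field $1/e$ time $1/(\pi c\,\mathrm{fwhm})$.  Transmission through
two samples composes exactly as summed optical depths.

The shipped library carries the teaching bands of the mapping
workflows: glycerin (851, 920, 1030 cm⁻¹), glucose (1142, 1360,
1427), albumin (1542, 1658), DOPC (1089, 1250), soybean oil (1463,
1747), water (1640) and CO₂ (2349).  Strengths are peak optical depths
of 0.35–0.8 — thin films and 25 µm channel fillings, giving
transmittance dips of roughly 0.3–0.6 — and widths are typical
condensed-phase values (24–40 cm⁻¹), 80 cm⁻¹ for the very broad liquid
water bending band, and an 18 cm⁻¹ *effective* envelope for CO₂: at
2.6–3.7 cm⁻¹ resolution the rovibrational structure is unresolved, and
the retrieval calibrates on the band centroid, so a single effective
band is the appropriate model.

### Phase matching

GaSe ordinary and principal extraordinary indices use a standard
published Sellmeier set (nominal validity 0.65–18 µm; the guard is
relaxed to 0.62 µm so the 638 nm SFG edge, still inside GaSe's
transparency range, can be evaluated).  The collinear type-I mismatch
is $\Delta k = k_e(\mathrm{SFG}) - k_o(\mathrm{CP}) -
k_o(\mathrm{MIR})$ and the relative efficiency
$\eta \propto L^2\,\mathrm{sinc}^2(\Delta k L/2)$.  The film's internal
propagation angle is a free parameter; its default, 26.5°, was chosen
once as the angle that maximizes the *minimum* in-band efficiency of
the 4.4 µm film over 640–3015 cm⁻¹ (phase-matched near 2030 cm⁻¹,
in-band minimum ≈ 0.70 of peak).  `band_coverage()` scans on a
≤ 1 cm⁻¹ grid and additionally reports an exact zero whenever
$\Delta k L/2$ crosses a non-zero multiple of $\pi$ between grid
points — without this, a discrete scan of a thick crystal would always
report a small positive minimum and the fringing verdict would be
wrong.  No walk-off, crystal absorption or étalon effects are modelled.

### Detection

The product-field spectrum is convolved with a Gaussian kernel of FWHM
equal to the 0.15 nm sampling, sampled at `n_bands` points across
638–752 nm, scaled so an unattenuated background peaks at 85 % of full
scale, multiplied by one log-normal frame factor of RMS 2.77 %, given
per-band Gaussian shot-like noise scaled so a full-scale signal has
SNR 1365, clipped and rounded to 12-bit integers.  `n_bands` and the
window are independent configuration values (the relation between the
instrument's 1069 points and its 0.15 nm step over the window is not
specified further); the desk-scale default is 256 bands, with
`full_scale = TRUE` selecting 1069.

Cube simulation deduplicates pixels by mixture (a five-channel phantom
needs only a handful of distinct spectra), applies the per-pixel
broadband transmission factor (walls, mesh bars, menisci), blurs every
band with an isotropic Gaussian PSF, then draws noise per band and per
voxel.  The PSF sigma default, 15/2.5631 ≈ 5.85 µm, makes an ideal
opaque edge show a 15 µm 10–90 % edge response.  Identical seeds give
bit-identical cubes.

## Retrieval

The measured sample spectrum is ratioed against the nitrogen-purged
background, mapped to MIR wavenumber by photon-energy conservation
($1/\lambda_\mathrm{MIR} = 1/\lambda_\mathrm{SFG} -
1/\lambda_\mathrm{CP}$), and corrected for the chirp-induced
cross-phase-modulation artifact.

### Chirp calibration

The chirp rate $a$ (rad/fs²) is fitted from a spectrally resolved
cross-correlation: the SFG spectrum as the MIR pulse is delayed across
the gate.  The per-delay spectral centroid is the gate's instantaneous
frequency; its slope against delay is $a$.  Two estimator details
matter for a *broadband* source whose envelope is clipped by the
detection window: (i) the per-frequency "centroid delay" construction
(the transposed estimator) is dominated by the static spectral envelope
and fails badly, so the per-delay centroid is used; (ii) a plain
centroid is still biased by the window edges, so the centroid is taken
inside a sub-window that translates with the current rate estimate and
the fit is iterated to its fixed point, at which the clipped mass is
delay-independent.  The recovered rate matches the generator to ~0.01 %.
A near-transform-limited gate scanned over the standard picosecond
range leaves too few bright delay slices, or an uncorrelated centroid
trace, and is flagged as degenerate.

### The XPM correction

With a linearly chirped gate $e^{i(\omega_0 t + a t^2/2)}$, the delay-domain
transform $G(\tau)$ of the measured spectrum (the autocorrelation of
the upconverted field) factors the FID cross-term as
$f(\tau)\,e^{\pm i a\tau^2/2}$: the line information is smeared into a
chirped oscillation running from the line toward low wavenumber.  The
correction:

1. resample the ratioed spectrum onto a uniform frequency grid with
   tapered zero-padding (0.4 of the band span per side, 4096-point
   grid; linear interpolation — smooth spectra do not ring);
2. weight the fluctuation $(R-1)$ by the background field amplitude
   $\sqrt{S_b}$, so the artifact components are regathered with the
   weights the field gave them (without this, lines near the sloping
   envelope edges are mis-restored by ~5 %);
3. transform to delay, multiply by $e^{-i a_\mathrm{eff}\tau^2/2}$ with
   $a_\mathrm{eff}$ = minus the signed calibrated rate (the branch
   follows from the fixed transform convention; the `flipped` option
   exists for diagnostics), and divide by the known Gaussian gate
   envelope (capped at 20× — the gate attenuates late FID, which is the
   physical resolution limit of the method);
4. zero the anti-causal half of the delay axis (it holds the
   doubly-chirped mirror image), halve the DC bin (it is shared by both
   halves; forgetting this offsets the whole baseline), and transform
   back: the result is the complex effective field transmission
   $1+F(\omega)$, and $|1+F|^2$ is the transmittance;
5. iterate (default 3 passes) subtracting the re-chirped $|F|^2$
   self-term, which matters for lines deeper than ~30 %.

A plain "multiply by the parabolic phase and take the real part" is
*provably* inert on a real spectrum — the two phase signs give complex
conjugate results with identical real parts — so the one-sided
reconstruction is essential, not an embellishment.  With zero chirp
rate the correction is the identity.

Retrieved lines recover to better than 0.02 absolute transmittance with
centers within one resolution element for positions from ~850 to
2900 cm⁻¹.  Within ~200 cm⁻¹ of the 640 cm⁻¹ window edge part of the
chirped artifact falls outside the measured window; that information is
physically lost (errors grow to ~0.05 at 800 cm⁻¹ and ~0.08 at
750 cm⁻¹), which is why the round-trip property is asserted from
850 cm⁻¹ up.  The wavenumber axis is finally calibrated by a rigid
offset aligning the CO₂ absorption centroid (a second pass re-centers
the centroid window on the dip so the Lorentzian wings clip
symmetrically); no stretch is applied, since the resolution cannot
separate individual rovibrational lines.

## Chemometrics

Classification operates on transmittance (after retrieval), not raw
counts.  The spectral angle mapper normalizes both pixel and teaching
spectra to unit length before taking inner products — raw inner
products are brightness-biased, and normalization is what makes the
method an *angle* mapper and scale-invariant.  Fisher LDA builds
between/within-class scatter from teaching-region spectra and takes up
to $C-1$ generalized eigenvectors of $(S_B, S_W)$, with a relative
$10^{-8}$ ridge added (and reported) when $S_W$ is singular — always
the case when bands outnumber teaching spectra; pixels are assigned to
the nearest projected centroid, ties to the lowest class index, label 0
reserved for zero-norm or masked pixels.

Teaching regions are axis-aligned rectangles drawn by rejection
sampling under strict side-length and area inequalities, without
overlap, reproducibly by seed; with a label map the sampler draws a
fixed number of regions entirely inside each class.  The desk-scale
channel workflow uses 8 regions per channel (the channels are only
8 px wide at 12.5 µm pitch; 20 regions per channel is the full-scale
geometry).  Channel location masks can be built by intersecting an
additive-averaging mask with an NDSI mask — the two "location
information" analyses — which the stage-4 script demonstrates.

The 10–90 % edge-response estimator interpolates the crossings of the
plateau span linearly and rejects profiles that are not monotone within
a 2 % tolerance.  For a Gaussian-blurred edge the closed form is
$2.5631\sigma$; the simulated copper-mesh image reproduces the ~15 µm
figure because the default PSF was *configured* from it — a consistency
check of the blur/estimator pair, not an independent prediction.

## Problem sizes, determinism, and limits

The shipped analyses and tests run at desk scale: 64 × 48 × 256 cubes,
16 384-point time grids, 49-delay cross-correlations, single spectra at
the full 1069-band sampling.  Full-scale 640 × 480 × 1069 cubes are a
configuration flag away and change memory and time, not code paths.
Every stochastic step (frame and shot noise, teaching-region sampling,
blob phantoms) flows from one integer seed; identical seeds reproduce
cubes bit for bit.

What passing tests do *not* show about real data: the noise model is a
two-parameter summary (frame RMS and max SNR), not a camera
calibration; the randomly appearing nitrogen-oxide/water artifact bands
of a filament source are not simulated by default; the MIR source
spectrum is smooth, whereas a real filament spectrum has structure; GaSe
absorption, étalon fringes and walk-off are ignored; and the phantoms
are piecewise-constant chemistry, so 100 % mapping accuracy on them is
an upper bound, not a field result.  Classification accuracy at the
instrument's 2.77 % frame noise (≥ 95 % required, 100 % observed) is
the meaningful robustness statement.
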