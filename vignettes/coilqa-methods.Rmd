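---
title: "Methods: SNR benchmarking of 13C RF coils from CSI phantom scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNR benchmarking of 13C RF coils from CSI phantom scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilqa)
```

## The problem

Carbon-13 MRI at 3T operates at 32.13 MHz, a quarter of the proton
frequency.  At this frequency coil conductor losses are no longer masked
by sample noise, so nominally similar receive coils can differ
substantially in realized SNR, and the question "which coil should I use
for this experiment" needs routine, quantitative quality assurance.
Comparing a single-channel volume coil with an n-channel array is the
delicate part: a sum-of-squares combined array image carries
non-central-chi background statistics that depend on the channel count,
so its "SNR" is not commensurable with the Rician background of a
single-receiver image.  This package implements a complete QA chain
whose combined array maps retain single-receiver (Rician) statistics,
making center and surface SNR directly comparable across coils.

The measurement is a 2-D non-refocused chemical shift imaging (CSI)
acquisition of a uniform phantom filled with ethylene glycol, whose
natural-abundance ^13^C resonance is a 1:2:1 triplet with one-bond
coupling J ≈ 142 Hz, plus a separate noise-only FID recorded at zero
transmit power.  Protocol defaults (also the package defaults in
`acquisition_spec()`): FOV 36×36 cm, matrix 24×24, slice 20 mm,
spectral bandwidth 5000 Hz, 1024 FID points, TR 1000 ms, nominal flip
70°, TE 2.3–3.1 ms depending on platform.

## The processing chain

1. **Reconstruction** (`recon_csi()`): a unitary, centered 2-D spatial
   DFT per channel and time sample, with no apodization and no
   zero-filling.  Unitary normalization is the package's realization of
   the protocol's central calibration requirement — every processing
   step must leave the noise standard deviation unchanged, so that a
   noise level measured separately remains valid for the signal data.

2. **Spectral filtering** (`spectral_filter()`): each voxel spectrum is
   multiplied by a rectangular window of ±10 ppm (±321 Hz at 32.13 MHz),
   wide enough to contain the whole triplet, and transformed back to the
   time domain.  To preserve the noise std the result is rescaled by
   1/√p, where p is the fraction of spectral points kept.  The
   documented side effect is that fully in-band signal is amplified by
   exactly 1/√p — this *is* the SNR benefit of discarding out-of-band
   noise, and the factor is recorded in provenance.

3. **Signal extraction** (`first_inphase_sample()`,
   `extract_signal()`): the J-coupled triplet components periodically
   de- and re-phase; the complex signal is read at the first time t ≥ 0
   with (t + TE) an integer multiple of 1/J, snapped to the sampling
   grid.  Using the in-phase time point instead of the spectral peak
   height makes the estimate robust to shim-dependent linewidth.  At
   J = 142 Hz and the protocol echo times the snapped time is 4.0–4.8 ms
   (dwell 0.2 ms).  J itself can be estimated from the peak-to-peak
   distance in a high-signal voxel (`estimate_j_coupling()`, 3-point
   quadratic peak interpolation, mean of the two adjacent gaps).

4. **Noise calibration** (`estimate_noise_covariance()`,
   `estimate_neb_factor()`, `scale_covariance()`): the channel
   covariance Ψ is the sample mean of n·n^H over the raw noise samples.
   Because the receiver's digital filter attenuates the band edges, the
   broadband variance underestimates the passband noise density; the
   noise-equivalent bandwidth (NEB) factor corrects this as
   Ψ_scaled = Ψ / factor.  The factor is the ratio of the band-average
   PSD to its passband plateau, with the PSD from Welch averaging
   (Hann, segment 256, 50% overlap, channels pooled).  The plateau is
   the *mean* over the central 50% of the band: a median of periodogram
   bins is biased low by up to log 2 when only a few segments are
   available (a 1024-point record gives seven), which would inflate all
   downstream SNR by up to ~20%; the mean is unbiased at any averaging
   depth, and robustness to outliers buys nothing on data that are
   noise-only by protocol.  Typical scanner constants are 0.845 (GE)
   and 0.793 (Siemens); estimates differing from a supplied scanner
   constant by more than ~10% deserve investigation.

5. **Sensitivity extraction** (`estimate_sensitivities()`): for arrays,
   the near-uniform phantom channel images are themselves noisy
   estimates of the complex receive profiles b.  Each channel is
   smoothed by Perona–Malik anisotropic diffusion
   (`perona_malik_filter()`): 4-neighbor explicit diffusion with
   conductance exp(−(|∇|/κ)²) computed on the magnitude image and
   applied identically to real and imaginary parts (preserving phase
   structure), reflecting boundaries, dt ≤ 0.25 for 2-D stability.
   The parameters adapt to each channel's SNR (`auto_pm_params()`):
   κ = c_k · σ_c · max(1, snr_ref/SNR_edge) — high edge SNR means a
   small κ, i.e. strong anisotropy and preserved object edges — and
   n_iter = clamp(round(c_n/SNR_overall), 2, 200) — high overall SNR
   means minimal smoothing.  Defaults c_k = 2, snr_ref = 20, c_n = 600
   (≈30 iterations at SNR 20); all constants are config-exposed.  The
   smoothed profiles are normalized to unit sum-of-squares magnitude per
   masked voxel ("sos-unit"); the SNR expression below is invariant to
   any per-voxel positive rescaling of b, so this convention cannot
   bias the result (tested).

6. **SNR maps** (`snr_map_single()`, `snr_map_array()`): for one
   channel, SNR = √2·|s|/σ; for arrays the covariance-weighted
   (Roemer) matched filter

   SNR = √2 · |bᴴ Ψ⁻¹ s| / √(bᴴ Ψ⁻¹ b).

   The √2 expresses SNR relative to the *real* channel noise component.
   No linear channel combination achieves a higher value, and the
   combined background is Rayleigh/Rician for any channel count — the
   property that justifies cross-coil comparison.  The Hermitian form
   bᴴΨ⁻¹s is used rather than the transpose-starred variant sometimes
   typeset (sᵀΨ⁻¹b*): the two coincide for real Ψ, but only the
   Hermitian form is invariant under simultaneous per-channel complex
   gains applied to s, b and Ψ, which is the physically required
   behavior.  Ψ⁻¹ is applied through a factorization, never formed
   explicitly.

7. **Summaries** (`snr_summary()`): center SNR = mean over the 3×3 block
   around the grid center voxel (the DC voxel, 0-based rows/cols 11–13
   of 24); surface SNR = maximum over the mask; profiles = per-position
   means over the three central lines, anterior–posterior and
   right–left.  `compare_coils()` adds per-metric relative columns
   normalized to the best coil (100%), keeping phantoms separate.

8. **Parallel imaging metrics** (`correlation_matrix()`,
   `sense_gfactor()`): the noise correlation matrix
   |Ψᵢⱼ|/√(ΨᵢᵢΨⱼⱼ) is an absolute array metric; the SENSE geometry
   factor for uniform retrospective undersampling at acceleration R is
   g_ρ = √([(SᴴΨ⁻¹S)⁻¹]ρρ·[SᴴΨ⁻¹S]ρρ) per aliasing set of R equally
   spaced voxels, computed from the extracted profiles.  g ≥ 1 wherever
   defined; singular aliasing sets are flagged `NA`, never clipped.

9. **Transmit inhomogeneity** (`smooth_txmap()`, `tx_snr_loss()`): a
   measured flip-angle-scale map β is smoothed by first-order local
   polynomial (plane) fits over 7.5 cm regions, and the steady-state
   SNR impact is 1 − S(β·α)/S(α) with
   S(α) = sin α·(1−E1)/(1−cos α·E1), E1 = exp(−TR/T1), T1 = 700 ms for
   ethylene glycol at room temperature.

## The simulator and what it does (not) capture

`simulate_csi()` generates full multi-channel CSI acquisitions with
known ground truth, so every stage is testable without scanner data.
Per voxel it builds the ethylene glycol FID (three lines at offsets
{−J, 0, +J}, common T2* envelope, steady-state excitation factor),
weights it by an 8×-supersampled partial-volume mask of the phantom
(250 mm cylinder or head-shaped ellipse) and by each channel's receive
profile, transforms to k-space with the exact inverse of the recon
convention, and adds complex Gaussian noise with a prescribed channel
covariance at every k-space sample (real and imaginary parts each with
covariance Ψ/2).  An optional receiver-coloring filter shapes the noise
PSD for NEB testing.

Receive profiles come from quasi-static Biot–Savart line integration of
circular loops, with phase arg(Bx − iBy) (the transverse circularly
polarized component), so array phase diversity is realistic.  No
wavelength effects, coil losses, or coupling are modeled — at 32 MHz
sample loading is negligible and coil-noise/sample-noise regimes are
represented entirely through Ψ.  Shipped layouts: `"array14"` (14 ×
80 mm loops on a 250 mm circle, single row), `"array8"` (two 4-loop
paddles), `"volume"` (uniform sensitivity), `"loop1"` (single surface
loop).  The simulator does not emulate B0 inhomogeneity (T2* is spatially
uniform), transmit inhomogeneity (unless a β map is applied downstream),
motion, or spurious signals; passing tests therefore validate the
estimation chain, not robustness to those real-world effects.

The ground-truth SNR is √2·A(t_ip)·√(bᴴΨ⁻¹b)/√p, with A(t_ip) the
noiseless voxel signal at the snapped in-phase sample and 1/√p the
spectral-filter gain, so pipeline output can be compared to truth
voxel-by-voxel.

## Numerical choices

* Unitary FFTs with centered conventions; k-space DC at 0-based index
  n/2.  Simulation and reconstruction are exact inverses (checked to
  float precision).
* The in-phase index snaps to the nearest sample; the continuous time is
  kept as metadata.
* T2* from the center-peak FWHM: half-maximum crossings are found on a
  continuous (trigonometric, DTFT-based) interpolation of the magnitude
  spectrum, and width maps to relaxation time by inverting the exact
  apparent width of a record-length-truncated sampled exponential.  For
  an infinite record this reduces to FWHM_mag = √3/(π·T2*); at a
  204.8 ms record and T2* = 132 ms ignoring truncation would bias the
  estimate by tens of percent.  The Lorentzian convention
  T2* = 1/(π·FWHM_abs) is the default, with a `"plain"` (1/FWHM)
  switch.
* Peak interpolation for J estimation is 3-point quadratic on the
  magnitude spectrum; ties break toward lower frequency through the
  deterministic ordering of local maxima.
* Degenerate inputs: voxels on a simulated loop wire are evaluated at a
  small offset and flagged; aliasing sets with singular sensitivity
  systems are returned `NA` with a count; transmit-map regions with
  fewer than 3 masked voxels fall back to nearest-neighbor, flagged.
* The support mask is sum-of-squares magnitude > 3× the background noise
  level, morphologically closed by one voxel (config-exposed).

## Problem sizes used in tests

The shipped tests run the full geometry (24×24, the protocol FOV and
bandwidth) but shorten the FID to 256 points where the spectral
dimension is not under test, use 10^5-sample Monte-Carlo checks for
variance-preservation and covariance convergence, 10^4 voxels for the
background-statistics moment tests, and 10 noise seeds for the
pipeline-vs-truth recovery check — sizes at which Monte-Carlo error is
comfortably below the tolerances being asserted.

## Known limitations

* Vendor raw formats are out of scope; data enter through the package's
  documented HDF5 container (an ISMRMRD import hook would be a thin
  adapter at `read_container()`'s level).
* Single-slice 2-D CSI only; no multi-slice or volumetric support.
* No spectral model fitting (Lorentzian/Voigt) and no B0 mapping; the
  in-phase-point design deliberately avoids needing them.
* g-factor maps describe retrospective uniform undersampling of the
  phantom acquisition; the package does not reconstruct actually
  undersampled data.
* SNR maps are reported without transmit-field correction;
  `tx_snr_loss()` quantifies the expected impact separately when a
  transmit map is available.
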