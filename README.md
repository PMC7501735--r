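# coilqa

Quality-assurance benchmarking of carbon-13 RF receive coils at 3T.

At the ^13^C Larmor frequency (32.13 MHz at 3T) coil conductor losses are
not masked by sample noise, so nominally similar coils can differ widely
in realized SNR — and comparing a volume coil against an n-channel array
is statistically treacherous, because sum-of-squares array combination
produces background noise whose distribution (non-central chi, 2n
degrees of freedom) depends on the channel count.  `coilqa` implements a
complete QA protocol that avoids this bias: chemical shift imaging (CSI)
of an ethylene glycol phantom is reconstructed with strictly
noise-std-preserving scalings, the complex signal is read at the first
J-coupling in-phase time point, the channel noise covariance Ψ is
estimated from a noise-only acquisition and corrected by the receiver's
noise-equivalent bandwidth, complex coil sensitivity profiles b are
extracted by SNR-adaptive Perona–Malik diffusion, and the final maps use
the noise-covariance-weighted (Roemer) matched filter

    SNR_single = √2 · |s| / σ
    SNR_array  = √2 · |bᴴ Ψ⁻¹ s| / √(bᴴ Ψ⁻¹ b)

whose combined background keeps single-receiver (Rician) statistics for
any channel count.  The package also computes array noise-correlation
summaries, SENSE g-factor maps for retrospective uniform undersampling
(g_ρ = √([(SᴴΨ⁻¹S)⁻¹]ρρ·[SᴴΨ⁻¹S]ρρ)), transmit-inhomogeneity SNR-loss
estimates under a steady-state model, and T2*/J estimators for scan QC.

A full phantom/coil simulator (partial-volume masks, Biot–Savart loop
sensitivities, J-coupled triplet FIDs, noise with prescribed channel
covariance and optional receiver coloring) provides analytic ground
truth, so the entire chain is testable without scanner data.  Raw and
derived data travel in a documented, self-describing HDF5 container
(readable from any HDF5 tool, e.g. h5py).

Intended users: MR physicists and coil developers running routine coil
QA or evaluating new ^13^C hardware across sites and vendors.

## Worked example

Simulate a cylindrical ethylene glycol phantom scanned with a 14-loop
head-sized receive array, run the full QA chain, and compare it with a
uniform volume coil:

```r
library(coilqa)

bundle <- run_qa(list(
  simulate = list(layout = "array14", seed = 42,
                  acq = list(n_fid_points = 256),
                  noise = list(sigma = 0.005)),
  j_hz = 142, gfactor_R = c(2, 4), gfactor_direction = "col"))
print(bundle)
#> QA bundle: coil 'array14', phantom 'cylinder', 14 channel(s)
#>   center SNR 24.2, surface SNR 322
#>   noise correlation: max 0.140, mean 0.056
#>   g-factor R2 (col): max 1.008
#>   g-factor R4 (col): max 1.312

vol <- run_qa(list(simulate = list(layout = "volume", seed = 42,
                                   acq = list(n_fid_points = 256),
                                   noise = list(sigma = 0.01))))
compare_coils(list(bundle, vol))
#>      coil n_channels center_abs center_rel surface_abs surface_rel
#> 1 array14         14       24.2       8.58         322       100.0
#> 2  volume          1      281.6     100.00         285        88.6
```

Reading the numbers: the array's surface SNR (322, the maximum over the
phantom) dwarfs its center SNR (24.2, the mean over the central 3×3
voxels) — surface loops are strongly depth-dependent, while the volume
coil is homogeneous.  The relative columns normalize each metric to the
best coil (100%).  Off-diagonal noise correlations (max 0.14) are low,
and g-factors near 1 at R = 2 with modest amplification at R = 4
indicate good parallel-imaging geometry for undersampling along the
array's azimuthal direction.  With `out = <dir>` the same call writes
SNR/sensitivity/g-factor maps (HDF5 + PNG), correlation and profile
CSVs, and a machine-readable `summary.json` with a full provenance block
(every scaling applied: FFT normalization, spectral-filter gain, NEB
factor, the √2 prefactor).

A thin command-line front end covering
`simulate / recon / noise / sens / snr / gfactor / qa / compare` is
installed at `system.file("cli", "coilqa", package = "coilqa")`.

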