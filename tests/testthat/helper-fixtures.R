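# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once per test run.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Short-FID acquisition used throughout: full protocol geometry, reduced
# FID length to keep simulations fast.
acq_short <- function(n_fid = 256) acquisition_spec(n_fid_points = n_fid)

# Single-channel volume-coil acquisition with known truth.
sim_volume <- function() fx("volume", function() {
  simulate_csi(phantom_spec(), builtin_layout("volume"), acq_short(),
               matrix(0.01^2 + 0i), seed = 7, noise_samples = 1024)
})

# 14-channel array acquisition, per-channel SNR >~ 100 at the surface.
sim_array14 <- function() fx("array14", function() {
  simulate_csi(phantom_spec(), builtin_layout("array14"), acq_short(),
               diag(0.005^2, 14) + 0i, seed = 11, noise_samples = 4096)
})

# Run the manual recon chain up to the signal map.
chain_signal <- function(sim, band_ppm = 10, j_hz = 142) {
  acq <- sim$raw$acq
  img <- spectral_filter(recon_csi(sim$raw), band_ppm, acq)
  ip <- first_inphase_sample(j_hz, acq$te_ms, acq)
  extract_signal(img, ip$index, ip$time_ms)
}

chain_noise_model <- function(sim) {
  scale_covariance(estimate_noise_covariance(sim$noise),
                   estimate_neb_factor(sim$noise))
}

# Complex white-noise array of given dims (deterministic).
cnoise <- function(dims, seed, sd = 1) {
  set.seed(seed)
  n <- prod(dims)
  array(complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
                imaginary = stats::rnorm(n, sd = sd / sqrt(2))), dims)
}

# Spectrum (centered order) of a synthetic one-voxel FID.
synth_spectrum <- function(phantom, acq, te_ms = acq$te_ms) {
  t_ms <- (seq_len(acq$n_fid_points) - 1) * 1000 / acq$spectral_bw_hz
  fid <- ethylene_glycol_fid(t_ms, phantom, te_ms)
  stats::fft(fid)[coilqa:::fftshift_idx(length(fid))]
}
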