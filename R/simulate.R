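#' Ethylene glycol triplet FID
#'
#' Time-domain signal of a J-coupled 1:2:1 triplet: three lines at
#' frequency offsets `{-J, 0, +J}` weighted by the (unit-sum normalized)
#' line amplitudes, under a common exponential T2* envelope.  For the
#' default 1:2:1 amplitudes this reduces to
#' `A * cos^2(pi * J * (t + TE)) * exp(-(t + TE) / T2*)`: the signal is
#' fully in phase whenever `(t + TE)` is an integer multiple of `1/J` and
#' nulls at odd multiples of `1/(2J)`.
#'
#' @param t_ms sample times after the start of sampling (ms, `>= 0`).
#' @param spec a [phantom_spec()].
#' @param te_ms echo time: delay from excitation to `t = 0` (ms).
#' @param phase0 optional global phase (radians).
#' @return Complex vector of FID samples.
#' @export
ethylene_glycol_fid <- function(t_ms, spec, te_ms, phase0 = 0) {
  if (any(t_ms < 0)) stopf("sample times must be >= 0")
  if (te_ms < 0) stopf("te_ms must be >= 0")
  tt <- (t_ms + te_ms) / 1000                 # seconds since excitation
  w <- spec$line_amplitudes
  f <- c(-spec$j_hz, 0, spec$j_hz)
  s <- Reduce(`+`, lapply(1:3, function(k) w[k] * exp(2i * pi * f[k] * tt)))
  spec$signal_amplitude * s * exp(-tt / (spec$t2star_ms / 1000)) *
    exp(1i * phase0)
}

# Steady-state longitudinal magnetization factor for repeated excitation:
# sin(a) (1 - E1) / (1 - cos(a) E1), E1 = exp(-TR/T1).
steady_state_factor <- function(flip_deg, tr_ms, t1_ms) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Receiver-filter coloring specifications
#'
#' `noise_filter("brickwall", keep = 0.8)` keeps the central 80% of the
#' band; `noise_filter("raised_cosine", rolloff = 0.2)` tapers the outer
#' 20% of each band half with a cosine amplitude roll-off.
#'
#' @param type `"brickwall"` or `"raised_cosine"`.
#' @param keep band fraction kept (brick-wall).
#' @param rolloff tapered fraction of the half-band (raised cosine).
#' @return An object of class `noise_filter`.
#' @export
noise_filter <- function(type = c("brickwall", "raised_cosine"),
                         keep = 0.8, rolloff = 0.2) {
  type <- match.arg(type)
  structure(list(type = type, keep = keep, rolloff = rolloff),
            class = "noise_filter")
}

# |H(f)| at normalized frequencies f in [-0.5, 0.5).
filter_response <- function(filt, fnorm) {
  af <- abs(fnorm)
  switch(filt$type,
    brickwall = as.numeric(af <= filt$keep / 2),
    raised_cosine = {
      f1 <- (1 - filt$rolloff) * 0.5
      h <- rep(1, length(af))
      tp <- af > f1
      h[tp] <- cos(pi / 2 * (af[tp] - f1) / (0.5 - f1))
      h
    })
}

#' Analytic noise-equivalent bandwidth of a coloring filter
#'
#' Ratio of the band-average of `|H|^2` to its passband plateau, by
#' numerical integration.
#'
#' @param filt a [noise_filter()].
#' @param n integration grid size.
#' @return The noise-equivalent bandwidth factor.
#' @export
neb_of_filter <- function(filt, n = 65536) {
  f <- (seq_len(n) - 0.5) / n - 0.5
  h2 <- filter_response(filt, f)^2
  mean(h2) / max(h2)
}

#' Simulate a multi-channel noise-only FID record
#'
#' Complex Gaussian samples with the requested channel covariance (real
#' and imaginary parts each carry covariance `psi/2`).  An optional
#' coloring filter is applied along time so the power spectral density
#' follows the receiver passband shape.
#'
#' @param psi channel covariance matrix (or a [noise_model()]).
#' @param n_samples samples per channel.
#' @param seed RNG seed.
#' @param coloring optional [noise_filter()].
#' @param spectral_bw_hz bandwidth recorded in the output.
#' @return A [noise_record()].
#' @export
simulate_noise <- function(psi, n_samples, seed, coloring = NULL,
                           spectral_bw_hz = 5000) {
  if (inherits(psi, "noise_model")) psi <- psi$psi
  psi <- as.matrix(psi); if (!is.complex(psi)) psi <- psi + 0i
  set.seed(seed)
  fid <- rcomplex_mvnorm(n_samples, psi)
  if (!is.null(coloring)) {
    n <- n_samples
    f <- (seq_len(n) - 1) / n
    f[f >= 0.5] <- f[f >= 0.5] - 1
    h <- filter_response(coloring, f)
    for (c in seq_len(nrow(fid)))
      fid[c, ] <- stats::fft(stats::fft(fid[c, ]) * h, inverse = TRUE) / n
  }
  noise_record(fid, spectral_bw_hz)
}

#' Simulate a full CSI acquisition with known ground truth
#'
#' Builds the per-voxel ethylene glycol FID weighted by the partial-volume
#' phantom mask, the steady-state factor and each channel's Biot-Savart
#' sensitivity, transforms to k-space with the exact inverse of the recon
#' convention, and adds complex Gaussian noise with channel covariance
#' `psi` independently at every k-space sample.  A separate noise-only
#' record with the same covariance is also produced.
#'
#' The returned ground truth carries the true sensitivities, the true
#' covariance, and the analytic SNR map the QA pipeline should reproduce:
#' `sqrt(2) * |signal at the snapped first in-phase sample| *
#' sqrt(b^H psi^-1 b) / sqrt(p)`, where `p` is the spectral-filter keep
#' fraction for `band_ppm` (the noise-std-preserving filter raises SNR by
#' `1/sqrt(p)`).
#'
#' @param phantom a [phantom_spec()].
#' @param coils a [coil_layout()].
#' @param acq an [acquisition_spec()].
#' @param psi channel noise covariance (matrix or [noise_model()]).
#' @param seed RNG seed.
#' @param steady_state apply the steady-state excitation factor.
#' @param band_ppm spectral filter half-width assumed for the ground-truth
#'   SNR (the protocol default, 10 ppm).
#' @param noise_samples length of the companion noise record.
#' @return `list(raw = csi_raw_data, noise = noise_record, truth = list(
#'   b_true, psi_true, snr_true, mask_frac, signal_params))`.
#' @export
simulate_csi <- function(phantom, coils, acq, psi, seed,
                         steady_state = TRUE, band_ppm = 10,
                         noise_samples = acq$n_fid_points) {
  if (inherits(psi, "noise_model")) psi <- psi$psi
  psi <- as.matrix(psi); if (!is.complex(psi)) psi <- psi + 0i
  nch <- coils$n_channels
  if (nrow(psi) != nch)
    stopf("psi is %dx%d but the layout has %d channel(s)",
          nrow(psi), ncol(psi), nch)
  n <- acq$matrix_size; nt <- acq$n_fid_points

  mask_frac <- phantom_mask(phantom, acq)
  b_true <- layout_sensitivities(coils, acq)
  ss <- if (steady_state)
    steady_state_factor(acq$nominal_flip_deg, acq$tr_ms, phantom$t1_ms)
  else 1
  amp <- mask_frac * ss   # the FID already carries signal_amplitude

  t_ms <- (seq_len(nt) - 1) * 1000 / acq$spectral_bw_hz
  fid <- ethylene_glycol_fid(t_ms, phantom, acq$te_ms)

  img <- array(0i, dim = c(n[1], n[2], nch, nt))
  vox <- as.vector(amp)
  for (c in seq_len(nch)) {
    base <- vox * as.vector(b_true[, , c])
    img[, , c, ] <- outer(base, fid)
  }
  ksp <- fft2c(img, inverse = FALSE)

  set.seed(seed)
  nz <- rcomplex_mvnorm(n[1] * n[2] * nt, psi)       # [ch, kx*ky*t]
  nz <- aperm(array(nz, dim = c(nch, n[1], n[2], nt)), c(2, 3, 1, 4))
  raw <- csi_raw_data(ksp + nz, acq)
  noise <- simulate_noise(psi, noise_samples, seed + 1L,
                          spectral_bw_hz = acq$spectral_bw_hz)

  ip <- first_inphase_sample(phantom$j_hz, acq$te_ms, acq)
  sig_t <- Mod(ethylene_glycol_fid(ip$snapped_time_ms, phantom, acq$te_ms))
  p <- spectral_keep_fraction(band_ppm, acq)
  q <- apply(b_true, c(1, 2), function(bv)
    Re(sum(Conj(bv) * solve(psi, bv))))      # b^H Psi^-1 b
  snr_true <- sqrt(2) * amp * sig_t * sqrt(pmax(q, 0)) / sqrt(p)

  list(raw = raw, noise = noise,
       truth = list(b_true = b_true, psi_true = psi, snr_true = snr_true,
                    mask_frac = mask_frac, inphase = ip,
                    filter_keep_fraction = p, signal_params = phantom))
}
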