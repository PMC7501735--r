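#' Reconstruct raw CSI data to the image domain
#'
#' Applies a unitary (orthonormal) centered 2-D spatial DFT to every
#' channel and time sample, with no apodization and no zero-filling.
#' Unitary normalization means white noise keeps its standard deviation
#' through the transform and total energy is conserved (Parseval), which
#' is the calibration requirement the whole SNR chain rests on.
#'
#' @param raw a [csi_raw_data()].
#' @return Complex image-domain array `[ny, nx, channel, time]`.
#' @export
recon_csi <- function(raw) {
  stopifnot(inherits(raw, "csi_raw_data"))
  fft2c(raw$kspace, inverse = TRUE)
}

# Fraction of spectral bins kept by the +-band_ppm rectangular window.
spectral_keep_fraction <- function(band_ppm, acq) {
  band_hz <- band_ppm * 1e-6 * acq$center_freq_hz
  if (band_hz > acq$spectral_bw_hz / 2 * (1 + 1e-9))
    stopf("spectral window (+-%g Hz) exceeds the Nyquist band (+-%g Hz)",
          band_hz, acq$spectral_bw_hz / 2)
  nt <- acq$n_fid_points
  df <- acq$spectral_bw_hz / nt
  f <- (seq_len(nt) - 1 - floor(nt / 2)) * df
  mean(abs(f) <= band_hz * (1 + 1e-9))
}

#' Noise-std-preserving spectral low-pass filter
#'
#' Transforms the time dimension to the spectral domain, multiplies by a
#' rectangular window spanning `+-band_ppm` around the center frequency,
#' transforms back, and rescales by `1/sqrt(p)` (`p` = fraction of
#' spectral points retained) so that white noise keeps its standard
#' deviation.  The documented side effect is that fully in-band signal is
#' scaled by exactly `1/sqrt(p)`; the factor is returned in the
#' `"filter_gain"` attribute and propagated into provenance.
#'
#' @param img_time image-domain array `[ny, nx, channel, time]` from
#'   [recon_csi()].
#' @param band_ppm half-width of the retained band (ppm).
#' @param acq an [acquisition_spec()].
#' @return Filtered array with attributes `filter_gain` (`1/sqrt(p)`) and
#'   `keep_fraction` (`p`).
#' @export
spectral_filter <- function(img_time, band_ppm, acq) {
  d <- dim(img_time)
  nt <- d[length(d)]
  if (nt != acq$n_fid_points)
    stopf("time dimension (%d) != acq n_fid_points (%d)", nt,
          acq$n_fid_points)
  band_hz <- band_ppm * 1e-6 * acq$center_freq_hz
  p <- spectral_keep_fraction(band_ppm, acq)   # errors beyond Nyquist
  df <- acq$spectral_bw_hz / nt
  f <- (seq_len(nt) - 1 - floor(nt / 2)) * df
  win <- as.numeric(abs(f) <= band_hz)

  tdim <- length(d)
  spec <- fft1c(img_time, dim = tdim, inverse = FALSE)
  spec <- sweep(spec, tdim, win, `*`)
  out <- fft1c(spec, dim = tdim, inverse = TRUE) / sqrt(p)
  attr(out, "filter_gain") <- 1 / sqrt(p)
  attr(out, "keep_fraction") <- p
  out
}

#' First in-phase time point of the J-coupled triplet
#'
#' The triplet components share phase whenever the total time since
#' excitation `(t + TE)` is an integer multiple of `1/J`.  Returns the
#' smallest such `t >= 0` within the sampled FID, together with the
#' nearest sampling index at dwell `1/spectral_bw_hz`.
#'
#' @param j_hz J coupling (Hz).
#' @param te_ms echo time (ms).
#' @param acq an [acquisition_spec()].
#' @return `list(index, time_ms, snapped_time_ms)`: `index` is the 0-based
#'   FID sample offset, `time_ms` the exact in-phase time and
#'   `snapped_time_ms = index * dwell`.
#' @export
first_inphase_sample <- function(j_hz, te_ms, acq) {
  if (j_hz <= 0) stopf("j_hz must be > 0")
  period_ms <- 1000 / j_hz
  k <- ceiling(te_ms / period_ms - 1e-12)
  t_ms <- k * period_ms - te_ms
  dwell_ms <- 1000 / acq$spectral_bw_hz
  idx <- as.integer(round(t_ms / dwell_ms))
  if (idx >= acq$n_fid_points)
    stopf("first in-phase time (%.3f ms) lies beyond the sampled FID", t_ms)
  list(index = idx, time_ms = t_ms, snapped_time_ms = idx * dwell_ms)
}

#' Extract the per-channel signal map at the in-phase sample
#'
#' @param filtered image-domain array `[ny, nx, channel, time]`.
#' @param index 0-based FID sample offset (from [first_inphase_sample()]).
#' @param time_ms optional continuous in-phase time recorded as metadata.
#' @return A [signal_map()]; the filter gain attribute of `filtered`, if
#'   present, is carried over.
#' @export
extract_signal <- function(filtered, index, time_ms = NULL) {
  d <- dim(filtered)
  if (index < 0 || index >= d[4]) stopf("in-phase index %d out of range", index)
  s <- filtered[, , , index + 1, drop = FALSE]
  dim(s) <- d[1:3]
  signal_map(s, time_ms %||% (NA_real_), index,
             filter_gain = attr(filtered, "filter_gain") %||% 1)
}

# Centered magnitude spectrum of one voxel FID.
voxel_spectrum <- function(fid) {
  stats::fft(fid)[fftshift_idx(length(fid))]
}

# Continuous-frequency magnitude of the spectrum by direct DTFT
# evaluation of the underlying FID (trigonometric interpolation of the
# sampled spectrum; no zero-filling of the stored data).
dtft_mod <- function(fid, f_hz, bw_hz) {
  n <- length(fid)
  t <- (seq_len(n) - 1) / bw_hz
  vapply(f_hz, function(f) Mod(sum(fid * exp(-2i * pi * f * t))), 0)
}

#' Estimate the J coupling from a voxel spectrum
#'
#' The triplet peak positions are located as the three largest local
#' maxima of the magnitude spectrum, refined by 3-point quadratic
#' interpolation; J is the mean of the two adjacent peak-to-peak gaps.
#'
#' @param spectrum complex spectral vector for one voxel, centered order
#'   (DC at `floor(n/2)+1`).
#' @param acq an [acquisition_spec()].
#' @param threshold peak acceptance threshold relative to the strongest
#'   peak.
#' @return Estimated J (Hz).
#' @export
estimate_j_coupling <- function(spectrum, acq, threshold = 0.25) {
  m <- Mod(spectrum)
  n <- length(m)
  df <- acq$spectral_bw_hz / n
  loc <- which(diff(sign(diff(m))) == -2) + 1      # strict local maxima
  loc <- loc[m[loc] >= threshold * max(m)]
  if (length(loc) < 3)
    stopf("fewer than 3 resolvable peaks: SNR too low or bad shim")
  loc <- loc[order(m[loc], decreasing = TRUE)][1:3]
  loc <- sort(loc)
  refine <- function(i) {
    ym <- m[i - 1]; y0 <- m[i]; yp <- m[i + 1]
    den <- ym - 2 * y0 + yp
    delta <- if (den != 0) 0.5 * (ym - yp) / den else 0
    (i - 1 - floor(n / 2) + delta) * df
  }
  fpk <- vapply(loc, refine, 0)
  mean(diff(fpk))
}

# Apparent magnitude-spectrum FWHM (Hz) of a sampled exponential decay
# exp(-t/tau) truncated at n samples: the half-maximum width of
# |(1 - r^n e^{-i n w}) / (1 - r e^{-i w})|, r = exp(-dt/tau).  At record
# lengths of only a few T2* the truncation term widens or narrows the
# apparent line by several percent, so the estimator inverts this exact
# width rather than the ideal-Lorentzian sqrt(3)/(pi*tau).
apparent_fwhm_hz <- function(tau_s, n, bw_hz) {
  dt <- 1 / bw_hz
  r <- exp(-dt / tau_s)
  mfun <- function(f) {
    w <- 2 * pi * f * dt
    Mod((1 - r^n * exp(-1i * n * w)) / (1 - r * exp(-1i * w)))
  }
  half <- mfun(0) / 2
  f <- 0; step <- 0.05 / (pi * tau_s)
  while (mfun(f + step) > half) f <- f + step
  2 * stats::uniroot(function(x) mfun(x) - half, c(f, f + step))$root
}

#' Estimate T2* from the center-peak linewidth
#'
#' Measures the full width at half maximum of the ethylene glycol center
#' peak on the magnitude spectrum, with half-maximum crossings found by
#' continuous (trigonometric) interpolation of the sampled spectrum, and
#' converts width to relaxation time by inverting the exact
#' magnitude-spectrum width of a sampled, record-length-truncated
#' exponential decay (for an infinite record this reduces to the
#' Lorentzian relation: magnitude FWHM `= sqrt(3)/(pi * T2*)`).
#' `convention = "lorentzian"` (default) reports
#' `T2* = 1/(pi * FWHM_absorption)`; `convention = "plain"` reports
#' `1/FWHM_absorption`, where `FWHM_absorption` is the truncation-corrected
#' absorption-mode linewidth.
#'
#' @param spectrum complex spectral vector for one voxel, centered order.
#' @param acq an [acquisition_spec()].
#' @param convention `"lorentzian"` (default) or `"plain"`.
#' @return Estimated T2* (ms).
#' @export
estimate_t2star <- function(spectrum, acq,
                            convention = c("lorentzian", "plain")) {
  convention <- match.arg(convention)
  m <- Mod(spectrum)
  n <- length(m)
  df <- acq$spectral_bw_hz / n
  ipk <- which.max(m)
  if (ipk <= 1 || ipk >= n)
    stopf("center peak lies at the spectral edge")
  # back to the FID for continuous interpolation
  fid <- stats::fft(spectrum[ifftshift_idx(n)], inverse = TRUE) / n
  fgrid <- (seq_len(n) - 1 - floor(n / 2)) * df
  peak_f <- stats::optimize(function(f) -dtft_mod(fid, f, acq$spectral_bw_hz),
                            interval = fgrid[ipk] + c(-1, 1) * df)$minimum
  half <- dtft_mod(fid, peak_f, acq$spectral_bw_hz) / 2
  cross <- function(side) {
    g <- function(f) dtft_mod(fid, f, acq$spectral_bw_hz) - half
    f <- peak_f
    step <- side * df / 4
    limit <- max(abs(fgrid))
    while (g(f + step) > 0) {
      f <- f + step
      if (abs(f) > limit) stopf("half-maximum crossing beyond spectral edge")
    }
    stats::uniroot(g, c(min(f, f + step), max(f, f + step)))$root
  }
  fwhm_mag <- cross(+1) - cross(-1)
  tau_s <- stats::uniroot(
    function(tau) apparent_fwhm_hz(tau, n, acq$spectral_bw_hz) - fwhm_mag,
    c(2e-3, 5), tol = 1e-7)$root
  fwhm_abs <- 1 / (pi * tau_s)
  1000 * (if (convention == "lorentzian") tau_s else 1 / fwhm_abs)
}
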