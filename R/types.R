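#' Acquisition parameters for a 2-D CSI scan
#'
#' Bundles the sequence metadata needed to interpret raw chemical shift
#' imaging (CSI) data: in-plane field of view and matrix, spectral bandwidth
#' and FID length, echo/repetition time, nominal flip angle and the receive
#' center frequency.  Defaults follow the reference QA protocol for
#' carbon-13 at 3T: 36x36 cm FOV, 24x24 matrix, 20 mm slice, 5000 Hz
#' bandwidth, 1024 FID points, TR 1000 ms, flip 70 degrees.
#'
#' @param fov_mm in-plane field of view, length-2 numeric (mm).
#' @param matrix_size in-plane matrix, length-2 integer.
#' @param slice_thickness_mm slice thickness (mm).
#' @param spectral_bw_hz spectral (readout) bandwidth (Hz); dwell time is
#'   `1/spectral_bw_hz`.
#' @param n_fid_points number of complex FID samples per voxel.
#' @param te_ms echo time: delay from excitation to first sample (ms).
#' @param tr_ms repetition time (ms).
#' @param nominal_flip_deg nominal excitation flip angle (degrees).
#' @param center_freq_hz receive center frequency (Hz); 32.13 MHz is the
#'   carbon-13 Larmor frequency at 3T.
#' @param nucleus nucleus label.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(fov_mm = c(360, 360), matrix_size = c(24, 24),
                             slice_thickness_mm = 20, spectral_bw_hz = 5000,
                             n_fid_points = 1024, te_ms = 2.7, tr_ms = 1000,
                             nominal_flip_deg = 70, center_freq_hz = 32.13e6,
                             nucleus = "13C") {
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 2 || any(matrix_size < 1))
    stopf("matrix_size must be two integers >= 1")
  if (length(fov_mm) != 2 || any(fov_mm <= 0))
    stopf("fov_mm must be two positive lengths")
  if (spectral_bw_hz <= 0) stopf("spectral_bw_hz must be > 0")
  if (n_fid_points < 2) stopf("n_fid_points must be >= 2")
  if (te_ms < 0) stopf("te_ms must be >= 0")
  structure(list(fov_mm = as.numeric(fov_mm), matrix_size = matrix_size,
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 spectral_bw_hz = as.numeric(spectral_bw_hz),
                 n_fid_points = as.integer(n_fid_points),
                 te_ms = as.numeric(te_ms), tr_ms = as.numeric(tr_ms),
                 nominal_flip_deg = as.numeric(nominal_flip_deg),
                 center_freq_hz = as.numeric(center_freq_hz),
                 nucleus = as.character(nucleus)),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("CSI acquisition: %s, FOV %gx%g mm, matrix %dx%d, bw %g Hz, %d FID pts, TE %g ms, TR %g ms, flip %g deg\n",
              x$nucleus, x$fov_mm[1], x$fov_mm[2], x$matrix_size[1],
              x$matrix_size[2], x$spectral_bw_hz, x$n_fid_points,
              x$te_ms, x$tr_ms, x$nominal_flip_deg))
  invisible(x)
}

#' Raw multi-channel CSI k-space data
#'
#' @param kspace complex array `[kx, ky, channel, time]`; the DC line sits
#'   at index `floor(n/2)+1` of each spatial axis (centered convention).
#' @param acq an [acquisition_spec()].
#' @param channel_labels optional channel names.
#' @return An object of class `csi_raw_data`.
#' @export
csi_raw_data <- function(kspace, acq, channel_labels = NULL) {
  stopifnot(inherits(acq, "acquisition_spec"))
  if (length(dim(kspace)) != 4)
    stopf("kspace must be a 4-D [kx, ky, channel, time] array")
  d <- dim(kspace)
  if (!identical(d[1:2], as.integer(acq$matrix_size)))
    stopf("kspace spatial dims (%d x %d) inconsistent with acq matrix (%d x %d)",
          d[1], d[2], acq$matrix_size[1], acq$matrix_size[2])
  if (d[4] != acq$n_fid_points)
    stopf("kspace time dim (%d) inconsistent with acq n_fid_points (%d)",
          d[4], acq$n_fid_points)
  if (d[3] < 1) stopf("at least one channel required")
  if (any(!is.finite(Re(kspace))) || any(!is.finite(Im(kspace))))
    stopf("kspace contains non-finite values")
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(d[3]))
  if (length(channel_labels) != d[3])
    stopf("channel_labels length (%d) != number of channels (%d)",
          length(channel_labels), d[3])
  structure(list(kspace = kspace, acq = acq,
                 channel_labels = as.character(channel_labels)),
            class = "csi_raw_data")
}

#' @export
print.csi_raw_data <- function(x, ...) {
  d <- dim(x$kspace)
  cat(sprintf("csi_raw_data: %dx%d k-space, %d channel(s), %d FID points\n",
              d[1], d[2], d[3], d[4]))
  print(x$acq)
  invisible(x)
}

#' Noise-only multi-channel FID record
#'
#' A non-localized FID acquired with zero transmit power, used to estimate
#' the channel noise covariance and the receiver's noise-equivalent
#' bandwidth.
#'
#' @param fid complex matrix `[channel, samples]`.
#' @param spectral_bw_hz sampling bandwidth of the record (Hz).
#' @return An object of class `noise_record`.
#' @export
noise_record <- function(fid, spectral_bw_hz) {
  if (!is.matrix(fid)) fid <- matrix(fid, nrow = 1)
  if (ncol(fid) < 64)
    stopf("noise record needs >= 64 samples for covariance estimation (got %d)",
          ncol(fid))
  if (spectral_bw_hz <= 0) stopf("spectral_bw_hz must be > 0")
  if (any(!is.finite(Re(fid))) || any(!is.finite(Im(fid))))
    stopf("noise fid contains non-finite values")
  structure(list(fid = fid, spectral_bw_hz = as.numeric(spectral_bw_hz),
                 n_samples = ncol(fid)),
            class = "noise_record")
}

#' Channel noise covariance model
#'
#' Holds the complex Hermitian channel covariance matrix (Psi), the
#' noise-equivalent bandwidth factor applied (or to be applied), and
#' whether the bandwidth scaling has been performed.
#'
#' @param psi complex Hermitian covariance matrix.
#' @param neb_factor noise-equivalent bandwidth factor in (0, 1.5].
#' @param scaled logical; `TRUE` once [scale_covariance()] has been applied.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(psi, neb_factor = 1, scaled = FALSE) {
  psi <- as.matrix(psi)
  if (!is.complex(psi)) psi <- psi + 0i
  if (nrow(psi) != ncol(psi)) stopf("psi must be square")
  herm_err <- max(Mod(psi - Conj(t(psi))))
  scale <- max(Mod(psi))
  if (herm_err > 1e-8 * max(scale, 1))
    stopf("psi is not Hermitian (max asymmetry %g)", herm_err)
  dg <- Re(diag(psi))
  if (any(dg <= 0)) stopf("psi diagonal must be real and positive")
  if (neb_factor <= 0 || neb_factor > 1.5)
    stopf("neb_factor must lie in (0, 1.5]")
  structure(list(psi = (psi + Conj(t(psi))) / 2,
                 neb_factor = as.numeric(neb_factor),
                 scaled = isTRUE(scaled)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: %d channel(s), neb_factor %.4g, %s\n",
              nrow(x$psi), x$neb_factor,
              if (x$scaled) "bandwidth-scaled" else "unscaled"))
  invisible(x)
}

#' Per-channel complex signal map at the in-phase time point
#'
#' @param s complex array `[ny, nx, channel]`.
#' @param inphase_time_ms continuous first in-phase time (ms after sampling
#'   start).
#' @param inphase_index 0-based FID sample offset the signal was taken from.
#' @param filter_gain documented signal-scale factor `1/sqrt(p)` introduced
#'   by the noise-std-preserving spectral filter (1 if unfiltered).
#' @return An object of class `signal_map`.
#' @export
signal_map <- function(s, inphase_time_ms, inphase_index, filter_gain = 1) {
  if (length(dim(s)) == 2) dim(s) <- c(dim(s), 1)
  if (length(dim(s)) != 3) stopf("s must be [ny, nx, channel]")
  if (inphase_index < 0) stopf("inphase_index must be >= 0")
  structure(list(s = s, inphase_time_ms = as.numeric(inphase_time_ms),
                 inphase_index = as.integer(inphase_index),
                 filter_gain = as.numeric(filter_gain)),
            class = "signal_map")
}

#' Complex coil sensitivity profiles with support mask
#'
#' @param b complex array `[ny, nx, channel]`; zero outside `mask`.
#' @param mask logical `[ny, nx]` support mask.
#' @param norm_convention label; `"sos-unit"` means the channel vector has
#'   unit sum-of-squares magnitude at every masked voxel.
#' @return An object of class `sensitivity_map`.
#' @export
sensitivity_map <- function(b, mask, norm_convention = "sos-unit") {
  if (length(dim(b)) == 2) dim(b) <- c(dim(b), 1)
  if (length(dim(b)) != 3) stopf("b must be [ny, nx, channel]")
  mask <- as.logical(mask)
  dim(mask) <- dim(b)[1:2]
  if (any(!is.finite(Re(b))) || any(!is.finite(Im(b))))
    stopf("b contains non-finite values")
  b <- b * rep(mask, times = dim(b)[3])  # zero outside support
  sos <- sqrt(apply(Mod(b)^2, c(1, 2), sum))
  if (any(mask & sos == 0))
    stopf("every masked voxel needs at least one channel with |b| > 0")
  structure(list(b = b, mask = mask,
                 norm_convention = as.character(norm_convention)),
            class = "sensitivity_map")
}

#' Scalar SNR map
#'
#' @param snr non-negative real `[ny, nx]`; zero outside `mask`.
#' @param mask logical support mask.
#' @param n_channels number of receive channels combined.
#' @return An object of class `snr_map`.
#' @export
snr_map <- function(snr, mask, n_channels) {
  snr <- as.matrix(snr)
  mask <- as.logical(mask); dim(mask) <- dim(snr)
  if (any(snr < 0)) stopf("snr must be non-negative")
  snr[!mask] <- 0
  structure(list(snr = snr, mask = mask, n_channels = as.integer(n_channels)),
            class = "snr_map")
}

#' @export
print.snr_map <- function(x, ...) {
  s <- snr_summary(x)
  cat(sprintf("snr_map: %dx%d, %d channel(s); center %.3g, surface %.3g\n",
              nrow(x$snr), ncol(x$snr), x$n_channels, s$center, s$surface))
  invisible(x)
}

#' SENSE geometry-factor map
#'
#' @param g real `[ny, nx]`; `NA` where the aliasing system is singular or
#'   the voxel is outside every evaluated aliasing set.
#' @param accel_R integer acceleration factor.
#' @param direction `"row"` or `"col"`: the undersampled image axis.
#' @param mask logical support mask.
#' @return An object of class `gfactor_map`.
#' @export
gfactor_map <- function(g, accel_R, direction, mask) {
  g <- as.matrix(g)
  direction <- match.arg(direction, c("row", "col"))
  mask <- as.logical(mask); dim(mask) <- dim(g)
  if (any(g[!is.na(g)] < 1 - 1e-6))
    stopf("g-factor below 1 beyond tolerance")
  structure(list(g = g, accel_R = as.integer(accel_R),
                 direction = direction, mask = mask),
            class = "gfactor_map")
}

#' Transmit (flip-angle scale) map
#'
#' @param beta real `[ny, nx]`, achieved/nominal flip-angle ratio.
#' @param smoothed logical; `TRUE` after [smooth_txmap()].
#' @return An object of class `tx_map`.
#' @export
tx_map <- function(beta, smoothed = FALSE) {
  beta <- as.matrix(beta)
  if (any(!is.finite(beta)) || any(beta < 0))
    stopf("beta must be finite and >= 0")
  structure(list(beta = beta, smoothed = isTRUE(smoothed)), class = "tx_map")
}
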