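#' Perona-Malik anisotropic diffusion of a complex image
#'
#' Iterative 4-neighbor diffusion with conductance
#' `g = exp(-(|grad| / kappa)^2)` evaluated on the magnitude image and
#' applied identically to the real and imaginary parts, so phase
#' structure is preserved.  Boundaries are reflecting (Neumann), which
#' makes the scheme conservative: the global mean is unchanged.  The
#' explicit scheme is stable for `dt <= 0.25` in 2-D.
#'
#' @param img complex (or real) `[ny, nx]` matrix.
#' @param kappa edge threshold: gradients well above `kappa` diffuse
#'   little (edges kept), gradients below smooth out.
#' @param n_iter number of iterations (0 returns the input).
#' @param dt time step, `<= 0.25`.
#' @return Filtered matrix.
#' @export
perona_malik_filter <- function(img, kappa, n_iter, dt = 0.2) {
  if (dt > 0.25) stopf("dt = %g is unstable; require dt <= 0.25", dt)
  if (n_iter < 0) stopf("n_iter must be >= 0")
  u <- img
  ny <- nrow(u); nx <- ncol(u)
  shift <- function(x, dr, dc) {   # replicate-edge shift (Neumann)
    r <- pmin(pmax(seq_len(ny) + dr, 1), ny)
    c <- pmin(pmax(seq_len(nx) + dc, 1), nx)
    x[r, c, drop = FALSE]
  }
  for (it in seq_len(n_iter)) {
    m <- Mod(u)
    dN <- shift(u, -1, 0) - u; gN <- exp(-(Mod(shift(m, -1, 0) - m) / kappa)^2)
    dS <- shift(u, +1, 0) - u; gS <- exp(-(Mod(shift(m, +1, 0) - m) / kappa)^2)
    dW <- shift(u, 0, -1) - u; gW <- exp(-(Mod(shift(m, 0, -1) - m) / kappa)^2)
    dE <- shift(u, 0, +1) - u; gE <- exp(-(Mod(shift(m, 0, +1) - m) / kappa)^2)
    u <- u + dt * (gN * dN + gS * dS + gW * dW + gE * dE)
  }
  u
}

#' SNR-adaptive Perona-Malik parameters
#'
#' Maps per-channel SNR statistics to filter parameters under the
#' qualitative contract: a high maximum SNR at the object edge yields a
#' small `kappa` (high anisotropy, edges preserved), and a high overall
#' SNR yields few iterations (minimal smoothing).
#' `kappa = c_k * noise_std * max(1, snr_ref / snr_max_edge)`;
#' `n_iter = clamp(round(c_n / max(snr_overall, eps)), 2, 200)`.
#'
#' @param snr_max_edge maximum SNR at the support boundary.
#' @param snr_overall mean SNR over the support.
#' @param noise_std channel noise standard deviation (complex).
#' @param c_k,snr_ref,c_n,dt mapping constants.
#' @return `list(kappa, n_iter, dt)`.
#' @export
auto_pm_params <- function(snr_max_edge, snr_overall, noise_std = 1,
                           c_k = 2, snr_ref = 20, c_n = 600, dt = 0.2) {
  if (snr_max_edge < 0 || snr_overall < 0) stopf("SNR estimates must be >= 0")
  kappa <- c_k * noise_std * max(1, snr_ref / max(snr_max_edge, 1e-12))
  n_iter <- max(2L, min(200L, as.integer(round(c_n / max(snr_overall, 1e-6)))))
  list(kappa = kappa, n_iter = n_iter, dt = dt)
}

# 3x3 binary dilation / erosion for mask cleanup.
dilate3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    r <- pmin(pmax(seq_len(ny) + dr, 1), ny)
    c <- pmin(pmax(seq_len(nx) + dc, 1), nx)
    out <- out | m[r, c]
  }
  out
}
erode3 <- function(m) !dilate3(!m)

#' Derive the object support mask from a signal map
#'
#' Voxels whose sum-of-squares channel magnitude exceeds `thresh` times
#' the sum-of-squares background noise level, morphologically closed by
#' one voxel.
#'
#' @param s a [signal_map()].
#' @param noise a [noise_model()].
#' @param thresh threshold in background-noise units.
#' @return Logical `[ny, nx]` mask.
#' @export
derive_mask <- function(s, noise, thresh = 3) {
  sos <- sqrt(apply(Mod(s$s)^2, c(1, 2), sum))
  # noise std is preserved through recon + filter, so psi applies directly
  level <- sqrt(sum(Re(diag(noise$psi))))
  erode3(dilate3(sos > thresh * level))
}

#' Estimate complex coil sensitivity profiles
#'
#' The near-uniform phantom channel images are themselves noisy estimates
#' of the receive profiles; each channel is smoothed by SNR-adaptive
#' Perona-Malik diffusion ([perona_malik_filter()], parameters from
#' [auto_pm_params()] using that channel's edge and overall SNR), then
#' the channel vector is normalized to unit sum-of-squares magnitude at
#' every masked voxel (`norm_convention = "sos-unit"`).  The combined-SNR
#' expression downstream is invariant to any per-voxel positive
#' rescaling of the profiles, so the normalization cannot bias SNR.
#'
#' @param s a [signal_map()].
#' @param noise a [noise_model()] (used for per-channel noise levels).
#' @param mask logical support mask; derived via [derive_mask()] if `NULL`.
#' @param pm_config optional list overriding [auto_pm_params()] constants
#'   (`c_k`, `snr_ref`, `c_n`, `dt`).
#' @return A [sensitivity_map()].
#' @export
estimate_sensitivities <- function(s, noise, mask = NULL, pm_config = list()) {
  stopifnot(inherits(s, "signal_map"), inherits(noise, "noise_model"))
  if (is.null(mask)) mask <- derive_mask(s, noise)
  if (!any(mask)) stopf("support mask is empty")
  nch <- dim(s$s)[3]
  edge <- mask & !erode3(mask)
  if (!any(edge)) edge <- mask
  b <- array(0i, dim = dim(s$s))
  for (c in seq_len(nch)) {
    sc <- s$s[, , c]
    sd_c <- sqrt(Re(noise$psi[c, c]))
    if (all(Mod(sc)[mask] == 0)) {
      warning(sprintf("channel %d is all-zero inside the mask; kept with zero weight", c))
      next
    }
    prm <- do.call(auto_pm_params,
                   c(list(snr_max_edge = max(Mod(sc)[edge]) / sd_c,
                          snr_overall = mean(Mod(sc)[mask]) / sd_c,
                          noise_std = sd_c),
                     pm_config))
    b[, , c] <- perona_malik_filter(sc, prm$kappa, prm$n_iter, prm$dt)
  }
  b <- b * rep(mask, times = nch)
  sos <- sqrt(apply(Mod(b)^2, c(1, 2), sum))
  sos[sos == 0] <- 1
  b <- b / rep(sos, times = nch)
  sensitivity_map(b, mask, norm_convention = "sos-unit")
}
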