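#' Estimate the channel noise covariance from a noise-only record
#'
#' `psi[i, j] = mean_t( n_i(t) * Conj(n_j(t)) )` over the raw noise
#' samples; Hermitian by construction, unscaled.  For a single-receiver
#' coil the result is the 1x1 complex sample variance.
#'
#' @param noise a [noise_record()].
#' @return An unscaled [noise_model()].
#' @export
estimate_noise_covariance <- function(noise) {
  stopifnot(inherits(noise, "noise_record"))
  fid <- noise$fid
  v <- rowMeans(Mod(fid)^2)
  if (any(v == 0))
    stopf("channel %d has zero noise variance", which(v == 0)[1])
  psi <- fid %*% Conj(t(fid)) / ncol(fid)
  noise_model((psi + Conj(t(psi))) / 2, neb_factor = 1, scaled = FALSE)
}

#' Estimate the noise-equivalent bandwidth factor
#'
#' The receiver's digital filter attenuates the band edges, so the
#' variance of broadband noise underestimates the passband-center noise
#' density.  The factor is the ratio of the mean power spectral density
#' over the full sampled band to the passband plateau, with the plateau
#' taken as the mean PSD over the central 50% of the band (unbiased for
#' any number of segment averages, unlike a median of periodogram bins,
#' which is biased low by up to log 2 when few segments are available).
#' PSDs are estimated by Welch averaging (Hann window, 50% overlap) and
#' pooled across channels.
#'
#' @param noise a [noise_record()]; 1024 or more samples recommended.
#' @param segment Welch segment length.
#' @param overlap Welch segment overlap fraction.
#' @return The dimensionless factor (1 for white noise).
#' @export
estimate_neb_factor <- function(noise, segment = 256, overlap = 0.5) {
  stopifnot(inherits(noise, "noise_record"))
  psd <- 0
  for (c in seq_len(nrow(noise$fid)))
    psd <- psd + welch_psd(noise$fid[c, ], segment, overlap)
  psd <- psd / nrow(noise$fid)
  n <- length(psd)
  central <- seq(floor(n / 4) + 1, floor(n / 4) + ceiling(n / 2))
  plateau <- mean(psd[central])
  if (plateau <= 0) stopf("passband plateau estimate is not positive")
  mean(psd) / plateau
}

#' Apply the noise-equivalent bandwidth scaling to a covariance model
#'
#' `psi_scaled = psi / factor`: for a factor below 1 (attenuated band
#' edges) the effective passband noise level is higher than the broadband
#' measurement, so division increases the variance.  Scaling twice is an
#' error.
#'
#' @param model an unscaled [noise_model()].
#' @param factor noise-equivalent bandwidth factor, e.g. from
#'   [estimate_neb_factor()] or a scanner constant such as 0.845 (GE) or
#'   0.793 (Siemens).
#' @return A scaled [noise_model()].
#' @export
scale_covariance <- function(model, factor) {
  stopifnot(inherits(model, "noise_model"))
  if (factor <= 0) stopf("neb factor must be > 0")
  if (model$scaled) stopf("noise model is already bandwidth-scaled")
  noise_model(model$psi / factor, neb_factor = factor, scaled = TRUE)
}

#' Noise correlation matrix and off-diagonal summaries
#'
#' `r[i, j] = |psi[i, j]| / sqrt(psi[i, i] * psi[j, j])`; the diagonal is
#' exactly 1 and entries lie in `[0, 1]` (up to estimation noise).
#'
#' @param model a [noise_model()].
#' @return `list(r, max_offdiag, mean_offdiag)`.
#' @export
correlation_matrix <- function(model) {
  stopifnot(inherits(model, "noise_model"))
  psi <- model$psi
  d <- sqrt(Re(diag(psi)))
  r <- Mod(psi) / outer(d, d)
  diag(r) <- 1
  off <- r[upper.tri(r)]
  list(r = r,
       max_offdiag = if (length(off)) max(off) else 0,
       mean_offdiag = if (length(off)) mean(off) else 0)
}
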