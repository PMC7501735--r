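#' SNR map for a single-receiver coil
#'
#' `SNR = sqrt(2) * |s| / sigma`, with `sigma` the scaled complex noise
#' standard deviation.  The factor `sqrt(2)` expresses SNR in terms of
#' the real channel noise component.
#'
#' @param s a [signal_map()] with exactly one channel.
#' @param noise a bandwidth-scaled [noise_model()].
#' @param mask logical support mask; [derive_mask()] if `NULL`.
#' @return An [snr_map()].
#' @export
snr_map_single <- function(s, noise, mask = NULL) {
  stopifnot(inherits(s, "signal_map"), inherits(noise, "noise_model"))
  if (dim(s$s)[3] != 1)
    stopf("signal map has %d channels; use snr_map_array()", dim(s$s)[3])
  if (!noise$scaled)
    warning("noise model is not bandwidth-scaled; applying psi as-is")
  if (is.null(mask)) mask <- derive_mask(s, noise)
  snr <- sqrt(2) * Mod(s$s[, , 1]) / sqrt(Re(noise$psi[1, 1]))
  snr_map(snr * mask, mask, 1L)
}

#' SNR map for an array coil via sensitivity-weighted combination
#'
#' Noise-covariance-weighted (Roemer) combination:
#' `SNR = sqrt(2) * |b^H Psi^-1 s| / sqrt(b^H Psi^-1 b)` per masked
#' voxel (for real covariance matrices this equals the transpose-starred
#' way the expression is often typeset; the Hermitian form is used
#' because it alone is invariant under per-channel complex gains).
#' This is the matched filter for the array: no linear
#' combination of channels achieves higher SNR, and the background of
#' the combined magnitude map keeps single-channel (Rician) statistics
#' regardless of channel count - the property that makes SNR comparable
#' between volume coils and arrays.  The linear systems are solved by
#' factorization of `Psi`; no explicit inverse is formed.
#'
#' @param s a [signal_map()].
#' @param b a [sensitivity_map()] with matching channel count.
#' @param noise a bandwidth-scaled [noise_model()].
#' @return An [snr_map()]; zero outside the sensitivity support mask.
#' @export
snr_map_array <- function(s, b, noise) {
  stopifnot(inherits(s, "signal_map"), inherits(b, "sensitivity_map"),
            inherits(noise, "noise_model"))
  nch <- dim(s$s)[3]
  if (dim(b$b)[3] != nch)
    stopf("signal (%d) and sensitivity (%d) channel counts differ",
          nch, dim(b$b)[3])
  if (nrow(noise$psi) != nch)
    stopf("psi is %dx%d but data have %d channels", nrow(noise$psi),
          ncol(noise$psi), nch)
  if (!noise$scaled)
    warning("noise model is not bandwidth-scaled; applying psi as-is")
  mask <- b$mask
  idx <- which(mask)
  d <- dim(s$s)
  S <- matrix(s$s, d[1] * d[2], nch)[idx, , drop = FALSE]
  B <- matrix(b$b, d[1] * d[2], nch)[idx, , drop = FALSE]
  Y <- tryCatch(solve(noise$psi, t(B)),           # Psi^-1 b  [nch x V]
                error = function(e) {
                  sv <- svd(noise$psi)$d
                  stopf("psi is singular (condition number %.3g)",
                        max(sv) / max(min(sv), .Machine$double.xmin))
                })
  num <- Mod(colSums(Conj(t(S)) * Y))              # |b^H Psi^-1 s| (conj.)
  den <- sqrt(pmax(Re(colSums(Conj(t(B)) * Y)), 0))  # sqrt(b^H Psi^-1 b)
  snr <- matrix(0, d[1], d[2])
  snr[idx] <- sqrt(2) * num / den
  snr_map(snr, mask, nch)
}

#' Sum-of-squares combined map (reference statistic)
#'
#' Root-sum-of-squares channel combination scaled to noise units,
#' `sqrt(2) * sqrt(sum_c |s_c|^2 / psi_cc)`.  Its background follows a
#' non-central chi distribution with `2n` degrees of freedom - channel
#' count dependent, which is exactly why the covariance-weighted
#' combination of [snr_map_array()] is used for coil comparisons.
#'
#' @param s a [signal_map()].
#' @param noise a [noise_model()].
#' @param mask logical support mask.
#' @return An [snr_map()]-like object (values are not SNR in the Rician
#'   sense).
#' @export
sos_combine <- function(s, noise, mask = NULL) {
  nch <- dim(s$s)[3]
  if (is.null(mask)) mask <- matrix(TRUE, dim(s$s)[1], dim(s$s)[2])
  v <- Re(diag(noise$psi))
  acc <- 0
  for (c in seq_len(nch)) acc <- acc + Mod(s$s[, , c])^2 / v[c]
  snr_map(sqrt(2 * acc) * mask, mask, nch)
}

#' Summary statistics of an SNR map
#'
#' Center SNR is the mean over the 3x3 voxel block around the grid
#' center voxel (the DC-voxel convention: rows/cols `floor(n/2)` 0-based);
#' surface SNR is the maximum over the mask; the profiles are per-position
#' means over the three central lines in the anterior-posterior (rows)
#' and right-left (columns) directions.
#'
#' @param map an [snr_map()] (or [gfactor_map()] for in-mask summaries).
#' @param mask optional mask overriding the map's own.
#' @return `list(center, surface, profile_ap, profile_rl)`.
#' @export
snr_summary <- function(map, mask = NULL) {
  x <- map$snr %||% map$g
  mask <- mask %||% map$mask
  if (!any(mask)) stopf("mask is empty")
  ny <- nrow(x); nx <- ncol(x)
  cy <- floor(ny / 2) + 1; cx <- floor(nx / 2) + 1
  rows <- (cy - 1):(cy + 1); cols <- (cx - 1):(cx + 1)
  if (!all(mask[rows, cols])) {
    warning("3x3 center block extends outside the mask; center undefined")
    center <- NA_real_
  } else {
    center <- mean(x[rows, cols])
  }
  surface <- max(x[mask], na.rm = TRUE)
  list(center = center, surface = surface,
       profile_ap = rowMeans(x[, cols, drop = FALSE]),
       profile_rl = colMeans(x[rows, , drop = FALSE]))
}

#' SENSE geometry-factor map for uniform retrospective undersampling
#'
#' For acceleration `R` along the chosen image axis, each set of `R`
#' equally spaced voxels aliases onto one reduced-FOV voxel.  With `S`
#' the `n_channels x R'` sensitivity matrix of the masked set members,
#' `g_rho = sqrt([(S^H Psi^-1 S)^-1]_rho,rho * [S^H Psi^-1 S]_rho,rho)`.
#' `g >= 1` wherever defined; voxels in singular aliasing sets are
#' returned as `NA` and counted in the `"n_singular"` attribute.
#'
#' @param b a [sensitivity_map()].
#' @param noise a [noise_model()].
#' @param R integer acceleration factor; must divide the matrix size
#'   along `direction` and not exceed the channel count.
#' @param direction `"row"` (undersample anterior-posterior) or `"col"`
#'   (right-left).
#' @param mask optional mask; defaults to the sensitivity support.
#' @return A [gfactor_map()].
#' @export
sense_gfactor <- function(b, noise, R, direction = c("row", "col"),
                          mask = NULL) {
  stopifnot(inherits(b, "sensitivity_map"), inherits(noise, "noise_model"))
  direction <- match.arg(direction)
  mask <- mask %||% b$mask
  d <- dim(b$b); ny <- d[1]; nx <- d[2]; nch <- d[3]
  R <- as.integer(R)
  if (R > nch) stopf("R = %d exceeds the channel count (%d)", R, nch)
  nax <- if (direction == "row") ny else nx
  if (nax %% R != 0) stopf("R = %d does not divide the matrix size %d", R, nax)
  g <- matrix(NA_real_, ny, nx)
  n_singular <- 0L
  stride <- nax / R
  psi <- noise$psi
  for (j in seq_len(if (direction == "row") nx else ny)) {
    for (r0 in seq_len(stride)) {
      set <- r0 + (0:(R - 1)) * stride
      Smat <- if (direction == "row") t(matrix(b$b[set, j, ], length(set), nch))
              else t(matrix(b$b[j, set, ], length(set), nch))
      inmask <- if (direction == "row") mask[set, j] else mask[j, set]
      if (!any(inmask)) next
      Sm <- Smat[, inmask, drop = FALSE]
      M <- Conj(t(Sm)) %*% solve(psi, Sm)           # S^H Psi^-1 S
      Minv <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(Minv) || !all(is.finite(Re(diag(Minv))))) {
        n_singular <- n_singular + sum(inmask)
        next
      }
      gv <- sqrt(pmax(Re(diag(Minv)) * Re(diag(M)), 0))
      kk <- which(inmask)
      for (ii in seq_along(kk)) {
        if (direction == "row") g[set[kk[ii]], j] <- gv[ii]
        else g[j, set[kk[ii]]] <- gv[ii]
      }
    }
  }
  out <- gfactor_map(g, R, direction, mask)
  attr(out, "n_singular") <- n_singular
  out
}

#' Smooth a transmit map by first-order local polynomial fitting
#'
#' Per voxel, an unweighted least-squares plane is fitted over the square
#' region of the given physical size (masked voxels only) and evaluated
#' at the voxel.  A region with fewer than 3 masked voxels falls back to
#' the nearest masked neighbor and is counted in the `"n_fallback"`
#' attribute.  Exact planes are reproduced unchanged.
#'
#' @param tx a [tx_map()].
#' @param region_mm side length of the fitting region (mm); 75 mm by
#'   default (a 5x5 window at 15 mm resolution).
#' @param acq an [acquisition_spec()].
#' @param mask logical mask of valid voxels; all voxels if `NULL`.
#' @return A smoothed [tx_map()].
#' @export
smooth_txmap <- function(tx, region_mm = 75, acq, mask = NULL) {
  stopifnot(inherits(tx, "tx_map"))
  beta <- tx$beta
  ny <- nrow(beta); nx <- ncol(beta)
  mask <- mask %||% matrix(TRUE, ny, nx)
  dy <- acq$fov_mm[1] / acq$matrix_size[1]
  dx <- acq$fov_mm[2] / acq$matrix_size[2]
  hy <- max(1, round((region_mm / dy - 1) / 2))
  hx <- max(1, round((region_mm / dx - 1) / 2))
  if (2 * hy + 1 < 2 && 2 * hx + 1 < 2) stopf("region must span >= 2 voxels")
  out <- matrix(NA_real_, ny, nx)
  n_fallback <- 0L
  midx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    rr <- max(1, r - hy):min(ny, r + hy)
    cc <- max(1, c - hx):min(nx, c + hx)
    sub <- mask[rr, cc]
    if (sum(sub) < 3) {
      dd <- (midx[, 1] - r)^2 + (midx[, 2] - c)^2
      out[r, c] <- beta[midx[which.min(dd), 1], midx[which.min(dd), 2]]
      n_fallback <- n_fallback + 1L
      next
    }
    ys <- rep(rr, times = length(cc))[sub]
    xs <- rep(cc, each = length(rr))[sub]
    z <- beta[rr, cc][sub]
    X <- cbind(1, ys - r, xs - c)
    fit <- stats::lm.fit(X, z)
    out[r, c] <- fit$coefficients[1]
  }
  res <- tx_map(pmax(out, 0), smoothed = TRUE)
  attr(res, "n_fallback") <- n_fallback
  res
}

#' Theoretical SNR loss from transmit inhomogeneity
#'
#' Under a steady-state assumption, the signal at flip-angle scale `beta`
#' relative to nominal is `S(beta * alpha)` with
#' `S(a) = sin(a) (1 - E1) / (1 - cos(a) E1)`, `E1 = exp(-TR/T1)`.  The
#' relative loss is `1 - S(beta * alpha) / S(alpha)`.
#'
#' @param beta a [tx_map()] or numeric matrix of flip-angle scales.
#' @param t1_ms longitudinal relaxation time (700 ms for ethylene
#'   glycol).
#' @param tr_ms repetition time (ms).
#' @param nominal_flip_deg nominal flip angle (degrees).
#' @return Matrix of relative SNR losses (0 where `beta = 1`; may be
#'   negative where `beta` over-flips toward the steady-state optimum).
#' @export
tx_snr_loss <- function(beta, t1_ms = 700, tr_ms = 1000,
                        nominal_flip_deg = 70) {
  if (inherits(beta, "tx_map")) beta <- beta$beta
  if (any(beta < 0)) stopf("beta must be >= 0")
  s0 <- steady_state_factor(nominal_flip_deg, tr_ms, t1_ms)
  1 - steady_state_factor(beta * nominal_flip_deg, tr_ms, t1_ms) / s0
}
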