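test_that("scalar SNR formula and its reduction behave as printed", {
  s <- signal_map(array(10 + 0i, c(1, 1, 1)), 0, 0)
  nm <- noise_model(matrix(2 + 0i), scaled = TRUE)
  expect_equal(snr_map_single(s, nm, matrix(TRUE, 1, 1))$snr[1, 1], 10)
  s0 <- signal_map(array(0i, c(1, 1, 1)), 0, 0)
  expect_equal(snr_map_single(s0, nm, matrix(TRUE, 1, 1))$snr[1, 1], 0)
  expect_error(snr_map_single(signal_map(array(0i, c(1, 1, 2)), 0, 0), nm),
               "snr_map_array")
})

test_that("covariance-weighted combination matches the hand-worked example", {
  b_vec <- c(0.8 + 0i, 0.6i)
  s <- signal_map(array(5 * b_vec, c(1, 1, 2)), 0, 0)
  b <- sensitivity_map(array(b_vec, c(1, 1, 2)), matrix(TRUE, 1, 1))
  nm <- noise_model(diag(2) + 0i, scaled = TRUE)
  expect_equal(snr_map_array(s, b, nm)$snr[1, 1], sqrt(2) * 5,
               tolerance = 1e-9)
  expect_error(snr_map_array(s, b, noise_model(diag(3) + 0i, scaled = TRUE)),
               "channels")
})

test_that("no linear channel combination beats the matched filter", {
  # noiseless signal s = A b with correlated noise: brute-force search
  # over random weight vectors never exceeds the closed form
  set.seed(61)
  nch <- 6
  psi <- 0.3 + 0.7 * diag(nch)
  psi <- psi + 0i
  b_vec <- complex(real = rnorm(nch), imaginary = rnorm(nch))
  A <- 3
  s <- signal_map(array(A * b_vec, c(1, 1, nch)), 0, 0)
  bm <- sensitivity_map(array(b_vec, c(1, 1, nch)), matrix(TRUE, 1, 1))
  nm <- noise_model(psi, scaled = TRUE)
  opt <- snr_map_array(s, bm, nm)$snr[1, 1]
  for (k in 1:500) {
    w <- complex(real = rnorm(nch), imaginary = rnorm(nch))
    cand <- sqrt(2) * Mod(sum(w * A * b_vec)) /
      sqrt(Re(sum(Conj(w) * (psi %*% w))))
    expect_lte(cand, opt + 1e-6)
  }
  # the matched weights themselves attain it
  w_star <- solve(psi, Conj(b_vec))
  att <- sqrt(2) * Mod(sum(w_star * A * b_vec)) /
    sqrt(Re(sum(Conj(w_star) * (psi %*% w_star))))
  expect_equal(att, opt, tolerance = 1e-9)
})

test_that("combined SNR is invariant to profile rescaling and unitary gains", {
  set.seed(62)
  dims <- c(4, 4, 3)
  b_arr <- cnoise(dims, 63)
  s_arr <- cnoise(dims, 64)
  mask <- matrix(TRUE, 4, 4)
  psi <- diag(3) * 2 + 0.5 + 0i; diag(psi) <- c(2.5, 2.1, 3)
  nm <- noise_model(psi, scaled = TRUE)
  base <- snr_map_array(signal_map(s_arr, 0, 0),
                        sensitivity_map(b_arr, mask), nm)
  # per-voxel positive rescaling of b
  scale <- matrix(runif(16, 0.1, 5), 4)
  b_resc <- b_arr * rep(scale, 3)
  resc <- snr_map_array(signal_map(s_arr, 0, 0),
                        sensitivity_map(b_resc, mask), nm)
  expect_equal(resc$snr, base$snr, tolerance = 1e-9)
  # simultaneous per-channel phase gains on s, b and psi
  g <- exp(1i * c(0.3, -1.2, 2.2))
  s_g <- sweep(s_arr, 3, g, `*`)
  b_g <- sweep(b_arr, 3, g, `*`)
  psi_g <- diag(g) %*% psi %*% Conj(diag(g))
  gain <- snr_map_array(signal_map(s_g, 0, 0),
                        sensitivity_map(b_g, mask),
                        noise_model(psi_g, scaled = TRUE))
  expect_equal(gain$snr, base$snr, tolerance = 1e-9)
})

test_that("including noise correlations pays off where channels couple", {
  # correlated top-paddle channels: reconstruction with the full
  # covariance materially outperforms the diagonal approximation there
  sim <- fx("array8_corr", function() {
    psi <- diag(0.005^2, 8) + 0i
    psi[1:4, 1:4] <- 0.005^2 * (0.7 + 0.3 * diag(4))
    simulate_csi(phantom_spec(), builtin_layout("array8"), acq_short(),
                 psi, seed = 4, noise_samples = 4096)
  })
  s <- chain_signal(sim)
  nm <- chain_noise_model(sim)
  mask <- sim$truth$mask_frac > 0.5
  bt <- sensitivity_map(sim$truth$b_true * rep(mask, 8), mask)
  full <- snr_map_array(s, bt, nm)
  nm_diag <- noise_model(diag(Re(diag(nm$psi))) + 0i, nm$neb_factor,
                         scaled = TRUE)
  diag_ <- snr_map_array(s, bt, nm_diag)
  top <- mask & row(mask) <= 10          # region seen by the coupled paddle
  ratio_top <- mean(full$snr[top] / diag_$snr[top])
  expect_gt(ratio_top, 1.3)
  # noiseless: the full covariance is never worse anywhere
  simc <- fx("array8_clean", function() {
    psi <- diag(0.005^2, 8) + 0i
    psi[1:4, 1:4] <- 0.005^2 * (0.7 + 0.3 * diag(4))
    simulate_csi(phantom_spec(), builtin_layout("array8"), acq_short(),
                 psi * 1e-20, seed = 5)
  })
  sc <- chain_signal(simc)
  psi <- diag(0.005^2, 8) + 0i
  psi[1:4, 1:4] <- 0.005^2 * (0.7 + 0.3 * diag(4))
  nm_true <- noise_model(psi, scaled = TRUE)
  nm_true_diag <- noise_model(diag(Re(diag(psi))) + 0i, scaled = TRUE)
  fullc <- snr_map_array(sc, bt, nm_true)
  # true SNR of the diagonal-weighted combination under the real noise
  w_num <- vapply(which(mask), function(i) {
    bv <- vapply(1:8, function(c) bt$b[, , c][i], 0i)
    sv <- vapply(1:8, function(c) sc$s[, , c][i], 0i)
    w <- solve(nm_true_diag$psi, Conj(bv))
    sqrt(2) * Mod(sum(sv * w)) / sqrt(Re(sum(Conj(w) * (psi %*% w))))
  }, 0)
  expect_true(all(fullc$snr[mask] >= w_num - 1e-6))
})

test_that("summary statistics follow the center and surface conventions", {
  mask <- matrix(FALSE, 24, 24); mask[6:19, 6:19] <- TRUE
  flat <- snr_map(mask * 7, mask, 1L)
  ss <- snr_summary(flat)
  expect_equal(ss$center, 7)
  expect_equal(ss$surface, 7)
  expect_true(all(ss$profile_rl[6:19] == 7))
  # a hot edge voxel moves the surface value, not the center
  hot <- mask * 7; hot[6, 10] <- 50
  ss2 <- snr_summary(snr_map(hot, mask, 1L))
  expect_equal(ss2$surface, 50)
  expect_equal(ss2$center, 7)
  # center block (0-based rows/cols 11-13) is exactly snr[12:14, 12:14]
  ramp <- snr_map(matrix(seq_len(576) / 10, 24), mask, 1L)
  expect_equal(snr_summary(ramp)$center, mean(ramp$snr[12:14, 12:14]))
  # center undefined when the block leaves the mask
  edge_mask <- matrix(FALSE, 24, 24); edge_mask[1:4, 1:4] <- TRUE
  expect_warning(ssu <- snr_summary(snr_map(edge_mask * 1, edge_mask, 1L)),
                 "undefined")
  expect_true(is.na(ssu$center))
})

test_that("g-factor closed forms and guards hold", {
  nm <- noise_model(diag(2) + 0i, scaled = TRUE)
  # orthogonal aliased sensitivities: no amplification
  b2 <- array(0i, c(2, 1, 2)); b2[1, 1, ] <- c(1, 0); b2[2, 1, ] <- c(0, 1)
  g <- sense_gfactor(sensitivity_map(b2, matrix(TRUE, 2, 1)), nm, 2, "row")
  expect_equal(as.vector(g$g), c(1, 1), tolerance = 1e-9)
  # 60 degrees apart: g = 1/sin(60)
  th <- 60 * pi / 180
  b3 <- array(0i, c(2, 1, 2)); b3[1, 1, ] <- c(1, 0)
  b3[2, 1, ] <- c(cos(th), sin(th))
  g3 <- sense_gfactor(sensitivity_map(b3, matrix(TRUE, 2, 1)), nm, 2, "row")
  expect_equal(as.vector(g3$g), rep(1 / sin(th), 2), tolerance = 1e-6)
  # R = 1 is the identity case
  g1 <- sense_gfactor(sensitivity_map(b3, matrix(TRUE, 2, 1)), nm, 1, "row")
  expect_equal(as.vector(g1$g), c(1, 1), tolerance = 1e-12)
  # guards
  expect_error(sense_gfactor(sensitivity_map(b3, matrix(TRUE, 2, 1)), nm,
                             4, "row"), "exceeds")
  b9 <- array(1 + 0i, c(9, 1, 2))
  expect_error(sense_gfactor(sensitivity_map(b9, matrix(TRUE, 9, 1)),
                             nm, 2, "row"), "divide")
  # identical sensitivities in an aliasing set are flagged singular
  bs <- array(0i, c(2, 1, 2)); bs[1, 1, ] <- c(1, 1); bs[2, 1, ] <- c(1, 1)
  gs <- sense_gfactor(sensitivity_map(bs, matrix(TRUE, 2, 1)), nm, 2, "row")
  expect_true(all(is.na(gs$g)))
  expect_gt(attr(gs, "n_singular"), 0)
})

test_that("array g-factor maps are ordered in acceleration", {
  acq <- acq_short()
  mask <- phantom_mask(phantom_spec(), acq) > 0.5
  for (layout in c("array14", "array8")) {
    b_true <- coilqa:::layout_sensitivities(builtin_layout(layout), acq)
    bm <- sensitivity_map(b_true * rep(mask, dim(b_true)[3]), mask)
    nm <- noise_model(diag(dim(b_true)[3]) + 0i, scaled = TRUE)
    dirn <- if (layout == "array14") "col" else "row"
    g2 <- sense_gfactor(bm, nm, 2, dirn)
    g4 <- sense_gfactor(bm, nm, 4, dirn)
    ok <- mask & !is.na(g2$g) & !is.na(g4$g)
    expect_gt(sum(ok), 0.9 * sum(mask))
    expect_true(all(g2$g[ok] >= 1 - 1e-9))
    expect_true(all(g4$g[ok] >= g2$g[ok] - 1e-9))
  }
})

test_that("transmit-map smoothing reproduces planes and attenuates noise", {
  acq <- acquisition_spec()
  plane <- outer(seq_len(24), seq_len(24),
                 function(r, c) 1 + 0.01 * r - 0.005 * c)
  sm <- smooth_txmap(tx_map(plane), 75, acq)
  expect_equal(sm$beta, plane, tolerance = 1e-12)
  expect_true(sm$smoothed)
  cst <- smooth_txmap(tx_map(matrix(1.07, 24, 24)), 75, acq)
  expect_equal(cst$beta, matrix(1.07, 24, 24), tolerance = 1e-12)
  set.seed(65)
  noisy <- tx_map(plane + matrix(rnorm(576, sd = 0.05), 24))
  smn <- smooth_txmap(noisy, 75, acq)
  expect_gt(stats::sd(noisy$beta - plane) / stats::sd(smn$beta - plane), 3)
})

test_that("steady-state transmit SNR loss follows the closed form", {
  expect_equal(tx_snr_loss(matrix(1), 700, 1000, 70)[1, 1], 0)
  # beta = 0.7 at the protocol settings: about 12.5% loss
  e1 <- exp(-1000 / 700)
  S <- function(a) sin(a) * (1 - e1) / (1 - cos(a) * e1)
  expect_equal(tx_snr_loss(matrix(0.7), 700, 1000, 70)[1, 1],
               1 - S(0.7 * 70 * pi / 180) / S(70 * pi / 180),
               tolerance = 1e-12)
  expect_equal(tx_snr_loss(matrix(0.7), 700, 1000, 70)[1, 1], 0.125,
               tolerance = 0.01)
  # loss grows monotonically as beta falls below the optimum
  betas <- seq(1, 0.3, by = -0.05)
  losses <- vapply(betas, function(b)
    tx_snr_loss(matrix(b), 700, 1000, 70)[1, 1], 0)
  expect_true(all(diff(losses) > 0))
})
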