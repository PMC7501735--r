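test_that("covariance estimation converges and handles edge cases", {
  psi <- diag(3) + 0i
  psi[1, 2] <- psi[2, 1] <- 0.4; psi[2, 3] <- 0.2i; psi[3, 2] <- -0.2i
  frob <- function(m) sqrt(sum(Mod(m)^2))
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    nr <- simulate_noise(psi, n, seed = as.integer(n))
    est <- estimate_noise_covariance(nr)
    frob(est$psi - psi) / frob(psi)
  }, 0)
  expect_lt(err[3], 0.02)
  expect_true(all(diff(err) < 0))        # error shrinks as n grows
  # single channel reduces to the complex sample variance
  nr1 <- simulate_noise(matrix(2 + 0i), 5000, seed = 41)
  est1 <- estimate_noise_covariance(nr1)
  expect_identical(dim(est1$psi), c(1L, 1L))
  expect_equal(Re(est1$psi[1, 1]), mean(Mod(nr1$fid)^2), tolerance = 1e-12)
  # identical channels give correlation exactly 1
  dup <- noise_record(rbind(nr1$fid, nr1$fid), 5000)
  r <- correlation_matrix(estimate_noise_covariance(dup))
  expect_equal(r$r[1, 2], 1)
  # a zero-variance channel is reported by index
  z <- noise_record(rbind(nr1$fid, 0 * nr1$fid), 5000)
  expect_error(estimate_noise_covariance(z), "channel 2")
})

test_that("noise-equivalent bandwidth estimation matches analytic factors", {
  white <- simulate_noise(matrix(1 + 0i), 2e5, seed = 42)
  expect_equal(estimate_neb_factor(white), 1, tolerance = 0.03)
  brick <- simulate_noise(matrix(1 + 0i), 2e5, seed = 42,
                          coloring = noise_filter("brickwall", keep = 0.8))
  expect_equal(estimate_neb_factor(brick), 0.8, tolerance = 0.03)
  rc <- noise_filter("raised_cosine", rolloff = 0.2)
  colored <- simulate_noise(matrix(1 + 0i), 2e5, seed = 43, coloring = rc)
  expect_equal(estimate_neb_factor(colored), neb_of_filter(rc),
               tolerance = 0.03)
  # the cosine-tapered band integrates to 1 - rolloff/2
  expect_equal(neb_of_filter(rc), 0.9, tolerance = 1e-3)
})

test_that("bandwidth scaling divides the covariance once", {
  nm <- noise_model(matrix(1 + 0i))
  expect_identical(scale_covariance(nm, 1)$psi, nm$psi)
  scaled <- scale_covariance(nm, 0.845)
  expect_equal(Re(scaled$psi[1, 1]), 1 / 0.845, tolerance = 1e-12)
  expect_true(scaled$scaled)
  expect_error(scale_covariance(scaled, 0.845), "already")
  # downstream SNR falls by sqrt(factor) when the factor shrinks
  s <- signal_map(array(10 + 0i, c(1, 1, 1)), 0, 0)
  m1 <- snr_map_single(s, scale_covariance(noise_model(matrix(1 + 0i)), 1),
                       matrix(TRUE, 1, 1))
  m05 <- snr_map_single(s, scale_covariance(noise_model(matrix(1 + 0i)), 0.5),
                        matrix(TRUE, 1, 1))
  expect_equal(m05$snr[1, 1] / m1$snr[1, 1], sqrt(0.5), tolerance = 1e-12)
})

test_that("correlation matrices are normalized and scale-invariant", {
  nm <- noise_model(diag(4) + 0i)
  r <- correlation_matrix(nm)
  expect_equal(r$r, diag(4))
  expect_equal(r$max_offdiag, 0)
  # uniform rho = 0.7 construction recovered from samples
  psi <- 0.7 + 0.3 * diag(8); psi <- psi + 0i
  nr <- simulate_noise(psi, 1e5, seed = 44)
  est <- correlation_matrix(estimate_noise_covariance(nr))
  off <- est$r[upper.tri(est$r)]
  expect_equal(max(off), 0.7, tolerance = 0.03 / 0.7)
  expect_true(all(off >= 0 & off <= 1))
  # invariant under per-channel rescaling
  g <- c(1, 2, 0.5, 3, 1, 1, 2, 0.1)
  psi_scaled <- diag(g) %*% psi %*% diag(g)
  expect_equal(correlation_matrix(noise_model(psi_scaled))$r,
               correlation_matrix(noise_model(psi))$r, tolerance = 1e-12)
})

test_that("applying the estimated NEB factor reconciles colored noise SNR", {
  # colored receiver noise, single channel: after NEB scaling, the
  # pipeline SNR agrees with the white-noise analytic value within 5%
  acq <- acquisition_spec(n_fid_points = 256)
  ph <- phantom_spec()
  sim <- simulate_csi(ph, builtin_layout("volume"), acq, matrix(0.01^2 + 0i),
                      seed = 45, noise_samples = 16384)
  filt <- noise_filter("brickwall", keep = 0.8)
  colored <- simulate_noise(matrix(0.01^2 + 0i), 16384, seed = 46,
                            coloring = filt)
  # color the acquisition noise identically, filtering along time
  sim_c <- simulate_csi(ph, builtin_layout("volume"), acq,
                        matrix(1e-30 + 0i), seed = 45)
  nt <- acq$n_fid_points
  fn <- (seq_len(nt) - 1) / nt; fn[fn >= 0.5] <- fn[fn >= 0.5] - 1
  h <- coilqa:::filter_response(filt, fn)
  w <- matrix(cnoise(c(24 * 24, nt), seed = 47, sd = 0.01), 24 * 24, nt)
  colored_t <- t(apply(w, 1, function(x)
    stats::fft(stats::fft(x) * h, inverse = TRUE) / nt))
  raw <- csi_raw_data(sim_c$raw$kspace +
                        array(as.vector(colored_t), c(24, 24, 1, nt)), acq)
  img <- spectral_filter(recon_csi(raw), 10, acq)
  ip <- sim$truth$inphase
  s <- extract_signal(img, ip$index, ip$time_ms)
  neb <- estimate_neb_factor(colored)
  nm <- scale_covariance(estimate_noise_covariance(colored), neb)
  mask <- sim$truth$mask_frac > 0.99
  m <- snr_map_single(s, nm, mask)
  expect_equal(mean(m$snr[mask]) / mean(sim$truth$snr_true[mask]), 1,
               tolerance = 0.05)
})
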