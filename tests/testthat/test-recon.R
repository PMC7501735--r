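test_that("spatial reconstruction is unitary", {
  acq <- acquisition_spec(n_fid_points = 16)
  ks <- cnoise(c(24, 24, 1, 16), seed = 31)
  raw <- csi_raw_data(ks, acq)
  img <- recon_csi(raw)
  # Parseval
  expect_equal(sum(Mod(img)^2), sum(Mod(ks)^2), tolerance = 1e-12)
  # white noise in, white noise of identical std out
  expect_equal(stats::sd(c(Re(img), Im(img))), stats::sd(c(Re(ks), Im(ks))),
               tolerance = 0.01)
  # delta at the DC index gives a constant image of 1/sqrt(Nkx*Nky)
  ks0 <- array(0i, c(24, 24, 1, 16)); ks0[13, 13, 1, 1] <- 2
  img0 <- recon_csi(csi_raw_data(ks0, acq))
  expect_equal(as.vector(Mod(img0[, , 1, 1])), rep(2 / 24, 24 * 24),
               tolerance = 1e-12)
})

test_that("spectral filter preserves noise std and rescales in-band signal", {
  acq <- acquisition_spec(n_fid_points = 1024)
  x <- cnoise(c(24, 24, 1, 1024), seed = 32)          # > 1e5 samples
  # half-band window
  ppm_half <- (acq$spectral_bw_hz / 4) / (1e-6 * acq$center_freq_hz)
  f <- spectral_filter(x, ppm_half, acq)
  expect_equal(attr(f, "keep_fraction"), 0.5009766, tolerance = 1e-6)
  expect_equal(stats::sd(c(Re(f), Im(f))), stats::sd(c(Re(x), Im(x))),
               tolerance = 0.02)
  # full-band window is the identity
  ppm_full <- (acq$spectral_bw_hz / 2) / (1e-6 * acq$center_freq_hz)
  f2 <- spectral_filter(x, ppm_full, acq)
  expect_equal(attr(f2, "keep_fraction"), 1)
  expect_lt(max(Mod(f2 - x)), 1e-10)
  # beyond Nyquist errors
  expect_error(spectral_filter(x, 1.01 * ppm_full, acq), "Nyquist")
  # noiseless in-band signal is scaled by exactly 1/sqrt(p)
  nt <- 256; acq2 <- acquisition_spec(n_fid_points = nt)
  sig <- array(0i, c(1, 1, 1, nt))
  f_bin <- 5 * 5000 / nt                 # an exact spectral bin in-band
  sig[1, 1, 1, ] <- exp(2i * pi * f_bin * (seq_len(nt) - 1) / 5000)
  fs <- spectral_filter(sig, 10, acq2)
  p <- attr(fs, "keep_fraction")
  expect_equal(Mod(fs[1, 1, 1, 10]), 1 / sqrt(p), tolerance = 1e-9)
})

test_that("first in-phase time follows J and TE", {
  acq <- acquisition_spec()
  # the three protocol echo times snap to 4.8, 4.4, 4.0 ms: mean 4.4 ms
  snapped <- vapply(c(2.3, 2.7, 3.1), function(te)
    first_inphase_sample(142, te, acq)$snapped_time_ms, 0)
  expect_equal(snapped, c(4.8, 4.4, 4.0))
  ip <- first_inphase_sample(142, 2.7, acq)
  expect_identical(ip$index, 22L)
  expect_equal(ip$time_ms, 1000 / 142 - 2.7)
  # TE already a multiple of 1/J: t = 0
  expect_equal(first_inphase_sample(142, 1000 / 142, acq)$time_ms, 0)
  expect_identical(first_inphase_sample(142, 1000 / 142, acq)$index, 0L)
  # enumerated multiple: J = 100 Hz, TE = 3 ms -> 7 ms
  expect_equal(first_inphase_sample(100, 3, acq)$time_ms, 7)
  # snapped residual is below half a dwell
  for (te in c(0.9, 2.3, 3.3, 5.1)) {
    ipk <- first_inphase_sample(142, te, acq)
    expect_lt(abs(ipk$snapped_time_ms - ipk$time_ms),
              0.5 * 1000 / acq$spectral_bw_hz)
  }
  expect_error(first_inphase_sample(142, 2.7,
                                    acquisition_spec(n_fid_points = 10)),
               "beyond")
})

test_that("signal extraction picks the in-phase sample", {
  acq <- acquisition_spec(n_fid_points = 64)
  sim <- simulate_csi(phantom_spec(), builtin_layout("volume"), acq,
                      matrix(1e-30 + 0i), seed = 3, band_ppm = 10)
  img <- spectral_filter(recon_csi(sim$raw), 10, acq)
  ip <- sim$truth$inphase
  s <- extract_signal(img, ip$index, ip$time_ms)
  expect_s3_class(s, "signal_map")
  ss <- coilqa:::steady_state_factor(acq$nominal_flip_deg, acq$tr_ms, 700)
  expected <- ss * Mod(ethylene_glycol_fid(ip$snapped_time_ms, phantom_spec(),
                                           acq$te_ms)) /
    sqrt(sim$truth$filter_keep_fraction)
  expect_equal(Mod(s$s[13, 13, 1]), expected, tolerance = 0.02)
  expect_error(extract_signal(img, 64), "out of range")
  expect_equal(Mod(extract_signal(img * 0, 0)$s), array(0, c(24, 24, 1)))
})

test_that("J coupling is recovered from synthetic triplets", {
  acq <- acquisition_spec()
  sp142 <- synth_spectrum(phantom_spec(j_hz = 142, t2star_ms = 90), acq)
  expect_equal(estimate_j_coupling(sp142, acq), 142, tolerance = 2 / 142)
  sp100 <- synth_spectrum(phantom_spec(j_hz = 100, t2star_ms = 90), acq)
  expect_equal(estimate_j_coupling(sp100, acq), 100, tolerance = 2 / 100)
  singlet <- synth_spectrum(phantom_spec(line_amplitudes = c(0, 1, 0)), acq)
  expect_error(estimate_j_coupling(singlet, acq), "peaks")
})

test_that("T2* is recovered from the center-peak linewidth", {
  acq <- acquisition_spec()
  for (tau in c(80, 132)) {
    sp <- synth_spectrum(phantom_spec(t2star_ms = tau), acq)
    expect_equal(estimate_t2star(sp, acq), tau, tolerance = 0.03)
  }
  # doubling T2* halves the (untruncated) apparent linewidth
  w80 <- coilqa:::apparent_fwhm_hz(0.080, 1e6, 5000)
  w160 <- coilqa:::apparent_fwhm_hz(0.160, 1e6, 5000)
  expect_equal(w80 / w160, 2, tolerance = 1e-4)
  expect_equal(w80, sqrt(3) / (pi * 0.080), tolerance = 1e-4)
  # plain convention drops the 1/pi
  sp80 <- synth_spectrum(phantom_spec(t2star_ms = 80), acq)
  expect_equal(estimate_t2star(sp80, acq, "plain") /
                 estimate_t2star(sp80, acq, "lorentzian"), pi,
               tolerance = 1e-6)
})
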