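make_block <- function(samples, fs = 40, depth = 2, sos = 1540) {
  structure(list(samples = samples, depth_centre = depth,
                 lateral_centre = 1, sampling_rate = fs,
                 speed_of_sound = sos), class = "qus_rf_block")
}

test_that("windowed power spectrum localizes a sinusoid and is linear in gain", {
  n <- 104
  t <- (seq_len(n) - 1) / 40
  x <- matrix(sin(2 * pi * 5 * t), n, 4)
  ps <- windowed_power_spectrum(make_block(x))
  df <- ps$freq_mhz[2] - ps$freq_mhz[1]
  expect_lt(abs(ps$freq_mhz[which.max(ps$value_db)] - 5), df + 1e-9)
  ps2 <- windowed_power_spectrum(make_block(2 * x))
  expect_equal(ps2$value_db - ps$value_db, rep(20 * log10(2), length(ps$value_db)))
})

test_that("white-noise window spectra are flat in band after line averaging", {
  set.seed(31)
  x <- matrix(rnorm(104 * 17), 104, 17)
  ps <- windowed_power_spectrum(make_block(x))
  sel <- ps$freq_mhz >= 4.2 & ps$freq_mhz <= 7.8
  dev <- ps$value_db[sel] - mean(ps$value_db[sel])
  expect_lt(max(abs(dev)), 3)
})

test_that("degenerate blocks are rejected or flagged", {
  expect_error(windowed_power_spectrum(make_block(matrix(0, 10, 4))), "32 samples")
  ps <- windowed_power_spectrum(make_block(matrix(0, 104, 4)))
  expect_false(ps$valid)
  expect_true(all(is.na(ps$value_db)))
})

test_that("self-normalization gives 0 dBr and zero spectral parameters in band", {
  refset <- shared_refset()
  acq <- default_acq()
  fr <- refset$phantom_frames[[1]]
  grid <- slide_windows(fr, matrix(TRUE, nrow(fr$samples), ncol(fr$samples)),
                        overlap = 0.5)
  set.seed(4)
  idx <- sample(which(grid$centres$row > 300 & grid$centres$row < 1800), 250)
  acc <- 0
  for (i in idx) {
    bl <- extract_block(fr, grid$centres$row[i], grid$centres$line[i],
                        grid$window_samples, grid$window_lines)
    psn <- normalize_to_phantom(windowed_power_spectrum(bl, nfft = grid$nfft),
                                refset)
    acc <- acc + 10^(psn$value_db / 10)
  }
  # mean normalized power spectrum: average in linear power, then dB
  mean_dbr <- qusmap:::db(acc / length(idx))
  sel <- psn <- NULL
  f <- qusmap:::half_freq_grid(grid$nfft, acq$sampling_rate)
  sel <- f >= 4.2 & f <= 7.8
  expect_lt(max(abs(mean_dbr[sel])), 1)
  fit <- fit_spectral_line(
    qusmap:::new_spectrum(f, mean_dbr, "phantom", 2, acq$sampling_rate,
                          grid$window_samples, grid$nfft, 17), c(4.2, 7.8))
  expect_lt(abs(fit$mbf), 0.5)
  expect_lt(abs(fit$ss), 0.5)
  expect_lt(abs(fit$si), 2)
})

test_that("a flat gain between sample and reference normalizes to 20 log10(g)", {
  refset <- shared_refset()
  fr <- refset$phantom_frames[[2]]
  bl <- extract_block(fr, 900, 200, 105, 17)
  ps <- windowed_power_spectrum(bl)
  bl2 <- bl; bl2$samples <- 3 * bl$samples
  ps2 <- windowed_power_spectrum(bl2)
  n1 <- normalize_to_phantom(ps, refset)
  n2 <- normalize_to_phantom(ps2, refset)
  expect_equal(n2$value_db - n1$value_db,
               rep(20 * log10(3), length(n1$value_db)))
})

test_that("attenuation compensation follows the layered two-way power formula", {
  f <- seq(1, 10, by = 0.5)
  ps <- qusmap:::new_spectrum(f, rep(0, length(f)), "phantom", 2, 40, 104,
                              512, 17)
  same <- compensate_attenuation(ps, data.frame(thickness_cm = 0, coeff = 1))
  expect_equal(same$value_db, ps$value_db)
  one <- compensate_attenuation(ps, data.frame(thickness_cm = 1, coeff = 1))
  expect_equal(one$value_db[f == 1], 4)
  expect_equal(one$value_db[f == 6], 24)
  expect_error(compensate_attenuation(
    ps, data.frame(thickness_cm = -1, coeff = 1)), "negative")
  expect_error(compensate_attenuation(
    windowed_power_spectrum(make_block(matrix(rnorm(416), 104, 4))),
    data.frame(thickness_cm = 1, coeff = 1)), "normalize")
})

test_that("attenuate-then-compensate round trip restores the spectrum within 1 dB", {
  # identical scatterer realization, two attenuation levels; after exact
  # compensation the mean normalized spectra must coincide in band
  acq <- default_acq()
  refset <- shared_refset()
  ratio <- refset$phantom_sos / acq$speed_of_sound
  ph_lo <- homogeneous_phantom(alpha = refset$phantom_attenuation * ratio)
  ph_hi <- homogeneous_phantom(alpha = 1.0)
  fr_lo <- simulate_frame(ph_lo, acq, seed = 77)
  fr_hi <- simulate_frame(ph_hi, acq, seed = 77)
  grid <- slide_windows(fr_lo, central_roi(), overlap = 0.5)
  idx <- which(grid$centres$inside)
  idx <- idx[seq(1, length(idx), by = 2)]
  f <- qusmap:::half_freq_grid(grid$nfft, acq$sampling_rate)
  sel <- f >= 4.2 & f <= 7.8
  acc_lo <- acc_hi <- 0
  for (i in idx) {
    bl_lo <- extract_block(fr_lo, grid$centres$row[i], grid$centres$line[i],
                           grid$window_samples, grid$window_lines)
    bl_hi <- extract_block(fr_hi, grid$centres$row[i], grid$centres$line[i],
                           grid$window_samples, grid$window_lines)
    n_lo <- normalize_to_phantom(windowed_power_spectrum(bl_lo, nfft = grid$nfft),
                                 refset)
    n_hi <- normalize_to_phantom(windowed_power_spectrum(bl_hi, nfft = grid$nfft),
                                 refset)
    z <- n_hi$depth_centre
    c_hi <- compensate_attenuation(
      n_hi, data.frame(thickness_cm = z, coeff = 1.0),
      reference_attenuation = refset$phantom_attenuation,
      reference_sos_ratio = ratio)
    acc_lo <- acc_lo + 10^(n_lo$value_db / 10)
    acc_hi <- acc_hi + 10^(c_hi$value_db / 10)
  }
  diff_db <- qusmap:::db(acc_hi[sel] / acc_lo[sel])
  expect_lt(max(abs(diff_db)), 1)
})

test_that("the spectral line fit is exact on a line and unbiased under noise", {
  f <- seq(3, 8, by = 0.1)
  ps <- qusmap:::new_spectrum(f, 2 * f - 5, "phantom", 2, 40, 104, 512, 17)
  fit <- fit_spectral_line(ps, c(3, 8))
  expect_equal(fit$ss, 2, tolerance = 1e-12)
  expect_equal(fit$si, -5, tolerance = 1e-12)
  expect_equal(fit$mbf, 2 * 5.5 - 5, tolerance = 1e-12)
  expect_equal(fit$mbf, fit$si + fit$ss * fit$f_centre)
  # Monte-Carlo unbiasedness of the slope under additive noise
  set.seed(17)
  ss_hat <- replicate(20000, {
    ps$value_db <- 2 * f - 5 + rnorm(length(f), sd = 2)
    fit_spectral_line(ps, c(3, 8))$ss
  })
  se <- sd(ss_hat) / sqrt(length(ss_hat))
  expect_lt(abs(mean(ss_hat) - 2), 2 * se)
})

test_that("MBF identity holds for arbitrary spectra", {
  set.seed(9)
  f <- seq(4, 8, by = 0.05)
  for (i in 1:20) {
    ps <- qusmap:::new_spectrum(f, rnorm(length(f), sd = 5), "phantom", 2,
                                40, 104, 512, 17)
    fit <- fit_spectral_line(ps, c(4, 8))
    expect_equal(fit$mbf, fit$si + fit$ss * fit$f_centre, tolerance = 1e-12)
  }
})

test_that("ACE reduces to the reference attenuation for a matched medium", {
  acq <- default_acq()
  refset <- shared_refset()
  ratio <- refset$phantom_sos / acq$speed_of_sound
  ph <- homogeneous_phantom(alpha = refset$phantom_attenuation * ratio)
  fr <- simulate_frame(ph, acq, seed = 21)
  ace <- estimate_ace(fr, central_roi(), refset, fast_config())
  expect_lt(abs(ace$ace - refset$phantom_attenuation), 0.1)
})

test_that("thin ROIs fall back to the configured default with a warning", {
  acq <- default_acq()
  refset <- shared_refset()
  fr <- refset$phantom_frames[[1]]
  roi <- matrix(FALSE, nrow(fr$samples), ncol(fr$samples))
  roi[1000:1056, 200:260] <- TRUE   # ~1 mm thick
  expect_warning(ace <- estimate_ace(fr, roi, refset, fast_config()),
                 "fallback")
  expect_true(ace$fallback)
  expect_equal(ace$ace, 1.0)
})
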