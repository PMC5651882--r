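test_that("BSC estimation scales the phantom model by the normalized spectrum", {
  refset <- shared_refset()
  f <- seq(4, 8, by = 0.1)
  mk <- function(v) {
    ps <- qusmap:::new_spectrum(f, v, "phantom", 2, 40, 104, 512, 17)
    ps$compensated <- TRUE
    ps
  }
  model <- approx(refset$bsc_model$freq_mhz, refset$bsc_model$bsc, xout = f)$y
  expect_equal(estimate_bsc(mk(rep(0, length(f))), refset)$bsc, model)
  expect_equal(estimate_bsc(mk(rep(10, length(f))), refset)$bsc, 10 * model)
  expect_error(estimate_bsc(mk(0 * f),
                            list(bsc_model = NULL)), "BSC model")
  raw <- qusmap:::new_spectrum(f, f, "raw", 2, 40, 104, 512, 17)
  expect_error(estimate_bsc(raw, refset), "compensated")
})

test_that("the Gaussian form-factor fit inverts the forward model exactly", {
  f <- seq(4, 8, by = 0.05)
  k <- 2 * pi * f * 1e6 / 1540
  a <- 50e-6
  C <- 30 * 4
  bsc <- structure(list(freq_mhz = f,
                        bsc = C * f^4 * exp(-0.827 * k^2 * a^2),
                        depth_centre = 2), class = "qus_bsc")
  fit <- fit_gaussian_form_factor(bsc, c(4, 8))
  expect_equal(fit$esd_um, 100, tolerance = 1e-9)
  expect_equal(fit$eac_db, db(C), tolerance = 1e-9)
  expect_lt(fit$fit_residual_db, 1e-9)
  expect_false(fit$pinned)
  # amplitude doubling: shape (ESD) unchanged, EAC up by 3.01 dB
  bsc2 <- bsc; bsc2$bsc <- 2 * bsc$bsc
  fit2 <- fit_gaussian_form_factor(bsc2, c(4, 8))
  expect_equal(fit2$esd_um, fit$esd_um, tolerance = 1e-12)
  expect_equal(fit2$eac_db - fit$eac_db, 10 * log10(2), tolerance = 1e-9)
})

test_that("non-physical (rising) form factors pin the ESD to the range edge", {
  f <- seq(4, 8, by = 0.05)
  bsc <- structure(list(freq_mhz = f, bsc = f^6, depth_centre = 2),
                   class = "qus_bsc")
  fit <- fit_gaussian_form_factor(bsc, c(4, 8), esd_range_um = c(20, 200))
  expect_true(fit$pinned)
  expect_equal(fit$esd_um, 20)
})

test_that("the Burg recursion matches the reference implementation per line", {
  set.seed(13)
  x <- matrix(rnorm(600), 120, 5)
  for (ord in c(2, 10, 25)) {
    own <- qusmap:::burg_columns(x, ord)
    for (j in 1:5) {
      ref <- stats::ar.burg(x[, j], aic = FALSE, order.max = ord,
                            demean = FALSE)
      expect_equal(own[seq_len(ord), j], -ref$ar, tolerance = 1e-10)
    }
  }
})

test_that("Burg spectra localize AR resonances and sinusoids", {
  # AR(2) with conjugate poles at 8 MHz (fs = 40 MHz)
  w0 <- 2 * pi * 8 / 40
  a <- c(2 * 0.95 * cos(w0), -0.95^2)
  set.seed(23)
  x <- matrix(0, 400, 8)
  for (j in 1:8) x[, j] <- as.numeric(
    stats::arima.sim(list(ar = a), 400))
  bl <- structure(list(samples = x, depth_centre = 2, lateral_centre = 1,
                       sampling_rate = 40, speed_of_sound = 1540),
                  class = "qus_rf_block")
  ps <- burg_spectrum(bl, order = 2)
  df <- ps$freq_mhz[2] - ps$freq_mhz[1]
  expect_lt(abs(ps$freq_mhz[which.max(ps$value_db)] - 8), 3 * df)
  # long sinusoid
  t <- (0:399) / 40
  bl$samples <- matrix(sin(2 * pi * 6.5 * t), 400, 2)
  ps2 <- burg_spectrum(bl, order = 8)
  expect_lt(abs(ps2$freq_mhz[which.max(ps2$value_db)] - 6.5), 3 * df)
  # white noise is flat in band
  set.seed(29)
  bl$samples <- matrix(rnorm(400 * 17), 400, 17)
  ps3 <- burg_spectrum(bl, order = 8)
  sel <- ps3$freq_mhz >= 4.2 & ps3$freq_mhz <= 7.8
  expect_lt(max(abs(ps3$value_db[sel] - mean(ps3$value_db[sel]))), 3)
})

test_that("AR spectra evaluated via FFT agree with the direct evaluation", {
  set.seed(41)
  x <- matrix(rnorm(300), 100, 3)
  ar <- qusmap:::burg_ar(x, 20)
  bins <- 150:400
  expect_equal(qusmap:::ar_psd_fft(ar, bins, 1024),
               qusmap:::ar_psd(ar, bins, 1024), tolerance = 1e-10)
})

test_that("the spacing-lag relation is exact: doubling the spacing halves the lag", {
  # synthetic comb spectra fed straight into the peak picker
  nfft <- 2048; fs <- 40; c_mps <- 1540
  df <- fs / nfft
  f <- (0:(nfft / 2)) * df
  sel <- f >= 3 & f <= 9
  for (d_mm in c(0.5, 1.0)) {
    delta_f <- c_mps / (2 * d_mm) / 1000
    v <- cos(2 * pi * f[sel] / delta_f)
    r <- qusmap:::autocorr_columns(matrix(v), length(v) - 2)
    lag <- qusmap:::sas_peaks_matrix(r, 2, nrow(r), 0.1)
    expect_equal(lag * df, delta_f, tolerance = 0.03)
  }
})

test_that("gain changes do not move the SAS estimate", {
  acq <- default_acq()
  refset <- shared_refset()
  ph <- homogeneous_phantom(pf = 0.6, lattice = 1.0)
  fr <- simulate_frame(ph, acq, seed = 31)
  bl <- extract_block(fr, 900, 250, 105, 17)
  s1 <- estimate_sas(bl, refset, c(3, 9))
  bl$samples <- 10 * bl$samples
  s2 <- estimate_sas(bl, refset, c(3, 9))
  expect_equal(s1$sas_mm, s2$sas_mm)
  expect_equal(s1$peak_prominence, s2$peak_prominence)
})

test_that("windows without a dominant autocorrelation peak are flagged missing", {
  refset <- shared_refset()
  n <- 105
  bl <- structure(list(samples = matrix(rep(sin((1:n) / 3), 17), n, 17),
                       depth_centre = 2, lateral_centre = 1,
                       sampling_rate = 40, speed_of_sound = 1540),
                  class = "qus_rf_block")
  s <- estimate_sas(bl, refset, c(3, 9))
  expect_true(is.na(s$sas_mm))
})
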