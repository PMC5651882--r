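test_that("window geometry matches the acquisition: 17 lines, 0.12 mm pitch", {
  acq <- default_acq()
  fr <- list(samples = matrix(0, qusmap:::n_axial_samples(acq),
                              acq$num_lines), acq = acq)
  class(fr) <- "qus_rf_frame"
  roi <- matrix(TRUE, nrow(fr$samples), ncol(fr$samples))
  grid <- slide_windows(fr, roi, window_mm = 2, overlap = 0.94)
  expect_equal(grid$window_lines, 17L)
  expect_equal(grid$pixel_pitch_mm, 0.12, tolerance = 1e-12)
  # integer strides imply a true pitch near the nominal value
  expect_lt(abs(grid$true_pitch_mm["axial"] - 0.12), 0.01)
  expect_lt(abs(grid$true_pitch_mm["lateral"] - 0.12), 0.01)
})

test_that("zero overlap tiles the ROI without window sharing", {
  acq <- default_acq()
  fr <- list(samples = matrix(0, qusmap:::n_axial_samples(acq),
                              acq$num_lines), acq = acq)
  class(fr) <- "qus_rf_frame"
  roi <- matrix(TRUE, nrow(fr$samples), ncol(fr$samples))
  grid <- slide_windows(fr, roi, window_mm = 2, overlap = 0)
  expect_gte(grid$stride_samples, grid$window_samples - 1)
  expect_gte(grid$stride_lines, grid$window_lines)
  expect_equal(length(grid$rows),
               floor((nrow(fr$samples) - grid$window_samples) /
                       grid$stride_samples) + 1)
})

test_that("an ROI smaller than one window is rejected with guidance", {
  acq <- default_acq()
  fr <- list(samples = matrix(0, qusmap:::n_axial_samples(acq),
                              acq$num_lines), acq = acq)
  class(fr) <- "qus_rf_frame"
  roi <- matrix(FALSE, nrow(fr$samples), ncol(fr$samples))
  roi[1000, 250] <- TRUE
  expect_error(slide_windows(fr, roi, gate = "full"), "ROI smaller")
})

test_that("full-containment gating is stricter than centre gating", {
  acq <- default_acq()
  fr <- list(samples = matrix(0, qusmap:::n_axial_samples(acq),
                              acq$num_lines), acq = acq)
  class(fr) <- "qus_rf_frame"
  roi <- qusmap::roi_mask(acq, list(cx_mm = 30, cz_mm = 20, ax_mm = 6,
                                    az_mm = 6))
  g_centre <- slide_windows(fr, roi, overlap = 0.5)
  g_full <- slide_windows(fr, roi, overlap = 0.5, gate = "full")
  expect_lt(sum(g_full$centres$inside), sum(g_centre$centres$inside))
  # full containment implies the centre is inside too
  expect_true(all(g_centre$centres$inside[g_full$centres$inside]))
})

map_fixture <- function() fixture("mapset", {
  acq <- default_acq()
  refset <- shared_refset()
  ph <- homogeneous_phantom(a_um = 55, eac_db = 38, alpha = 1.0, pf = 0.8,
                            lattice = 1.0)
  fr <- simulate_frame(ph, acq, seed = 3)
  list(frame = fr, roi = central_roi(),
       maps = build_parametric_maps(fr, central_roi(), shared_refset(),
                                    fast_config()))
})

test_that("all six maps share shape, pitch and validity support", {
  ms <- map_fixture()$maps
  shapes <- vapply(ms$maps, dim, integer(2))
  expect_true(all(shapes == shapes[, 1]))
  for (p in c("MBF", "SS", "SI", "ESD", "EAC"))
    expect_identical(is.na(ms$maps[[p]]), !ms$validity)
  # SAS may have extra missing pixels, but only inside the shared support
  expect_true(all(is.na(ms$maps$SAS[!ms$validity])))
})

test_that("batched map construction agrees with the per-window operation chain", {
  fx <- map_fixture()
  ms <- fx$maps; fr <- fx$frame; roi <- fx$roi
  acq <- fr$acq
  refset <- shared_refset()
  cfg <- fast_config()
  grid <- slide_windows(fr, roi, overlap = cfg$map$overlap)
  ratio <- refset$phantom_sos / acq$speed_of_sound
  z_top <- min(which(rowSums(roi) > 0)) * qusmap:::sample_pitch_mm(acq) / 10
  band <- c(cfg$spectral$band_lo_mhz, cfg$spectral$band_hi_mhz)
  rows_in <- which(ms$validity, arr.ind = TRUE)
  set.seed(8)
  pick <- rows_in[sample(nrow(rows_in), 5), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    r_idx <- pick[i, 1]; c_idx <- pick[i, 2]
    row <- round(ms$depth_cm[r_idx] * 10 / qusmap:::sample_pitch_mm(acq))
    line <- round(ms$lateral_cm[c_idx] * 10 / qusmap:::line_pitch_mm(acq))
    bl <- extract_block(fr, row, line, grid$window_samples,
                        grid$window_lines)
    ps <- windowed_power_spectrum(bl, nfft = grid$nfft)
    psn <- normalize_to_phantom(ps, refset)
    z <- psn$depth_centre
    psc <- compensate_attenuation(
      psn, data.frame(thickness_cm = c(min(z, z_top), max(z - z_top, 0)),
                      coeff = c(cfg$spectral$intervening_ace_db_mhz_cm,
                                ms$ace$ace)),
      reference_attenuation = refset$phantom_attenuation,
      reference_sos_ratio = ratio)
    fit <- fit_spectral_line(psc, band)
    expect_equal(fit$mbf, ms$maps$MBF[r_idx, c_idx], tolerance = 1e-6)
    expect_equal(fit$ss, ms$maps$SS[r_idx, c_idx], tolerance = 1e-6)
    expect_equal(fit$si, ms$maps$SI[r_idx, c_idx], tolerance = 1e-6)
    ff <- fit_gaussian_form_factor(estimate_bsc(psc, refset), band,
                                   sos = acq$speed_of_sound)
    expect_equal(ff$esd_um, ms$maps$ESD[r_idx, c_idx], tolerance = 1e-4)
    expect_equal(ff$eac_db, ms$maps$EAC[r_idx, c_idx], tolerance = 1e-6)
    sas <- estimate_sas(bl, refset,
                        c(acq$centre_frequency * (1 - 0.5),
                          acq$centre_frequency * (1 + 0.5)),
                        nfft = cfg$scatterer$sas_nfft)
    expect_equal(sas$sas_mm, ms$maps$SAS[r_idx, c_idx], tolerance = 1e-4)
  }
})

test_that("homogeneous media give spatially stable estimates", {
  ms <- map_fixture()$maps
  for (p in c("MBF", "SI", "ESD", "EAC")) {
    v <- ms$maps[[p]][ms$validity]
    expect_lt(sd(v) / abs(mean(v)), 0.3)
  }
  sas <- ms$maps$SAS[ms$validity]
  expect_lt(sd(sas, na.rm = TRUE) / mean(sas, na.rm = TRUE), 0.3)
})

test_that("frame-wide gain leaves SS/SAS/ESD fixed and shifts MBF/SI/EAC consistently", {
  fx <- map_fixture()
  fr2 <- fx$frame
  fr2$samples <- 2 * fr2$samples
  ms2 <- build_parametric_maps(fr2, fx$roi, shared_refset(), fast_config())
  ms <- fx$maps
  g <- 20 * log10(2)
  expect_equal(ms2$maps$SS, ms$maps$SS, tolerance = 1e-8)
  expect_equal(ms2$maps$ESD, ms$maps$ESD, tolerance = 1e-6)
  expect_equal(ms2$maps$SAS, ms$maps$SAS, tolerance = 1e-8)
  expect_equal(ms2$maps$MBF - ms$maps$MBF,
               ms$maps$MBF * 0 + g, tolerance = 1e-6)
  expect_equal(ms2$maps$SI - ms$maps$SI,
               ms$maps$SI * 0 + g, tolerance = 1e-6)
  expect_equal(ms2$maps$EAC - ms$maps$EAC,
               ms$maps$EAC * 0 + g, tolerance = 1e-6)
})

test_that("a two-compartment lesion separates in the ESD map with a large effect size", {
  acq <- default_acq()
  refset <- shared_refset()
  ph_small <- homogeneous_phantom(a_um = 40)
  ph_large <- homogeneous_phantom(a_um = 70)
  # two frames, same geometry: left half from one medium, right from the other
  fr_s <- simulate_frame(ph_small, acq, seed = 61)
  fr_l <- simulate_frame(ph_large, acq, seed = 62)
  fr <- fr_s
  fr$samples[, 257:512] <- fr_l$samples[, 257:512]
  ms <- build_parametric_maps(fr, central_roi(), refset, fast_config())
  left <- ms$maps$ESD[, ms$lateral_cm < 2.8]
  right <- ms$maps$ESD[, ms$lateral_cm > 3.2]
  left <- left[is.finite(left)]; right <- right[is.finite(right)]
  d <- (mean(right) - mean(left)) /
    sqrt((var(left) + var(right)) / 2)
  expect_gt(d, 1)
})
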