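# Windowed power spectra, reference-phantom normalization, attenuation
# estimation/compensation and the MBF/SS/SI line fit.

#' Cut an analysis block out of an RF frame
#'
#' @param frame A `qus_rf_frame`.
#' @param centre_row,centre_line Window centre, in samples / lines.
#' @param window_samples,window_lines Window extent.
#' @return A `qus_rf_block` with its physical depth and lateral centre.
#' @export
extract_block <- function(frame, centre_row, centre_line, window_samples,
                          window_lines) {
  hs <- (window_samples - 1) %/% 2
  hl <- (window_lines - 1) %/% 2
  rows <- (centre_row - hs):(centre_row - hs + window_samples - 1)
  cols <- (centre_line - hl):(centre_line - hl + window_lines - 1)
  if (rows[1] < 1 || rows[length(rows)] > nrow(frame$samples) ||
      cols[1] < 1 || cols[length(cols)] > ncol(frame$samples))
    stopf("analysis window falls outside the frame")
  acq <- frame$acq
  structure(list(
    samples = frame$samples[rows, cols, drop = FALSE],
    depth_centre = centre_row * sample_pitch_mm(acq) / 10,
    lateral_centre = centre_line * line_pitch_mm(acq) / 10,
    sampling_rate = acq$sampling_rate,
    speed_of_sound = acq$speed_of_sound
  ), class = "qus_rf_block")
}

new_spectrum <- function(freq, value, kind, depth, fs, window_samples,
                         nfft, n_lines, valid = TRUE, compensated = FALSE) {
  structure(list(freq_mhz = freq, value_db = value, kind = kind,
                 depth_centre = depth, fs = fs,
                 window_samples = window_samples, nfft = nfft,
                 n_lines = n_lines, valid = valid, compensated = compensated),
            class = "qus_spectrum")
}

#' @export
print.qus_spectrum <- function(x, ...) {
  cat(sprintf("%s power spectrum: %d bins to %.1f MHz, depth %.2f cm%s\n",
              x$kind, length(x$freq_mhz), max(x$freq_mhz), x$depth_centre,
              if (x$compensated) ", attenuation-compensated" else ""))
  invisible(x)
}

#' Windowed power spectrum of an RF block
#'
#' Hanning apodization along each scan line, squared-magnitude DFT, averaged
#' across the lines of the window, in dB. The transform length defaults to
#' the next power of two at least `nfft_factor` times the window length,
#' which stabilizes the band-edge regression.
#'
#' @param block A `qus_rf_block` (see [extract_block()]).
#' @param nfft_factor Zero-padding factor.
#' @param nfft Explicit transform length (overrides `nfft_factor`).
#' @return A raw `qus_spectrum` on the positive-frequency grid.
#' @export
windowed_power_spectrum <- function(block, nfft_factor = 4, nfft = NULL) {
  x <- block$samples
  n <- nrow(x)
  if (n < 32 || ncol(x) < 2)
    stopf("block too small for spectral analysis (need >= 32 samples x 2 lines)")
  nfft <- nfft %||% next_pow2(nfft_factor * n)
  valid <- any(x != 0)
  w <- hanning_window(n)
  xw <- x * w
  pad <- rbind(xw, matrix(0, nfft - n, ncol(x)))
  P <- Mod(stats::mvfft(pad))^2
  freq <- half_freq_grid(nfft, block$sampling_rate)
  pw <- rowMeans(P[seq_along(freq), , drop = FALSE])
  vals <- if (valid) db(pw) else rep(NA_real_, length(freq))
  new_spectrum(freq, vals, "raw", block$depth_centre, block$sampling_rate,
               n, nfft, ncol(x), valid = valid)
}

# ---- reference spectra ------------------------------------------------------

# Mean phantom power spectra on a depth grid, averaged over many independent
# blocks per depth row (all lateral positions of every phantom frame), cached
# on the reference set. Also caches planar-reflector periodograms.
reference_spectra <- function(refset, window_samples, nfft, row_stride = 16,
                              line_stride = 4) {
  key <- sprintf("ps_%d_%d", window_samples, nfft)
  if (!is.null(refset$cache[[key]])) return(refset$cache[[key]])
  acq <- refset$acq
  n_ax <- nrow(refset$phantom_frames[[1]]$samples)
  starts <- seq(1, n_ax - window_samples + 1, by = row_stride)
  w <- hanning_window(window_samples)
  freq <- half_freq_grid(nfft, acq$sampling_rate)
  acc <- matrix(0, length(freq), length(starts))
  n_acc <- 0
  for (fr in refset$phantom_frames) {
    cols <- seq(1, acq$num_lines, by = line_stride)
    for (s in seq_along(starts)) {
      seg <- fr$samples[starts[s]:(starts[s] + window_samples - 1), cols,
                        drop = FALSE] * w
      pad <- rbind(seg, matrix(0, nfft - window_samples, length(cols)))
      P <- Mod(stats::mvfft(pad))^2
      acc[, s] <- acc[, s] + rowSums(P[seq_along(freq), , drop = FALSE])
    }
    n_acc <- n_acc + length(cols)
  }
  depth_cm <- (starts + (window_samples - 1) / 2) * sample_pitch_mm(acq) / 10
  out <- list(freq_mhz = freq, depth_cm = depth_cm,
              ref_db = db(acc / n_acc), window_samples = window_samples,
              nfft = nfft)
  refset$cache[[key]] <- out
  out
}

# reference dB spectrum interpolated to a depth
ref_db_at_depth <- function(ref, depth_cm, window_cm) {
  d <- ref$depth_cm
  if (depth_cm < d[1] - window_cm / 2 ||
      depth_cm > d[length(d)] + window_cm / 2)
    stopf("no reference spectra within half a window of depth %.2f cm",
          depth_cm)
  i <- findInterval(depth_cm, d, all.inside = TRUE)
  t <- (depth_cm - d[i]) / (d[i + 1] - d[i])
  t <- min(max(t, 0), 1)
  ref$ref_db[, i] * (1 - t) + ref$ref_db[, i + 1] * t
}

#' Normalize a sample spectrum to the reference phantom
#'
#' Subtracts (in dB) the depth-matched mean phantom spectrum computed with
#' identical window settings, removing the system transfer function and
#' beam-forming effects; the result is in dBr.
#'
#' @param ps A raw `qus_spectrum`.
#' @param refset A [simulate_reference_set()] result (or an object with the
#'   same fields for measured data).
#' @return The phantom-normalized `qus_spectrum`.
#' @export
normalize_to_phantom <- function(ps, refset) {
  if (ps$kind != "raw") stopf("expected a raw power spectrum")
  ref <- reference_spectra(refset, ps$window_samples, ps$nfft)
  window_cm <- ps$window_samples * sample_pitch_mm(refset$acq) / 10
  rv <- ref_db_at_depth(ref, ps$depth_centre, window_cm)
  new_spectrum(ps$freq_mhz, ps$value_db - rv, "phantom", ps$depth_centre,
               ps$fs, ps$window_samples, ps$nfft, ps$n_lines,
               valid = ps$valid)
}

#' Point attenuation compensation of a normalized spectrum
#'
#' Adds back, in dB, the two-way frequency-dependent attenuation accumulated
#' along a layered path: `4 f sum_l (alpha_l - alpha_ref * sos_ratio) t_l`
#' with `f` in MHz, layer coefficients in dB/MHz/cm and thicknesses in cm.
#' For phantom-normalized spectra the compensation is differential against
#' the reference medium (whose depth at equal echo time scales by the
#' phantom/tissue speed-of-sound ratio); for reflector-normalized spectra
#' pass `reference_attenuation = 0` to compensate absolutely.
#'
#' @param ps A normalized `qus_spectrum`.
#' @param layers Data frame with columns `thickness_cm` and `coeff`
#'   (dB/MHz/cm) covering the propagation path to the window.
#' @param reference_attenuation Reference-medium attenuation, dB/MHz/cm.
#' @param reference_sos_ratio Reference-to-sample speed-of-sound ratio
#'   (maps equal echo time to reference depth).
#' @return The compensated `qus_spectrum`.
#' @export
compensate_attenuation <- function(ps, layers, reference_attenuation = 0,
                                   reference_sos_ratio = 1) {
  if (ps$kind == "raw") stopf("normalize the spectrum before compensating")
  if (any(layers$thickness_cm < 0)) stopf("negative layer thickness")
  eff <- sum((layers$coeff - reference_attenuation * reference_sos_ratio) *
               layers$thickness_cm)
  out <- ps
  out$value_db <- ps$value_db + 4 * ps$freq_mhz * eff
  out$compensated <- TRUE
  out
}

#' Linear fit of a normalized spectrum: MBF, SS, SI
#'
#' Ordinary least squares of dBr versus MHz over the analysis band. SS is
#' the slope (dBr/MHz), SI the intercept at 0 MHz (dBr) and MBF the fitted
#' value at the band-centre frequency, so `MBF = SI + SS * f_centre` holds by
#' construction.
#'
#' @param ps A normalized (and usually attenuation-compensated)
#'   `qus_spectrum`.
#' @param band Analysis band `c(lo, hi)`, MHz.
#' @return A `qus_spectral_fit` with fields `mbf`, `ss`, `si`, `band`,
#'   `f_centre` and `r_squared`.
#' @export
fit_spectral_line <- function(ps, band) {
  sel <- ps$freq_mhz >= band[1] & ps$freq_mhz <= band[2]
  if (sum(sel) < 8) stopf("need at least 8 frequency bins inside the band")
  f <- ps$freq_mhz[sel]
  y <- ps$value_db[sel]
  fc <- mean(band)
  fm <- mean(f); ym <- mean(y)
  ss <- sum((f - fm) * (y - ym)) / sum((f - fm)^2)
  si <- ym - ss * fm
  res <- y - (si + ss * f)
  r2 <- if (sum((y - ym)^2) > 0) 1 - sum(res^2) / sum((y - ym)^2) else 1
  structure(list(mbf = si + ss * fc, ss = ss, si = si, band = band,
                 f_centre = fc, r_squared = r2),
            class = "qus_spectral_fit")
}

#' @export
print.qus_spectral_fit <- function(x, ...) {
  cat(sprintf("MBF %.2f dBr, SS %.2f dBr/MHz, SI %.2f dBr (band %.1f-%.1f MHz, R^2 %.2f)\n",
              x$mbf, x$ss, x$si, x$band[1], x$band[2], x$r_squared))
  invisible(x)
}

#' Spectral-difference attenuation estimate over an ROI
#'
#' Estimates the tumour attenuation coefficient from the rate of change of
#' the phantom-normalized spectral power with depth: for each in-band
#' frequency the depth slope of dBr power over ROI windows is converted to a
#' differential attenuation via the two-way power convention
#' (`slope = -4 * delta_alpha(f)`, dB/cm), `delta_alpha(f) = a f` is fitted
#' through the origin, and the reference attenuation (scaled by the
#' speed-of-sound ratio) is added back.
#'
#' @param frame A `qus_rf_frame`.
#' @param roi Logical ROI mask on the frame sample grid.
#' @param refset Reference set (see [simulate_reference_set()]).
#' @param config Spectral configuration, see [qus_config()]; uses the
#'   analysis band, window size and fallback value.
#' @return A `qus_attenuation` with `ace` (dB/MHz/cm), the layer model used
#'   downstream, and diagnostic fields.
#' @export
estimate_ace <- function(frame, roi, refset, config = qus_config()) {
  sc <- config$spectral
  grid <- slide_windows(frame, roi, window_mm = config$map$window_mm,
                        overlap = sc$ace_overlap)
  band <- c(sc$band_lo_mhz, sc$band_hi_mhz)
  ratio <- refset$phantom_sos / frame$acq$speed_of_sound
  n_rows <- length(unique(grid$centres$row[grid$centres$inside]))
  if (sum(grid$centres$inside) < 8 || n_rows < 4) {
    warnf("ROI too thin for attenuation estimation; using fallback %.2f dB/MHz/cm",
          sc$ace_fallback)
    return(structure(list(ace = sc$ace_fallback, fallback = TRUE,
                          clamped = FALSE, n_windows = sum(grid$centres$inside)),
                     class = "qus_attenuation"))
  }
  idx <- which(grid$centres$inside)
  ref <- reference_spectra(refset, grid$window_samples, grid$nfft)
  sel <- NULL
  ys <- NULL
  zs <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    bl <- extract_block(frame, grid$centres$row[i], grid$centres$line[i],
                        grid$window_samples, grid$window_lines)
    ps <- windowed_power_spectrum(bl, nfft = grid$nfft)
    psn <- normalize_to_phantom(ps, refset)
    if (is.null(sel)) {
      sel <- psn$freq_mhz >= band[1] & psn$freq_mhz <= band[2]
      ys <- matrix(NA_real_, sum(sel), length(idx))
    }
    ys[, j] <- psn$value_db[sel]
    zs[j] <- psn$depth_centre
  }
  f <- half_freq_grid(grid$nfft, frame$acq$sampling_rate)[sel]
  zc <- zs - mean(zs)
  denom <- sum(zc^2)
  slopes <- as.numeric(ys %*% zc) / denom      # dB/cm per frequency bin
  delta_alpha <- -slopes / 4
  a <- sum(f * delta_alpha) / sum(f^2)
  ace <- a + refset$phantom_attenuation * ratio
  clamped <- ace < 0 || ace > 3
  ace <- min(max(ace, 0), 3)
  structure(list(ace = ace, fallback = FALSE, clamped = clamped,
                 n_windows = length(idx), n_rows = n_rows,
                 delta_alpha_per_mhz = a),
            class = "qus_attenuation")
}

#' @export
print.qus_attenuation <- function(x, ...) {
  cat(sprintf("ACE %.3f dB/MHz/cm (%d windows%s%s)\n", x$ace,
              x$n_windows %||% 0,
              if (isTRUE(x$fallback)) ", fallback" else "",
              if (isTRUE(x$clamped)) ", clamped" else ""))
  invisible(x)
}
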