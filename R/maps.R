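# Sliding-window engine producing the six co-registered parametric maps.

#' Sliding-window grid over an ROI
#'
#' Converts the nominal window size and overlap into integer sample/line
#' strides and enumerates window centres; a window is emitted when its
#' centre lies inside the ROI (default) or when it is fully contained.
#' With the default acquisition (512 lines / 6 cm) a 2 mm window spans 17
#' scan lines, and 94% overlap gives a nominal 0.12 mm isotropic pixel
#' pitch; the exact pitches implied by the integer strides are recorded as
#' metadata.
#'
#' @param frame A `qus_rf_frame`.
#' @param roi Logical ROI mask on the frame sample grid.
#' @param window_mm Window side length, mm.
#' @param overlap Fractional overlap between adjacent windows (both axes).
#' @param nfft_factor Zero-padding factor carried to the spectral stage.
#' @param gate `"centre"` (window centre inside ROI) or `"full"` (whole
#'   window inside ROI).
#' @return A `qus_window_grid`: window extent, strides, nominal and true
#'   pixel pitches, and the centre table with ROI membership.
#' @export
slide_windows <- function(frame, roi, window_mm = 2.0, overlap = 0.94,
                          nfft_factor = 4, gate = c("centre", "full")) {
  gate <- match.arg(gate)
  acq <- frame$acq
  sp <- sample_pitch_mm(acq)
  lp <- line_pitch_mm(acq)
  win_s <- round(window_mm / sp); win_s <- 2L * (win_s %/% 2L) + 1L
  win_l <- round(window_mm / lp); win_l <- 2L * (win_l %/% 2L) + 1L
  step_mm <- window_mm * (1 - overlap)
  stride_s <- max(1L, as.integer(round(step_mm / sp)))
  stride_l <- max(1L, as.integer(round(step_mm / lp)))
  hs <- (win_s - 1L) %/% 2L; hl <- (win_l - 1L) %/% 2L
  n_ax <- nrow(frame$samples); n_li <- ncol(frame$samples)
  rows <- seq(hs + 1L, n_ax - hs, by = stride_s)
  lines <- seq(hl + 1L, n_li - hl, by = stride_l)
  if (!length(rows) || !length(lines))
    stopf("frame smaller than one %.1f mm window", window_mm)

  if (gate == "centre") {
    inside <- roi[rows, lines, drop = FALSE]
  } else {
    # summed-area table: window fully inside ROI iff its ROI count equals
    # the window area
    sat <- apply(apply(roi, 2, cumsum), 1, cumsum)  # transposed table
    at <- function(c1, r1) ifelse(c1 >= 1 & r1 >= 1, sat[cbind(pmax(c1, 1), pmax(r1, 1))], 0)
    cnt <- function(r1, r2, c1, c2)
      at(c2, r2) - at(c1 - 1, r2) - at(c2, r1 - 1) + at(c1 - 1, r1 - 1)
    inside <- outer(rows, lines, function(r, l)
      cnt(r - hs, r + hs, l - hl, l + hl) == as.numeric(win_s) * win_l)
  }
  if (!any(inside))
    stopf("ROI smaller than one %.1f x %.1f mm window; enlarge the lesion ROI",
          window_mm, window_mm)

  centres <- data.frame(
    row = rep(rows, times = length(lines)),
    line = rep(lines, each = length(rows)),
    inside = as.vector(inside))
  centres$depth_cm <- centres$row * sp / 10
  centres$lateral_cm <- centres$line * lp / 10
  structure(list(
    window_samples = win_s, window_lines = win_l,
    stride_samples = stride_s, stride_lines = stride_l,
    rows = rows, lines = lines, centres = centres,
    pixel_pitch_mm = step_mm,
    true_pitch_mm = c(axial = stride_s * sp, lateral = stride_l * lp),
    nfft = next_pow2(nfft_factor * win_s), gate = gate
  ), class = "qus_window_grid")
}

#' @export
print.qus_window_grid <- function(x, ...) {
  cat(sprintf(
    "Window grid: %d samples x %d lines per window, %d x %d centres (%d in ROI)\n",
    x$window_samples, x$window_lines, length(x$rows), length(x$lines),
    sum(x$centres$inside)))
  cat(sprintf("  nominal pitch %.2f mm (true %.3f axial / %.3f lateral mm)\n",
              x$pixel_pitch_mm, x$true_pitch_mm[1], x$true_pitch_mm[2]))
  invisible(x)
}

# segment periodogram stack: single-line Hanning periodograms for every
# (window row, scan line) pair the grid can need, as [bins x nrow x nline]
segment_power <- function(samples, rows, line_range, win_s, nfft,
                          taper = TRUE) {
  n_ax <- nrow(samples)
  hs <- (win_s - 1L) %/% 2L
  starts <- rows - hs
  lines <- line_range
  seg0 <- rep((lines - 1L) * n_ax, each = length(starts)) +
    rep(starts, times = length(lines))
  idx <- outer(0:(win_s - 1L), seg0, "+")
  X <- matrix(samples[idx], win_s, length(seg0))
  if (taper) X <- X * hanning_window(win_s)
  X
}

moving_line_sum <- function(arr3, centre_lines, line_range, win_l) {
  hl <- (win_l - 1L) %/% 2L
  out <- 0
  for (o in (-hl):hl) {
    out <- out + arr3[, , match(centre_lines + o, line_range), drop = FALSE]
  }
  out
}

#' Build the six QUS parametric maps for one frame
#'
#' Runs the full per-window chain over the ROI: windowed power spectrum,
#' reference-phantom normalization, frame-level attenuation estimation,
#' two-layer (intervening tissue + tumour) point compensation, MBF/SS/SI
#' line fit, BSC estimation with the spherical Gaussian form-factor fit
#' (ESD/EAC), and AR-spectrum scatterer spacing (SAS) on the raw windows.
#' All six maps share the pixel grid and ROI validity support. The
#' computation batches the single-line spectra shared by overlapping
#' windows, and is verified against the per-window operations in the test
#' suite.
#'
#' @param frame A `qus_rf_frame`.
#' @param roi Logical ROI mask.
#' @param refset Reference set (see [simulate_reference_set()]).
#' @param config A [qus_config()].
#' @return A `qus_map_set`.
#' @export
build_parametric_maps <- function(frame, roi, refset, config = qus_config()) {
  acq <- frame$acq
  sc <- config$spectral; scat <- config$scatterer; mp <- config$map
  grid <- slide_windows(frame, roi, window_mm = mp$window_mm,
                        overlap = mp$overlap, nfft_factor = sc$nfft_factor,
                        gate = mp$gate)
  band <- c(sc$band_lo_mhz, sc$band_hi_mhz)
  R <- grid$rows; C <- grid$lines
  inside <- matrix(grid$centres$inside, length(R), length(C))
  ci <- range(which(colSums(inside) > 0)); ri <- range(which(rowSums(inside) > 0))
  R <- R[ri[1]:ri[2]]; C <- C[ci[1]:ci[2]]
  inside <- inside[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
  hl <- (grid$window_lines - 1L) %/% 2L
  E <- (min(C) - hl):(max(C) + hl)
  win_s <- grid$window_samples
  nfft <- grid$nfft
  fs <- acq$sampling_rate
  freq <- half_freq_grid(nfft, fs)
  bsel <- which(freq >= band[1] & freq <= band[2])
  f <- freq[bsel]
  depth_cm <- R * sample_pitch_mm(acq) / 10

  # --- mean normalized power spectra over the window grid
  X0 <- segment_power(frame$samples, R, E, win_s, nfft, taper = FALSE)
  pad <- matrix(0, nfft, ncol(X0))
  pad[seq_len(win_s), ] <- X0 * hanning_window(win_s)
  P <- Mod(stats::mvfft(pad))^2
  P <- P[bsel, , drop = FALSE]
  arr <- array(P, c(length(bsel), length(R), length(E)))
  W <- moving_line_sum(arr, C, E, grid$window_lines) / grid$window_lines
  Wm <- matrix(W, length(bsel))
  zero_win <- matrix(colSums(Wm <= 0) > 0, length(R), length(C))
  W[W <= 0] <- .Machine$double.xmin
  Y <- db(W)                                     # [bins x |R| x |C|]

  ref <- reference_spectra(refset, win_s, nfft)
  window_cm <- win_s * sample_pitch_mm(acq) / 10
  refv <- vapply(depth_cm, function(z)
    ref_db_at_depth(ref, z, window_cm)[bsel], numeric(length(bsel)))
  Yn <- sweep(Y, c(1, 2), refv, "-")             # phantom-normalized, dBr

  # --- frame-level attenuation estimate from pre-compensation spectra
  sos_ratio <- refset$phantom_sos / acq$speed_of_sound
  ins_idx <- which(inside)
  Ymat <- matrix(Yn, length(bsel), length(R) * length(C))
  z_all <- rep(depth_cm, times = length(C))
  n_rows_in <- length(unique(((ins_idx - 1) %% length(R)) + 1))
  if (length(ins_idx) >= 8 && n_rows_in >= 4) {
    zc <- z_all[ins_idx] - mean(z_all[ins_idx])
    slopes <- as.numeric(Ymat[, ins_idx, drop = FALSE] %*% zc) / sum(zc^2)
    a <- sum(f * (-slopes / 4)) / sum(f^2)
    ace_val <- min(max(a + refset$phantom_attenuation * sos_ratio, 0), 3)
    ace <- structure(list(ace = ace_val, fallback = FALSE,
                          clamped = ace_val %in% c(0, 3),
                          n_windows = length(ins_idx), n_rows = n_rows_in),
                     class = "qus_attenuation")
  } else {
    warnf("ROI too thin for attenuation estimation; using fallback %.2f dB/MHz/cm",
          sc$ace_fallback)
    ace <- structure(list(ace = sc$ace_fallback, fallback = TRUE,
                          clamped = FALSE, n_windows = length(ins_idx)),
                     class = "qus_attenuation")
  }

  # --- two-layer point compensation (intervening tissue above the ROI at
  #     the configured coefficient, tumour at the estimated ACE)
  roi_rows <- which(rowSums(roi) > 0)
  z_top <- min(roi_rows) * sample_pitch_mm(acq) / 10
  path <- sc$intervening_ace_db_mhz_cm * pmin(z_all, z_top) +
    ace$ace * pmax(z_all - z_top, 0) -
    refset$phantom_attenuation * sos_ratio * z_all
  Yc <- Ymat + outer(4 * f, path)                # compensated dBr

  # --- MBF / SS / SI
  fm <- mean(f); fc <- mean(band)
  fdev <- f - fm
  sslope <- as.numeric(crossprod(fdev, Yc)) / sum(fdev^2)
  sicpt <- colMeans(Yc) - sslope * fm
  mbf <- sicpt + sslope * fc

  # --- BSC + Gaussian form factor (ESD / EAC)
  model <- stats::approx(refset$bsc_model$freq_mhz, refset$bsc_model$bsc,
                         xout = f, rule = 2)$y
  Ylin <- log(model) + log(10) / 10 * Yc         # ln bsc
  yln <- Ylin - 4 * log(f)
  k2 <- (2 * pi * f * 1e6 / acq$speed_of_sound)^2
  k2c <- k2 - mean(k2)
  ffslope <- as.numeric(crossprod(k2c, yln)) / sum(k2c^2)
  fficpt <- colMeans(yln) - ffslope * mean(k2)
  esd <- rep(scat$esd_min_um, length(ffslope))
  neg <- ffslope < 0
  esd[neg] <- 2e6 * sqrt(-ffslope[neg] / 0.827)
  esd <- pmin(pmax(esd, scat$esd_min_um), scat$esd_max_um)
  eac <- 10 * fficpt / log(10)

  # --- SAS from AR spectra normalized to the planar reflector
  nfft_ar <- scat$sas_nfft
  sband <- c(scat$sas_band_lo_mhz %||%
               (acq$centre_frequency * (1 - acq$pulse_bandwidth_frac * 5 / 6)),
             scat$sas_band_hi_mhz %||%
               (acq$centre_frequency * (1 + acq$pulse_bandwidth_frac * 5 / 6)))
  ar_order <- scat$ar_order %||% floor(0.75 * win_s)
  # Burg on mean-removed raw segments
  ar <- burg_ar(X0 - rep(colMeans(X0), each = win_s), ar_order)
  df_ar <- fs / nfft_ar
  abins <- which(half_freq_grid(nfft_ar, fs) >= sband[1] &
                   half_freq_grid(nfft_ar, fs) <= sband[2]) - 1L
  f_ar <- abins * df_ar
  psd <- ar_psd_fft(ar, abins, nfft_ar)
  arr_ar <- array(psd, c(length(abins), length(R), length(E)))
  War <- moving_line_sum(arr_ar, C, E, grid$window_lines) / grid$window_lines
  Yar <- db(array(pmax(War, .Machine$double.xmin),
                  dim(War)))
  refl <- reflector_spectra(refset, win_s, nfft_ar)
  refl_row <- vapply(depth_cm, function(z)
    which.min(abs(refl$depths_cm - z)), integer(1))
  Yar <- Yar - array(refl$ref_db[abins + 1L, refl_row],
                     c(length(abins), length(R), length(C)))
  V <- matrix(Yar, length(abins), length(R) * length(C))
  # remove mean and linear tilt per window before the autocorrelation
  fac <- f_ar - mean(f_ar)
  V <- sweep(V, 2, colMeans(V))
  V <- V - outer(fac, as.numeric(crossprod(fac, V)) / sum(fac^2))
  nb <- length(abins)
  lag_lo <- acq$speed_of_sound / (2 * scat$sas_max_mm) / (1000 * df_ar)
  lag_hi <- acq$speed_of_sound / (2 * scat$sas_min_mm) / (1000 * df_ar)
  Lmax <- min(nb - 2L, floor(lag_hi) + 1L)
  rmat <- autocorr_columns(V, Lmax)
  lag_px <- sas_peaks_matrix(rmat, lag_lo, lag_hi, scat$sas_prominence)
  sas <- acq$speed_of_sound / (2 * lag_px * df_ar) / 1000
  sas[!as.vector(inside)] <- NA_real_

  shape <- c(length(R), length(C))
  validity <- inside & !zero_win
  as_map <- function(v) {
    m <- matrix(v, shape[1], shape[2])
    m[!validity] <- NA_real_
    m
  }
  maps <- list(MBF = as_map(mbf), SS = as_map(sslope), SI = as_map(sicpt),
               SAS = as_map(sas), ESD = as_map(esd), EAC = as_map(eac))
  structure(list(
    maps = maps, validity = validity,
    pixel_pitch_mm = grid$pixel_pitch_mm,
    true_pitch_mm = grid$true_pitch_mm,
    depth_cm = depth_cm,
    lateral_cm = C * line_pitch_mm(acq) / 10,
    ace = ace, band = band, plane_offset = frame$plane_offset,
    window = c(samples = win_s, lines = grid$window_lines)
  ), class = "qus_map_set")
}

#' @export
print.qus_map_set <- function(x, ...) {
  cat(sprintf("QUS parametric maps: %d x %d pixels (%.2f mm pitch), %d valid\n",
              nrow(x$maps$MBF), ncol(x$maps$MBF), x$pixel_pitch_mm,
              sum(x$validity)))
  for (p in names(x$maps)) {
    v <- x$maps[[p]][x$validity]
    cat(sprintf("  %-3s median %8.2f  IQR [%.2f, %.2f]  (%d NA)\n", p,
                stats::median(v, na.rm = TRUE),
                stats::quantile(v, 0.25, na.rm = TRUE),
                stats::quantile(v, 0.75, na.rm = TRUE), sum(is.na(v))))
  }
  cat(sprintf("  ACE %.2f dB/MHz/cm%s\n", x$ace$ace,
              if (isTRUE(x$ace$fallback)) " (fallback)" else ""))
  invisible(x)
}

#' Display a parametric map
#'
#' @param x A `qus_map_set`.
#' @param parameter Which map to draw.
#' @param ... Passed to [graphics::image()].
#' @export
plot.qus_map_set <- function(x, parameter = "MBF", ...) {
  m <- x$maps[[parameter]]
  graphics::image(x$lateral_cm, x$depth_cm, t(m[nrow(m):1, , drop = FALSE]),
                  xlab = "lateral (cm)", ylab = "depth (cm)",
                  main = parameter, useRaster = TRUE, ...)
  invisible(x)
}
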