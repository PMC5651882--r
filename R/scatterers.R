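# Backscatter-coefficient estimation, spherical Gaussian form-factor fitting
# (ESD/EAC) and scatterer-spacing (SAS) estimation from autoregressive
# spectra normalized to a planar reflector.

#' Backscatter coefficient via the reference-phantom method
#'
#' Converts an attenuation-compensated, phantom-normalized power spectrum to
#' a backscatter coefficient curve by scaling the phantom's known BSC:
#' `bsc(f) = bsc_phantom(f) * 10^(dBr(f)/10)`.
#'
#' @param ps A phantom-normalized, attenuation-compensated `qus_spectrum`.
#' @param refset Reference set carrying the tabulated `bsc_model`.
#' @return A `qus_bsc` with `freq_mhz` and linear-scale `bsc`.
#' @export
estimate_bsc <- function(ps, refset) {
  if (ps$kind != "phantom" || !isTRUE(ps$compensated))
    stopf("BSC estimation expects a phantom-normalized, attenuation-compensated spectrum")
  if (is.null(refset$bsc_model)) stopf("reference set has no phantom BSC model")
  model <- stats::approx(refset$bsc_model$freq_mhz, refset$bsc_model$bsc,
                         xout = ps$freq_mhz, rule = 1)$y
  structure(list(freq_mhz = ps$freq_mhz, bsc = model * 10^(ps$value_db / 10),
                 depth_centre = ps$depth_centre),
            class = "qus_bsc")
}

#' Spherical Gaussian form-factor fit: ESD and EAC
#'
#' Fits `bsc(f) = C f^4 exp(-0.827 k^2 a^2)` by linear regression of
#' `ln(bsc) - 4 ln(f)` on `k^2` over the analysis band: the slope gives the
#' effective scatterer radius (`slope = -0.827 a^2`, ESD = 2a) and the
#' intercept the effective acoustic concentration in dB
#' (`EAC = 10 log10(C)`), exactly inverting the simulator's forward model in
#' the noise-free case.
#'
#' @param bsc A `qus_bsc` curve.
#' @param band Analysis band `c(lo, hi)`, MHz.
#' @param esd_range_um Physical search range for ESD; estimates are pinned to
#'   the range edge (and flagged) on non-physical slopes.
#' @param sos Speed of sound used for the acoustic wavenumber, m/s.
#' @return A `qus_scatterer_fit` with `esd_um`, `eac_db`, `fit_residual_db`
#'   and a `pinned` flag.
#' @export
fit_gaussian_form_factor <- function(bsc, band, esd_range_um = c(20, 200),
                                     sos = 1540) {
  sel <- bsc$freq_mhz >= band[1] & bsc$freq_mhz <= band[2] & bsc$bsc > 0 &
    is.finite(bsc$bsc)
  if (sum(sel) < 8) stopf("need at least 8 positive in-band BSC points")
  f <- bsc$freq_mhz[sel]
  k2 <- (2 * pi * f * 1e6 / sos)^2
  y <- log(bsc$bsc[sel]) - 4 * log(f)
  xm <- mean(k2); ym <- mean(y)
  slope <- sum((k2 - xm) * (y - ym)) / sum((k2 - xm)^2)
  icpt <- ym - slope * xm
  pinned <- FALSE
  if (slope < 0) {
    a_m <- sqrt(-slope / 0.827)
  } else {
    a_m <- esd_range_um[1] / 2 * 1e-6
    pinned <- TRUE
  }
  esd <- 2 * a_m * 1e6
  if (esd < esd_range_um[1]) { esd <- esd_range_um[1]; pinned <- TRUE }
  if (esd > esd_range_um[2]) { esd <- esd_range_um[2]; pinned <- TRUE }
  resid <- y - (icpt + slope * k2)
  structure(list(esd_um = esd, eac_db = 10 * icpt / log(10),
                 fit_residual_db = sqrt(mean(resid^2)) * 10 / log(10),
                 pinned = pinned),
            class = "qus_scatterer_fit")
}

#' @export
print.qus_scatterer_fit <- function(x, ...) {
  cat(sprintf("ESD %.1f um, EAC %.1f dB/cm^3 (residual %.2f dB%s)\n",
              x$esd_um, x$eac_db, x$fit_residual_db,
              if (x$pinned) ", pinned" else ""))
  invisible(x)
}

# ---- autoregressive spectra -------------------------------------------------

# Burg AR coefficients per column; wraps the compiled recursion and reduces
# the order on numerically singular segments.
burg_ar <- function(x, order) {
  out <- burg_columns(x, as.integer(order))
  bad <- !apply(is.finite(out), 2, all)
  if (any(bad)) {
    warnf("Burg recursion singular on %d segment(s); order reduced", sum(bad))
    red <- burg_columns(x[, bad, drop = FALSE], as.integer(max(1, order %/% 2)))
    out[, bad] <- 0
    out[seq_len(nrow(red) - 1), bad] <- red[seq_len(nrow(red) - 1), ]
    out[nrow(out), bad] <- red[nrow(red), ]
  }
  out
}

# AR power spectral density at the given DFT bins of an nfft-point grid
ar_psd <- function(ar, freq_bins, nfft) {
  order <- nrow(ar) - 1
  w <- 2 * pi * freq_bins / nfft
  E <- exp(-1i * outer(w, seq_len(order)))
  D <- E %*% ar[seq_len(order), , drop = FALSE] + 1
  sweep(1 / Mod(D)^2, 2, ar[order + 1, ], "*")
}

# same quantity evaluated for every column via FFT of the zero-padded AR
# polynomial (cheaper than the dense product when many bins are needed);
# processes columns in chunks to bound memory
ar_psd_fft <- function(ar, freq_bins, nfft, chunk = 2000L) {
  order <- nrow(ar) - 1
  m <- ncol(ar)
  out <- matrix(NA_real_, length(freq_bins), m)
  pad <- matrix(0, nfft, min(chunk, m))
  for (s in seq(1, m, by = chunk)) {
    j <- s:min(s + chunk - 1, m)
    A <- pad[, seq_along(j), drop = FALSE]
    A[1, ] <- 1
    A[2:(order + 1), ] <- ar[seq_len(order), j]
    D <- stats::mvfft(A)[freq_bins + 1L, , drop = FALSE]
    out[, j] <- sweep(1 / Mod(D)^2, 2, ar[order + 1, j], "*")
  }
  out
}

#' Burg autoregressive power spectrum of an RF block
#'
#' Fits an AR model per scan line with Burg's reflection-coefficient
#' recursion (after removing each line's mean) and averages the resulting
#' AR power spectral densities across lines.
#'
#' @param block A `qus_rf_block`.
#' @param order AR model order.
#' @param nfft Frequency-grid length.
#' @return A `qus_spectrum` of kind `"ar"`.
#' @export
burg_spectrum <- function(block, order = 10, nfft = 1024) {
  x <- block$samples
  if (order >= nrow(x)) stopf("AR order must be below the block length")
  xc <- sweep(x, 2, colMeans(x))
  ar <- burg_ar(xc, order)
  bins <- 0:(nfft %/% 2)
  psd <- rowMeans(ar_psd(ar, bins, nfft))
  new_spectrum(bins * block$sampling_rate / nfft, db(psd), "ar",
               block$depth_centre, block$sampling_rate, nrow(x), nfft,
               ncol(x))
}

# planar-reflector periodograms on the AR frequency grid, cached per
# reference set; one column per reflector depth
reflector_spectra <- function(refset, window_samples, nfft) {
  key <- sprintf("refl_%d_%d", window_samples, nfft)
  if (!is.null(refset$cache[[key]])) return(refset$cache[[key]])
  w <- hanning_window(window_samples)
  freq_bins <- 0:(nfft %/% 2)
  out <- vapply(refset$reflector_frames, function(fr) {
    line <- fr$samples[, 1]
    ctr <- which.max(abs(line))
    hs <- (window_samples - 1) %/% 2
    lo <- max(1, ctr - hs)
    seg <- line[lo:min(length(line), lo + window_samples - 1)]
    seg <- c(seg, numeric(window_samples - length(seg))) * w
    P <- Mod(stats::fft(c(seg, numeric(nfft - window_samples))))^2
    db(pmax(P[freq_bins + 1], .Machine$double.xmin))
  }, numeric(length(freq_bins)))
  res <- list(freq_mhz = freq_bins * refset$acq$sampling_rate / nfft,
              ref_db = out, depths_cm = refset$reflector_depths_cm)
  refset$cache[[key]] <- res
  res
}

# normalized autocorrelation of every column up to lag Lmax, via FFT
autocorr_columns <- function(V, Lmax) {
  nb <- nrow(V)
  nfft <- next_pow2(2 * nb)
  pad <- rbind(V, matrix(0, nfft - nb, ncol(V)))
  S <- Re(stats::mvfft(Mod(stats::mvfft(pad))^2, inverse = TRUE)) / nfft
  r <- S[2:(Lmax + 1), , drop = FALSE]
  sweep(r, 2, pmax(S[1, ], .Machine$double.xmin), "/")
}

# vectorized variant of sas_peak over the columns of a lag x window matrix;
# returns the interpolated peak lag (NA where no dominant peak)
sas_peaks_matrix <- function(rmat, lag_lo, lag_hi, prominence) {
  L <- nrow(rmat); m <- ncol(rmat)
  lo <- max(2L, as.integer(ceiling(lag_lo)))
  hi <- min(L - 1L, as.integer(floor(lag_hi)))
  out <- rep(NA_real_, m)
  if (hi < lo) return(out)
  cand <- matrix(-Inf, L, m)
  sel <- lo:hi
  is_max <- rmat[sel, , drop = FALSE] > rmat[sel - 1L, , drop = FALSE] &
    rmat[sel, , drop = FALSE] >= rmat[sel + 1L, , drop = FALSE]
  cand[sel, ][is_max] <- rmat[sel, , drop = FALSE][is_max]
  l1 <- max.col(t(cand), ties.method = "first")
  r1 <- cand[cbind(l1, seq_len(m))]
  cand[cbind(l1, seq_len(m))] <- -Inf
  r2 <- cand[cbind(max.col(t(cand), ties.method = "first"), seq_len(m))]
  prom <- r1 - pmax(r2, 0)
  ok <- is.finite(r1) & r1 >= prominence & prom >= prominence
  if (!any(ok)) return(out)
  j <- which(ok)
  rm1 <- rmat[cbind(l1[j] - 1L, j)]
  rp1 <- rmat[cbind(l1[j] + 1L, j)]
  r0 <- rmat[cbind(l1[j], j)]
  den <- rm1 - 2 * r0 + rp1
  delta <- ifelse(den < 0, 0.5 * (rm1 - rp1) / den, 0)
  out[j] <- l1[j] + delta
  out
}

# peak of the normalized spectral autocorrelation within a lag window, with
# parabolic sub-bin interpolation. The prominence of the best local maximum
# is its height above the runner-up local maximum (topographic dominance):
# windows whose autocorrelation shows several comparable peaks - the
# signature of random speckle pair-echo ripple rather than a lattice comb -
# are flagged missing instead of contributing an arbitrary mode.
sas_peak <- function(r, lag_lo, lag_hi, prominence) {
  L <- length(r)
  lo <- max(2, ceiling(lag_lo))
  hi <- min(L - 1, floor(lag_hi))
  if (hi < lo) return(c(NA_real_, NA_real_))
  cand <- lo:hi
  is_max <- r[cand] > r[cand - 1] & r[cand] >= r[cand + 1]
  cand <- cand[is_max]
  if (!length(cand)) return(c(NA_real_, NA_real_))
  o <- order(r[cand], decreasing = TRUE)
  l <- cand[o[1]]
  runner_up <- if (length(cand) > 1) max(r[cand[o[2]]], 0) else 0
  prom <- r[l] - runner_up
  if (r[l] < prominence || prom < prominence)
    return(c(NA_real_, NA_real_))
  denom <- r[l - 1] - 2 * r[l] + r[l + 1]
  delta <- if (denom < 0) 0.5 * (r[l - 1] - r[l + 1]) / denom else 0
  c(l + delta, prom)
}

# remove the residual spectral tilt (linear in frequency) so the
# autocorrelation background does not drag the comb peak toward small lags
detrend_linear <- function(f, v) {
  fc <- f - mean(f)
  v - mean(v) - fc * sum(fc * v) / sum(fc^2)
}

#' Scatterer spacing from the AR-spectrum autocorrelation
#'
#' Estimates the mean spacing of coherently, quasi-periodically arranged
#' scatterers: the block's Burg AR spectrum is normalized (in dB) to the
#' nearest-depth planar-reflector spectrum, the in-band normalized spectrum
#' is detrended (mean and linear tilt removed), and its autocorrelation
#' over frequency lag is searched for a peak; the peak lag `df*` maps to
#' spacing via `SAS = c / (2 df*)`. Windows with no peak above the
#' prominence floor return `NA` (excluded pixel).
#'
#' The AR model can only express a spectral comb whose underlying echo
#' delay (in samples) does not exceed the model order, so the default order
#' is three quarters of the block length rather than a small fixed value;
#' see the methods vignette.
#'
#' @param block A `qus_rf_block`.
#' @param refset Reference set with planar-reflector frames.
#' @param band Analysis band `c(lo, hi)`, MHz; spacing detection benefits
#'   from a wider band than the regression estimators use.
#' @param sas_range_mm Physical search range, mm.
#' @param prominence Minimum normalized autocorrelation peak height.
#' @param ar_order Burg AR order; `NULL` = 3/4 of the block length.
#' @param nfft Frequency-grid length for the AR spectra.
#' @return A `qus_sas` with `sas_mm`, `peak_prominence` and `ar_order`.
#' @export
estimate_sas <- function(block, refset, band, sas_range_mm = c(0.25, 3),
                         prominence = 0.1, ar_order = NULL, nfft = 1024) {
  ar_order <- ar_order %||% floor(0.75 * nrow(block$samples))
  ars <- burg_spectrum(block, order = ar_order, nfft = nfft)
  refl <- reflector_spectra(refset, nrow(block$samples), nfft)
  ri <- which.min(abs(refl$depths_cm - block$depth_centre))
  v <- ars$value_db - refl$ref_db[, ri]
  sel <- ars$freq_mhz >= band[1] & ars$freq_mhz <= band[2]
  v <- detrend_linear(ars$freq_mhz[sel], v[sel])
  ss <- sum(v^2)
  df <- block$sampling_rate / nfft
  c_mps <- block$speed_of_sound
  lag_of <- function(d_mm) c_mps / (2 * d_mm) / (1000 * df)
  n <- length(v)
  lags <- seq_len(n - 2)
  r <- vapply(lags, function(l) sum(v[1:(n - l)] * v[(1 + l):n]) / ss,
              numeric(1))
  pk <- sas_peak(r, lag_of(sas_range_mm[2]), lag_of(sas_range_mm[1]),
                 prominence)
  sas <- if (is.na(pk[1])) NA_real_ else c_mps / (2 * pk[1] * df) / 1000
  structure(list(sas_mm = sas, peak_prominence = pk[2], ar_order = ar_order),
            class = "qus_sas")
}

#' @export
print.qus_sas <- function(x, ...) {
  if (is.na(x$sas_mm)) cat("SAS: no autocorrelation peak above prominence floor\n")
  else cat(sprintf("SAS %.2f mm (prominence %.2f, AR order %d)\n",
                   x$sas_mm, x$peak_prominence, x$ar_order))
  invisible(x)
}
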