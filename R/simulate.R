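#' @useDynLib qusmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- scatterer fields -------------------------------------------------------

# Draw scatterer positions (mm) for a rectangular region. A fraction of the
# scatterers sits on a jittered axial lattice (shared phase within the
# region) that carries the coherent, quasi-periodic component the SAS
# estimator looks for; the rest are uniform (diffuse speckle).
draw_scatterers <- function(phantom, lat_range, z_range, lattice_jitter) {
  area <- diff(lat_range) * diff(z_range)               # mm^2 (1 mm slice)
  n_total <- round(phantom$number_density * area)
  if (n_total < 1) return(data.frame(x = numeric(), z = numeric()))
  n_per <- round(phantom$periodic_fraction * n_total)
  n_dif <- n_total - n_per
  x <- stats::runif(n_dif, lat_range[1], lat_range[2])
  z <- stats::runif(n_dif, z_range[1], z_range[2])
  if (n_per > 0) {
    d <- phantom$lattice_spacing
    phase <- stats::runif(1, 0, d)
    zk <- seq(z_range[1] + phase, z_range[2], by = d)
    if (length(zk)) {
      reps <- ceiling(n_per / length(zk))
      zp <- rep(zk, reps)[seq_len(n_per)] +
        stats::rnorm(n_per, 0, lattice_jitter * d)
      xp <- stats::runif(n_per, lat_range[1], lat_range[2])
      keep <- zp > z_range[1] & zp < z_range[2]
      x <- c(x, xp[keep]); z <- c(z, zp[keep])
    }
  }
  data.frame(x = x, z = z)
}

# Patchwise heterogeneity: multiplicative modulation of local impedance
# contrast (full strength) and scatterer radius (half strength) on a grid of
# patch_size-mm cells.
patch_multipliers <- function(pts, phantom, lat_range, z_range) {
  h <- phantom$heterogeneity
  n <- nrow(pts)
  if (h <= 0 || n == 0)
    return(list(w = rep(1, n), a = rep(1, n)))
  ps <- phantom$patch_size
  nx <- max(1L, ceiling(diff(lat_range) / ps))
  nz <- max(1L, ceiling(diff(z_range) / ps))
  zw <- matrix(stats::rnorm(nx * nz), nz, nx)
  za <- matrix(stats::rnorm(nx * nz), nz, nx)
  ix <- pmin(nx, 1L + floor((pts$x - lat_range[1]) / ps))
  iz <- pmin(nz, 1L + floor((pts$z - z_range[1]) / ps))
  idx <- cbind(iz, ix)
  list(w = pmax(0.1, 1 + h * zw[idx]),
       a = pmax(0.3, 1 + 0.5 * h * za[idx]))
}

# ---- per-scatterer response kernels ----------------------------------------

# Zero-phase impulse responses on the RF sample grid for each unique
# (scatterer radius, one-way path loss) class:
#   H(|f|) = pulse(|f|) * f_MHz^2 * sqrt(F(f; a)) * 10^(-L * |f| / 5)
# with the spherical Gaussian form factor F = exp(-0.827 k^2 a^2),
# k = 2 pi f / c_medium, and L = integral of alpha dz along the one-way
# path (dB/MHz). The kernel carries the full two-way response; the
# attenuation convention is 4 L f dB of round-trip power (2 alpha f z dB of
# amplitude per one-way path), matching the point-compensation and
# spectral-difference formulas the estimators use.
build_kernels <- function(acq, sos, a_um, L_db_mhz, half_width = 72,
                          nfft = 512) {
  fs <- acq$sampling_rate
  j <- 0:(nfft - 1)
  f <- ifelse(j <= nfft / 2, j, j - nfft) * fs / nfft   # signed MHz
  af <- abs(f)
  pulse <- pulse_spectrum_analytic(acq, af)
  k <- 2 * pi * af * 1e6 / sos                          # rad/m
  n_k <- length(a_um)
  H <- matrix(0, nfft, n_k)
  for (i in seq_len(n_k)) {
    ff <- exp(-0.827 * k^2 * (a_um[i] * 1e-6)^2)
    H[, i] <- pulse * af^2 * sqrt(ff) * 10^(-L_db_mhz[i] * af / 5)
  }
  h <- Re(stats::mvfft(H, inverse = TRUE)) / nfft       # real, even kernels
  idx <- c((nfft - half_width + 1):nfft, 1:(half_width + 1))
  kern <- h[idx, , drop = FALSE]
  # cosine edge taper suppresses truncation leakage, which would otherwise
  # put a broadband floor under strongly attenuated responses
  klen <- nrow(kern)
  edge <- 24
  tap <- rep(1, klen)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(edge) - 0.5) / edge))
  tap[seq_len(edge)] <- ramp
  tap[klen + 1 - seq_len(edge)] <- ramp
  kern <- kern * tap
  list(kernels = kern, centre = half_width)             # 0-based centre tap
}

# one-way path loss (dB/MHz) at depth z (mm) for an ambient medium with an
# optional elliptical lesion inclusion of different attenuation
path_loss_db_mhz <- function(x, z, alpha_bg, lesion_alpha = NULL,
                             geom = NULL) {
  L <- alpha_bg * z / 10                                # z mm -> cm
  if (is.null(geom)) return(L)
  u <- (x - geom$cx_mm) / geom$ax_mm
  inside_col <- abs(u) < 1
  if (!any(inside_col)) return(L)
  hz <- geom$az_mm * sqrt(pmax(0, 1 - u^2))
  z_in <- geom$cz_mm - hz
  z_out <- geom$cz_mm + hz
  chord <- pmin(pmax(z - z_in, 0), z_out - z_in)        # path inside lesion
  L + inside_col * (lesion_alpha - alpha_bg) * chord / 10
}

# ---- frame simulation -------------------------------------------------------

#' Simulate one beamformed RF frame
#'
#' Point-scatterer forward model: every scatterer contributes the transmit
#' pulse filtered by its frequency response (`f^2 sqrt(F(f))` with a
#' spherical Gaussian form factor, so the ensemble backscatter coefficient is
#' proportional to `f^4 F(f)`) and by two-way frequency-dependent path
#' attenuation, delayed by its two-way travel time and weighted by a Gaussian
#' lateral beam profile. An optional elliptical lesion inclusion uses its own
#' scattering medium, with patchwise intra-lesion heterogeneity.
#'
#' @param phantom Ambient [phantom_spec()].
#' @param acq [acquisition_spec()].
#' @param seed Integer seed; identical inputs give bit-identical frames.
#' @param lesion Optional [phantom_spec()] for an elliptical inclusion.
#' @param lesion_geom Optional list `(cx_mm, cz_mm, ax_mm, az_mm)` placing
#'   the inclusion (centre and semi-axes, mm).
#' @param plane_offset Elevational plane position, mm (metadata only).
#' @param lattice_jitter Axial lattice jitter as a fraction of the lattice
#'   pitch.
#' @return An object of class `qus_rf_frame`: `samples` (axial x lines),
#'   the acquisition, and simulation provenance.
#' @export
simulate_frame <- function(phantom, acq, seed = 1L, lesion = NULL,
                           lesion_geom = NULL, plane_offset = 0,
                           lattice_jitter = 0.05) {
  validate_acquisition(acq)
  if (!is.null(lesion) && is.null(lesion_geom))
    stopf("lesion_geom is required when a lesion medium is given")
  if (!is.null(lesion_geom)) {
    if (lesion_geom$cx_mm + lesion_geom$ax_mm > acq$lateral_fov * 10 ||
        lesion_geom$cx_mm - lesion_geom$ax_mm < 0 ||
        lesion_geom$cz_mm + lesion_geom$az_mm > acq$depth * 10 ||
        lesion_geom$cz_mm - lesion_geom$az_mm < 0)
      stopf("lesion does not fit inside the imaged field of view")
  }
  set.seed(seed)
  n_ax <- n_axial_samples(acq)
  lp <- line_pitch_mm(acq)
  sos <- phantom$speed_of_sound
  lat_range <- c(-2, acq$lateral_fov * 10 + 2)
  z_range <- c(0.5, acq$depth * 10 + 1)

  bg <- draw_scatterers(phantom, lat_range, z_range, lattice_jitter)
  mult_bg <- patch_multipliers(bg, phantom, lat_range, z_range)
  a_um <- phantom$scatterer_radius_mean * mult_bg$a *
    pmax(0.2, 1 + phantom$radius_cv * stats::rnorm(nrow(bg)))
  w <- phantom$impedance_contrast * mult_bg$w
  alpha_les <- NULL
  if (!is.null(lesion)) {
    g <- lesion_geom
    u2 <- ((bg$x - g$cx_mm) / g$ax_mm)^2 + ((bg$z - g$cz_mm) / g$az_mm)^2
    keep <- u2 > 1
    bg <- bg[keep, ]; a_um <- a_um[keep]; w <- w[keep]
    les_lat <- c(g$cx_mm - g$ax_mm, g$cx_mm + g$ax_mm)
    les_z <- c(g$cz_mm - g$az_mm, g$cz_mm + g$az_mm)
    ls <- draw_scatterers(lesion, les_lat, les_z, lattice_jitter)
    ins <- ((ls$x - g$cx_mm) / g$ax_mm)^2 + ((ls$z - g$cz_mm) / g$az_mm)^2 <= 1
    ls <- ls[ins, ]
    mult_ls <- patch_multipliers(ls, lesion, les_lat, les_z)
    a_ls <- lesion$scatterer_radius_mean * mult_ls$a *
      pmax(0.2, 1 + lesion$radius_cv * stats::rnorm(nrow(ls)))
    w_ls <- lesion$impedance_contrast * mult_ls$w
    bg <- rbind(bg, ls)
    a_um <- c(a_um, a_ls)
    w <- c(w, w_ls)
    alpha_les <- lesion$attenuation_coeff
  }

  empty <- nrow(bg) == 0
  if (empty) {
    warnf("scattering medium is empty; returning a silent frame")
    samples <- matrix(0, n_ax, acq$num_lines)
  } else {
    L <- path_loss_db_mhz(bg$x, bg$z, phantom$attenuation_coeff,
                          alpha_les, lesion_geom)
    # quantize kernel classes: 1 um in radius, 0.02 dB/MHz in path loss
    a_q <- round(a_um)
    L_q <- round(L / 0.02) * 0.02
    key <- paste(a_q, L_q)
    uk <- !duplicated(key)
    kid <- match(key, key[uk])
    kern <- build_kernels(acq, sos, a_q[uk], L_q[uk])
    t_us <- 2 * bg$z / (sos * 1e-3)                     # two-way, us
    pos_samp <- t_us * acq$sampling_rate
    line_pos <- bg$x / lp - 0.5                         # line centres
    sigma_lines <- (acq$beam_width / 2.355) / lp
    samples <- rf_synth(n_ax, acq$num_lines, pos_samp, line_pos, w,
                        as.integer(kid), kern$kernels, kern$centre,
                        sigma_lines, as.integer(ceiling(3 * sigma_lines)))
  }

  structure(list(
    samples = samples, acq = acq, plane_offset = plane_offset,
    medium = phantom, lesion = lesion, lesion_geom = lesion_geom,
    seed = seed, empty = empty
  ), class = "qus_rf_frame")
}

#' @export
print.qus_rf_frame <- function(x, ...) {
  cat(sprintf("RF frame: %d samples x %d lines (%.1f x %.1f cm), plane %+.1f mm\n",
              nrow(x$samples), ncol(x$samples), x$acq$depth,
              x$acq$lateral_fov, x$plane_offset))
  invisible(x)
}

# ---- reference set ----------------------------------------------------------

#' Simulate reference-phantom and planar-reflector acquisitions
#'
#' Produces the normalization references the estimators need: frames from a
#' homogeneous tissue-mimicking phantom of known attenuation, speed of sound
#' and backscatter coefficient (used for reference-phantom normalization of
#' window spectra, attenuation estimation and BSC estimation), and planar
#' reflector echoes recorded at a set of depths (used to normalize the
#' autoregressive spectra feeding the scatterer-spacing estimator). The
#' default phantom mirrors a glass-bead reference medium with attenuation
#' 0.576 dB/MHz/cm and speed of sound 1488 m/s.
#'
#' @param acq [acquisition_spec()]; must match the sample frames.
#' @param phantom_attenuation Phantom attenuation, dB/MHz/cm.
#' @param phantom_sos Phantom speed of sound, m/s.
#' @param seed Integer seed.
#' @param n_phantom_frames Number of independent phantom frames averaged
#'   into the reference spectra.
#' @param reflector_depths_cm Depths (cm) of the planar-reflector records.
#' @param bead_radius_um Mean glass-bead radius of the phantom, micrometres.
#' @return An object of class `qus_reference_set` with the phantom frames, a
#'   tabulated phantom BSC model, and the reflector frames.
#' @export
simulate_reference_set <- function(acq, phantom_attenuation = 0.576,
                                   phantom_sos = 1488, seed = 1L,
                                   n_phantom_frames = 4,
                                   reflector_depths_cm = seq(0.5, 3.5, 0.5),
                                   bead_radius_um = 10) {
  if (phantom_attenuation <= 0) stopf("phantom attenuation must be positive")
  if (any(reflector_depths_cm <= 0)) stopf("reflector depths must be positive")
  ph <- phantom_spec(scatterer_radius_mean = bead_radius_um, radius_cv = 0.3,
                     number_density = 30, impedance_contrast = 1,
                     periodic_fraction = 0, heterogeneity = 0,
                     attenuation_coeff = phantom_attenuation,
                     speed_of_sound = phantom_sos)
  frames <- lapply(seq_len(n_phantom_frames), function(i)
    simulate_frame(ph, acq, seed = derive_seed(seed, i)))

  # ensemble BSC of the phantom in the estimator's convention:
  # density * contrast^2 * f^4 * E_a[F(f; a)], tabulated vs frequency
  f <- seq(0.05, acq$sampling_rate / 2, by = 0.05)
  a_grid <- bead_radius_um * pmax(0.2, 1 + ph$radius_cv *
                                    stats::qnorm(seq(0.01, 0.99, 0.02)))
  k <- 2 * pi * f * 1e6 / phantom_sos
  Fbar <- rowMeans(exp(-0.827 * outer(k^2, (a_grid * 1e-6)^2)))
  bsc <- ph$number_density * ph$impedance_contrast^2 * f^4 * Fbar

  pulse <- make_pulse(acq)
  n_ax <- n_axial_samples(acq)
  reflectors <- lapply(reflector_depths_cm, function(zc) {
    t_us <- 2 * (zc * 10) / (phantom_sos * 1e-3)
    centre <- t_us * acq$sampling_rate
    line <- numeric(n_ax)
    idx <- round(centre) + seq_along(pulse$waveform) -
      (which.max(abs(pulse$waveform)))
    ok <- idx >= 1 & idx <= n_ax
    line[idx[ok]] <- pulse$waveform[ok]
    structure(list(samples = matrix(line, n_ax, acq$num_lines),
                   acq = acq, plane_offset = 0, medium = NULL,
                   seed = seed, empty = FALSE, depth_cm = zc),
              class = "qus_rf_frame")
  })

  structure(list(
    acq = acq, phantom_frames = frames, phantom_spec = ph,
    phantom_attenuation = phantom_attenuation, phantom_sos = phantom_sos,
    bsc_model = data.frame(freq_mhz = f, bsc = bsc),
    reflector_depths_cm = reflector_depths_cm,
    reflector_frames = reflectors,
    cache = new.env(parent = emptyenv())
  ), class = "qus_reference_set")
}

#' @export
print.qus_reference_set <- function(x, ...) {
  cat(sprintf(
    "Reference set: %d phantom frames (%.3f dB/MHz/cm, %d m/s), reflectors at %s cm\n",
    length(x$phantom_frames), x$phantom_attenuation, round(x$phantom_sos),
    paste(x$reflector_depths_cm, collapse = ", ")))
  invisible(x)
}

# ---- cohort -----------------------------------------------------------------

draw_class_phantom <- function(class_spec) {
  m <- class_spec$mean
  draw <- unclass(m)
  lo <- list(scatterer_radius_mean = 15, radius_cv = 0, number_density = 1,
             periodic_fraction = 0, lattice_spacing = 0.3,
             attenuation_coeff = 0.05, heterogeneity = 0, patch_size = 0.5)
  hi <- list(periodic_fraction = 1, attenuation_coeff = 3)
  for (field in names(class_spec$sd)) {
    if (field == "impedance_contrast") {
      # positive scale parameter: log-normal, so the acoustic concentration
      # (proportional to 20 log10 contrast) is normal in dB between patients
      draw[[field]] <- m[[field]] *
        exp(stats::rnorm(1, 0, class_spec$sd[[field]] / m[[field]]))
    } else {
      draw[[field]] <- rnorm_trunc(1, m[[field]], class_spec$sd[[field]],
                                   lo[[field]] %||% -Inf, hi[[field]] %||% Inf)
    }
  }
  do.call(phantom_spec, draw[names(formals(phantom_spec))])
}

#' Simulate one patient of a synthetic cohort
#'
#' Draws patient-level tissue parameters from the class distribution, a
#' lesion diameter, and simulates the plane stack crossing the (spherical)
#' lesion; planes whose in-plane lesion cross-section is smaller than one
#' analysis window are dropped.
#'
#' @param spec A [cohort_spec()].
#' @param index Patient index within the cohort (1-based, benign patients
#'   first); fixes the patient's deterministic random substream.
#' @param seed Cohort root seed.
#' @return A list with `patient_id`, `label`, `truth` (sampled parameters),
#'   `frames`, and per-frame `lesion_geom`.
#' @export
simulate_patient <- function(spec, index, seed = 1L) {
  label <- if (index <= spec$n_benign) "benign" else "malignant"
  cls <- if (label == "benign") spec$benign else spec$malignant
  pseed <- derive_seed(seed, index)
  set.seed(pseed)
  lesion <- draw_class_phantom(cls)
  diam_cm <- rnorm_trunc(1, spec$lesion_diameter_cm_mean,
                         spec$lesion_diameter_cm_sd, lo = 0.6, hi = 2.8)
  r_mm <- diam_cm * 10 / 2
  acq <- spec$acq
  cx <- acq$lateral_fov * 10 / 2 + stats::runif(1, -3, 3)
  cz <- acq$depth * 10 / 2
  offs <- (seq_len(spec$planes_per_patient) -
             (spec$planes_per_patient + 1) / 2) * spec$plane_spacing_mm
  frames <- list(); geoms <- list()
  for (p in seq_along(offs)) {
    if (abs(offs[p]) >= r_mm) next
    r_p <- r_mm * sqrt(1 - (offs[p] / r_mm)^2)
    if (r_p < 2.2) next                                 # below one window
    geom <- list(cx_mm = cx, cz_mm = cz, ax_mm = r_p, az_mm = r_p)
    fr <- simulate_frame(spec$background, acq,
                         seed = derive_seed(pseed, p),
                         lesion = lesion, lesion_geom = geom,
                         plane_offset = offs[p])
    frames[[length(frames) + 1]] <- fr
    geoms[[length(geoms) + 1]] <- geom
  }
  truth <- data.frame(patient_id = sprintf("P%03d", index), label = label,
                      lesion_diameter_cm = diam_cm,
                      eac_db = true_eac_db(lesion),
                      as.data.frame(unclass(lesion)[
                        c("scatterer_radius_mean", "number_density",
                          "impedance_contrast", "periodic_fraction",
                          "lattice_spacing", "attenuation_coeff",
                          "heterogeneity")]))
  list(patient_id = sprintf("P%03d", index), label = label, truth = truth,
       frames = frames, lesion_geoms = geoms, seed = pseed)
}

#' Generate a synthetic two-class cohort
#'
#' Materializes every patient of a [cohort_spec()] in memory (intended for
#' small cohorts; the pipeline streams patients instead). Fully reproducible
#' under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Cohort root seed.
#' @return An object of class `qus_cohort`: `patients` (see
#'   [simulate_patient()]) and a `ground_truth` table with one row per
#'   patient.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  n <- spec$n_benign + spec$n_malignant
  patients <- lapply(seq_len(n), function(i) simulate_patient(spec, i, seed))
  truth <- do.call(rbind, lapply(patients, `[[`, "truth"))
  structure(list(patients = patients, ground_truth = truth, spec = spec,
                 seed = seed), class = "qus_cohort")
}

#' @export
print.qus_cohort <- function(x, ...) {
  nf <- sum(vapply(x$patients, function(p) length(p$frames), integer(1)))
  cat(sprintf("Synthetic cohort: %d patients (%s), %d RF frames\n",
              length(x$patients),
              paste(table(x$ground_truth$label), collapse = " / "), nf))
  invisible(x)
}

# elliptical lesion ROI mask on the RF sample grid
#' ROI mask for an elliptical lesion
#'
#' @param acq [acquisition_spec()].
#' @param geom Lesion geometry list `(cx_mm, cz_mm, ax_mm, az_mm)`.
#' @return Logical matrix aligned to the frame sample grid.
#' @export
roi_mask <- function(acq, geom) {
  n_ax <- n_axial_samples(acq)
  z <- (seq_len(n_ax) - 0.5) * sample_pitch_mm(acq)
  x <- (seq_len(acq$num_lines) - 0.5) * line_pitch_mm(acq)
  outer(((z - geom$cz_mm) / geom$az_mm)^2,
        ((x - geom$cx_mm) / geom$ax_mm)^2, "+") <= 1
}
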