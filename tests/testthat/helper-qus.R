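# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_acq <- function() fixture("acq", acquisition_spec())

# reference set shared by estimator tests (cache of reference spectra warms
# up once)
shared_refset <- function() fixture("refset", {
  simulate_reference_set(default_acq(), seed = 11)
})

# big central ROI for single-frame estimator recovery
central_roi <- function(acq = default_acq()) fixture("roi", {
  m <- matrix(FALSE, n_axial_samples(acq), acq$num_lines)
  m[400:1700, 80:430] <- TRUE
  m
})

# coarse-overlap config for fast map builds in unit tests
fast_config <- function() qus_config(overlap = 0.5)

# homogeneous test media
homogeneous_phantom <- function(a_um = 50, eac_db = 36, alpha = 1.0,
                                pf = 0, lattice = 1.0) {
  phantom_spec(scatterer_radius_mean = a_um, radius_cv = 0,
               number_density = 30,
               impedance_contrast = contrast_for_eac(eac_db, 30),
               periodic_fraction = pf, lattice_spacing = lattice,
               attenuation_coeff = alpha, heterogeneity = 0)
}

# envelope of an RF line via the analytic signal
rf_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# brute-force GLCM feature oracle: explicit loop over all pixel pairs
oracle_glcm_features <- function(map, n_levels, distance, angle) {
  valid <- is.finite(map)
  rng <- range(map[valid])
  q <- matrix(NA_integer_, nrow(map), ncol(map))
  q[valid] <- if (rng[1] == rng[2]) 1L else
    pmin(1L + as.integer(floor((map[valid] - rng[1]) / diff(rng) * n_levels)),
         n_levels)
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  counts <- matrix(0, n_levels, n_levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
    if (is.na(q[i, j]) || is.na(q[i2, j2])) next
    counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
  }
  counts <- counts + t(counts)
  if (sum(counts) == 0) return(NULL)
  p <- counts / sum(counts)
  lev <- seq_len(n_levels)
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj)
  s_i <- sqrt(sum((lev - mu_i)^2 * pi_)); s_j <- sqrt(sum((lev - mu_j)^2 * pj))
  im <- matrix(lev, n_levels, n_levels); jm <- t(im)
  c(contrast = sum(abs(im - jm)^2 * p),
    correlation = if (s_i > 0 && s_j > 0)
      sum((im - mu_i) * (jm - mu_j) * p) / (s_i * s_j) else NA_real_,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(im - jm))))
}
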