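# Internal helpers shared across modules.

# axial sample pitch in mm: c / (2 fs)
sample_pitch_mm <- function(acq) {
  (acq$speed_of_sound * 1e3) / (2 * acq$sampling_rate * 1e6)
}

line_pitch_mm <- function(acq) {
  acq$lateral_fov * 10 / acq$num_lines
}

n_axial_samples <- function(acq) {
  round(acq$depth * 10 / sample_pitch_mm(acq))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

hanning_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

db <- function(x) 10 * log10(x)

# positive-frequency grid (MHz) of an n-point DFT at fs (MHz)
half_freq_grid <- function(nfft, fs) (0:(nfft %/% 2)) * fs / nfft

# deterministic per-unit substream seed below 2^31, so patient subsets
# reproduce independently of cohort ordering
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 1) %%
               2147483629)
}

# truncated-normal draw used for patient-level tissue parameters
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
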