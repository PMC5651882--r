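#' Ultrasound acquisition settings
#'
#' Describes a linear-array acquisition: centre frequency, sampling rate,
#' scan-line geometry and the pulse model used by the simulator. Defaults
#' emulate a clinical breast scan with a ~6 MHz linear probe sampled at
#' 40 MHz, 512 scan lines over a 6 cm lateral field of view and 4 cm
#' imaging depth.
#'
#' @param centre_frequency Pulse centre frequency, MHz.
#' @param sampling_rate RF sampling rate, MHz. Must exceed twice the upper
#'   band edge `centre_frequency * (1 + pulse_bandwidth_frac)`.
#' @param num_lines Number of lateral scan lines.
#' @param lateral_fov Lateral field of view, cm.
#' @param depth Imaging depth, cm.
#' @param speed_of_sound Assumed tissue speed of sound, m/s.
#' @param pulse_bandwidth_frac Fractional -6 dB (two-sided) bandwidth of the
#'   transmit pulse, dimensionless.
#' @param beam_width Lateral -6 dB beam width, mm (Gaussian beam profile).
#'
#' @return An object of class `qus_acquisition`.
#' @export
acquisition_spec <- function(centre_frequency = 6,
                             sampling_rate = 40,
                             num_lines = 512,
                             lateral_fov = 6,
                             depth = 4,
                             speed_of_sound = 1540,
                             pulse_bandwidth_frac = 0.6,
                             beam_width = 1.0) {
  acq <- structure(list(
    centre_frequency = centre_frequency,
    sampling_rate = sampling_rate,
    num_lines = as.integer(num_lines),
    lateral_fov = lateral_fov,
    depth = depth,
    speed_of_sound = speed_of_sound,
    pulse_bandwidth_frac = pulse_bandwidth_frac,
    beam_width = beam_width
  ), class = "qus_acquisition")
  validate_acquisition(acq)
  acq
}

validate_acquisition <- function(acq) {
  if (acq$num_lines < 2) stopf("acquisition needs at least 2 scan lines")
  if (acq$depth <= 0) stopf("imaging depth must be positive")
  f_hi <- acq$centre_frequency * (1 + acq$pulse_bandwidth_frac)
  if (acq$sampling_rate <= 2 * f_hi) {
    stopf(paste0(
      "sampling rate %.1f MHz violates Nyquist for the pulse band ",
      "(upper edge %.1f MHz needs > %.1f MHz)"),
      acq$sampling_rate, f_hi, 2 * f_hi)
  }
  invisible(acq)
}

#' @export
print.qus_acquisition <- function(x, ...) {
  cat(sprintf(
    "Acquisition: %.1f MHz centre, %.0f MHz sampling, %d lines / %.1f cm, %.1f cm depth\n",
    x$centre_frequency, x$sampling_rate, x$num_lines, x$lateral_fov, x$depth))
  cat(sprintf("  c = %.0f m/s, fractional -6 dB bandwidth %.2f, beam %.1f mm\n",
              x$speed_of_sound, x$pulse_bandwidth_frac, x$beam_width))
  invisible(x)
}

# Gaussian spectral envelope parameters: the -6 dB two-sided width equals
# pulse_bandwidth_frac * fc, so sigma_f = width / (2 * sqrt(2 ln 10^(0.3)))
pulse_sigma_f <- function(acq) {
  acq$pulse_bandwidth_frac * acq$centre_frequency / (2 * sqrt(2 * log(10^0.3)))
}

#' Transmit pulse waveform and spectrum
#'
#' Builds the Gaussian-modulated sinusoid implied by an acquisition spec,
#' sampled at its RF rate, with unit peak amplitude, together with its
#' one-sided amplitude spectrum.
#'
#' @param acq An [acquisition_spec()].
#' @param nfft Transform length for the returned spectrum.
#' @return A list with `t_us` (time, microseconds, centred on the pulse
#'   peak), `waveform`, `freq_mhz`, `amplitude` (linear, unit peak), and the
#'   measured -6 dB `band` (MHz).
#' @export
make_pulse <- function(acq, nfft = 1024) {
  validate_acquisition(acq)
  sigma_f <- pulse_sigma_f(acq)         # MHz
  sigma_t <- 1 / (2 * pi * sigma_f)     # microseconds
  fs <- acq$sampling_rate
  half <- ceiling(4.5 * sigma_t * fs)
  t_us <- (-half:half) / fs
  waveform <- exp(-t_us^2 / (2 * sigma_t^2)) *
    cos(2 * pi * acq$centre_frequency * t_us)
  waveform <- waveform / max(abs(waveform))

  spec <- abs(stats::fft(c(waveform, numeric(nfft - length(waveform)))))
  freq <- half_freq_grid(nfft, fs)
  amp <- spec[seq_along(freq)]
  amp <- amp / max(amp)
  above <- freq[amp >= 10^(-6 / 20)]
  list(t_us = t_us, waveform = waveform, freq_mhz = freq, amplitude = amp,
       band = range(above), sigma_f_mhz = sigma_f, sigma_t_us = sigma_t)
}

# analytic pulse amplitude spectrum (positive frequencies, MHz)
pulse_spectrum_analytic <- function(acq, f_mhz) {
  sigma_f <- pulse_sigma_f(acq)
  exp(-(f_mhz - acq$centre_frequency)^2 / (2 * sigma_f^2)) +
    exp(-(f_mhz + acq$centre_frequency)^2 / (2 * sigma_f^2))
}

# default analysis band: the -6 dB band of the pulse
default_band <- function(acq) {
  acq$centre_frequency * c(1 - acq$pulse_bandwidth_frac / 2,
                           1 + acq$pulse_bandwidth_frac / 2)
}
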