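# RF container I/O: flat binary sample block with a JSON sidecar.

#' Write / read an RF frame container
#'
#' Samples are stored as little-endian float64, axial-major (column by scan
#' line), beside a JSON sidecar carrying the acquisition metadata
#' (`sampling_rate_hz`, `line_pitch_m`, `c_mps`, `centre_frequency_hz`,
#' `plane_offset_mm`, array shape). Unknown sidecar keys are preserved on
#' read with a warning; missing required keys and truncated sample files are
#' errors.
#'
#' @param frame A `qus_rf_frame`.
#' @param path Path of the binary container; the sidecar is `path` +
#'   `".json"`.
#' @return `write_rf_frame` returns `path` invisibly; `read_rf_frame`
#'   returns a `qus_rf_frame`.
#' @export
write_rf_frame <- function(frame, path) {
  acq <- frame$acq
  sidecar <- list(
    n_axial = nrow(frame$samples),
    n_lines = ncol(frame$samples),
    sampling_rate_hz = acq$sampling_rate * 1e6,
    line_pitch_m = line_pitch_mm(acq) * 1e-3,
    c_mps = acq$speed_of_sound,
    centre_frequency_hz = acq$centre_frequency * 1e6,
    lateral_fov_cm = acq$lateral_fov,
    depth_cm = acq$depth,
    pulse_bandwidth_frac = acq$pulse_bandwidth_frac,
    beam_width_mm = acq$beam_width,
    plane_offset_mm = frame$plane_offset
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(frame$samples), con, size = 8, endian = "little")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rf_frame
#' @export
read_rf_frame <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stopf("missing sidecar %s", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required <- c("n_axial", "n_lines", "sampling_rate_hz", "line_pitch_m",
                "c_mps", "centre_frequency_hz")
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stopf("sidecar is missing required field(s): %s",
          paste(miss, collapse = ", "))
  known <- c(required, "lateral_fov_cm", "depth_cm", "pulse_bandwidth_frac",
             "beam_width_mm", "plane_offset_mm")
  extra <- setdiff(names(meta), known)
  if (length(extra))
    warnf("sidecar has unknown key(s), preserved: %s",
          paste(extra, collapse = ", "))
  expected <- as.numeric(meta$n_axial) * as.numeric(meta$n_lines)
  actual <- file.info(path)$size
  if (actual != expected * 8)
    stopf("truncated or corrupt container: expected %d bytes, found %d (offset %d)",
          expected * 8, actual, actual)
  con <- file(path, "rb")
  on.exit(close(con))
  samples <- matrix(readBin(con, "double", n = expected, size = 8,
                            endian = "little"),
                    meta$n_axial, meta$n_lines)
  acq <- acquisition_spec(
    centre_frequency = meta$centre_frequency_hz / 1e6,
    sampling_rate = meta$sampling_rate_hz / 1e6,
    num_lines = meta$n_lines,
    lateral_fov = meta$lateral_fov_cm %||%
      (meta$line_pitch_m * 1e3 * meta$n_lines / 10),
    depth = meta$depth_cm %||%
      (meta$n_axial * meta$c_mps / (2 * meta$sampling_rate_hz) * 100),
    speed_of_sound = meta$c_mps,
    pulse_bandwidth_frac = meta$pulse_bandwidth_frac %||% 0.6,
    beam_width = meta$beam_width_mm %||% 1.0)
  structure(list(samples = samples, acq = acq,
                 plane_offset = meta$plane_offset_mm %||% 0,
                 medium = NULL, seed = NA_integer_, empty = FALSE,
                 sidecar_extra = if (length(extra)) meta[extra] else NULL),
            class = "qus_rf_frame")
}

#' Write a simulated cohort to disk
#'
#' One RF container (+ JSON sidecar) per frame, run-length-encoded ROI masks
#' as JSON, `manifest.csv` (patient_id, class, frame_path, roi_path) and
#' `ground_truth.csv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (pat in cohort$patients) {
    for (p in seq_along(pat$frames)) {
      fr <- pat$frames[[p]]
      base <- sprintf("%s_plane%02d", pat$patient_id, p)
      fpath <- file.path(dir, paste0(base, ".rf"))
      rpath <- file.path(dir, paste0(base, "_roi.json"))
      write_rf_frame(fr, fpath)
      mask <- roi_mask(fr$acq, pat$lesion_geoms[[p]])
      write_roi_rle(mask, rpath)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pat$patient_id, class = pat$label,
        frame_path = basename(fpath), roi_path = basename(rpath))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# run-length encoding of a logical mask (column-major), as JSON
write_roi_rle <- function(mask, path) {
  r <- rle(as.vector(mask))
  jsonlite::write_json(list(n_axial = nrow(mask), n_lines = ncol(mask),
                            lengths = r$lengths, values = r$values),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @param path Path of a run-length ROI JSON file.
#' @export
read_roi_rle <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  matrix(inverse.rle(structure(list(lengths = m$lengths,
                                    values = as.logical(m$values)),
                               class = "rle")),
         m$n_axial, m$n_lines)
}
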