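# Gray-level co-occurrence texture features of parametric maps.

#' Quantize a parametric map to discrete gray levels
#'
#' Linear min-max scaling of the map's own valid range into `n_levels`
#' levels: `level = 1 + floor((v - min) / (max - min) * n_levels)`, with the
#' maximum clamped to `n_levels`. Missing pixels stay missing; a constant map
#' quantizes to level 1 everywhere.
#'
#' @param map Numeric matrix (NA = missing).
#' @param n_levels Number of gray levels.
#' @return A `qus_quantized` integer matrix with attribute `n_levels`.
#' @export
quantize_map <- function(map, n_levels = 16) {
  valid <- is.finite(map)
  if (!any(valid)) stopf("map has no valid pixels to quantize")
  rng <- range(map[valid])
  q <- matrix(NA_integer_, nrow(map), ncol(map))
  if (rng[1] == rng[2]) {
    q[valid] <- 1L
  } else {
    lv <- 1L + as.integer(floor((map[valid] - rng[1]) / diff(rng) * n_levels))
    q[valid] <- pmin(lv, as.integer(n_levels))
  }
  structure(q, n_levels = as.integer(n_levels), class = "qus_quantized")
}

glcm_offset <- function(distance, angle) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stopf("angle must be one of 0, 45, 90, 135 degrees"))
}

#' Symmetric gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized levels at a fixed pixel displacement
#' (`distance` pixels along one of the four standard directions; 0 degrees is
#' the lateral neighbour, 90 degrees the axial one), over all pixel pairs
#' where both members are valid; the matrix is symmetrized with its transpose
#' and normalized to probabilities. Pairs touching missing pixels are
#' excluded.
#'
#' @param qmap A [quantize_map()] result.
#' @param distance Inter-pixel distance, pixels.
#' @param angle Direction, degrees (0, 45, 90, 135).
#' @return A `qus_glcm`: probability matrix `p`, `pair_count`, marginal
#'   moments, and the (distance, angle) it was computed for.
#' @export
glcm <- function(qmap, distance = 1, angle = 0) {
  if (!distance %in% 1:5) stopf("distance must be in 1..5 pixels")
  ng <- attr(qmap, "n_levels")
  off <- glcm_offset(as.integer(distance), angle)
  nr <- nrow(qmap); nc <- ncol(qmap)
  r_lo <- max(1L, 1L - off[1]); r_hi <- min(nr, nr - off[1])
  c_lo <- max(1L, 1L - off[2]); c_hi <- min(nc, nc - off[2])
  if (r_lo > r_hi || c_lo > c_hi) return(empty_glcm(ng, distance, angle))
  r1 <- r_lo:r_hi
  c1 <- c_lo:c_hi
  a <- unclass(qmap)[r1, c1, drop = FALSE]
  b <- unclass(qmap)[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(empty_glcm(ng, distance, angle))
  counts <- matrix(tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng),
                   ng, ng, byrow = TRUE)
  counts <- counts + t(counts)
  new_glcm(counts, distance, angle)
}

empty_glcm <- function(ng, distance, angle) {
  structure(list(p = matrix(0, ng, ng), distance = distance, angle = angle,
                 pair_count = 0L, mu_i = NA_real_, mu_j = NA_real_,
                 sigma_i = NA_real_, sigma_j = NA_real_, empty = TRUE),
            class = "qus_glcm")
}

new_glcm <- function(counts, distance, angle) {
  ng <- nrow(counts)
  total <- sum(counts)
  p <- counts / total
  i <- seq_len(ng)
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(i * pi_); mu_j <- sum(i * pj)
  structure(list(p = p, distance = distance, angle = angle,
                 pair_count = as.integer(total),
                 mu_i = mu_i, mu_j = mu_j,
                 sigma_i = sqrt(sum((i - mu_i)^2 * pi_)),
                 sigma_j = sqrt(sum((i - mu_j)^2 * pj)),
                 empty = FALSE),
            class = "qus_glcm")
}

#' @export
print.qus_glcm <- function(x, ...) {
  cat(sprintf("GLCM (%d levels, d = %d, %d deg): %d pairs%s\n",
              nrow(x$p), x$distance, x$angle, x$pair_count,
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Haralick features of one GLCM
#'
#' Contrast `sum |i-j|^2 p(i,j)`, correlation
#' `sum (i - mu_i)(j - mu_j) p(i,j) / (sigma_i sigma_j)`, energy
#' `sum p(i,j)^2` and homogeneity `sum p(i,j) / (1 + |i-j|)`. Correlation is
#' missing when either marginal standard deviation is zero.
#'
#' @param g A [glcm()] result.
#' @return Named numeric vector `(contrast, correlation, energy,
#'   homogeneity)`.
#' @export
glcm_features <- function(g) {
  if (g$empty) stopf("cannot compute features of an empty GLCM")
  ng <- nrow(g$p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  adiff <- abs(i - j)
  contrast <- sum(adiff^2 * g$p)
  energy <- sum(g$p^2)
  homogeneity <- sum(g$p / (1 + adiff))
  correlation <- if (g$sigma_i > 0 && g$sigma_j > 0)
    sum((i - g$mu_i) * (j - g$mu_j) * g$p) / (g$sigma_i * g$sigma_j)
  else NA_real_
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' Mean-value and texture biomarkers of one parametric map
#'
#' The mean over valid pixels plus the four GLCM features averaged over all
#' (distance, angle) combinations (default 5 distances x 4 directions = 20
#' GLCMs); empty GLCMs and degenerate (zero-variance) correlations are
#' skipped with counts recorded.
#'
#' @param map Numeric matrix (NA = missing).
#' @param mask Optional logical mask of pixels to use.
#' @param n_levels Gray levels for quantization.
#' @param distances Inter-pixel distances, pixels.
#' @param angles Directions, degrees.
#' @return Named list: `mean`, `contrast`, `correlation`, `energy`,
#'   `homogeneity`, `n_glcms_averaged`, `n_correlation_averaged`.
#' @export
map_features <- function(map, mask = NULL, n_levels = 16, distances = 1:5,
                         angles = c(0, 45, 90, 135)) {
  if (!is.null(mask)) map[!mask] <- NA_real_
  valid <- is.finite(map)
  if (!any(valid)) stopf("map has no valid pixels")
  q <- quantize_map(map, n_levels)
  feats <- matrix(NA_real_, length(distances) * length(angles), 4)
  k <- 0
  for (d in distances) for (ang in angles) {
    k <- k + 1
    g <- glcm(q, d, ang)
    if (!g$empty) feats[k, ] <- glcm_features(g)
  }
  have <- !is.na(feats[, 1])
  if (!any(have))
    return(list(mean = mean(map[valid]), contrast = NA_real_,
                correlation = NA_real_, energy = NA_real_,
                homogeneity = NA_real_, n_glcms_averaged = 0L,
                n_correlation_averaged = 0L))
  corr_have <- !is.na(feats[, 2])
  list(mean = mean(map[valid]),
       contrast = mean(feats[have, 1]),
       correlation = if (any(corr_have)) mean(feats[corr_have, 2]) else NA_real_,
       energy = mean(feats[have, 3]),
       homogeneity = mean(feats[have, 4]),
       n_glcms_averaged = sum(have),
       n_correlation_averaged = sum(corr_have))
}

#' Biomarkers of a full parametric map set
#'
#' Applies [map_features()] to each of the six maps of a `qus_map_set`.
#'
#' @param mapset A [build_parametric_maps()] result.
#' @param ... Passed to [map_features()].
#' @return A data frame with one row per parameter.
#' @export
mapset_features <- function(mapset, ...) {
  rows <- lapply(names(mapset$maps), function(p) {
    ft <- map_features(mapset$maps[[p]], ...)
    data.frame(parameter = p, mean = ft$mean, contrast = ft$contrast,
               correlation = ft$correlation, energy = ft$energy,
               homogeneity = ft$homogeneity,
               n_glcms_averaged = ft$n_glcms_averaged)
  })
  out <- do.call(rbind, rows)
  out$plane_offset <- mapset$plane_offset
  out$ace <- mapset$ace$ace
  out
}
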