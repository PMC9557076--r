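#' Two-sphere contrast phantom
#'
#' Two discs filled with compartments representative of post-contrast T1
#' times of the blood pool and the healthy myocardium (T1 = 489 ms and
#' 910 ms), side by side on a square grid — the geometry used for the
#' contrast-homogeneity phantom experiment.
#'
#' @param n Grid side length in voxels (default 128).
#' @param radius Disc radius in voxels (default 20).
#' @param t1_blood_ms,t1_myo_ms Compartment T1 values (ms).
#' @param ... Noise arguments forwarded to [phantom_spec()]
#'   (`noise_sd`, `baseline_snr`, `snr_reference`).
#' @return A [phantom_spec()] with compartments `"blood"` (label 1) and
#'   `"myocardium"` (label 2).
#' @export
#' @examples
#' ph <- phantom_two_sphere(n = 64, radius = 10)
#' table(ph$label_map)
phantom_two_sphere <- function(n = 128L, radius = 20L,
                               t1_blood_ms = 489, t1_myo_ms = 910, ...) {
  stopifnot(n >= 4 * radius / 1.5, radius >= 2)
  lm <- matrix(0L, n, n)
  cx <- n / 2 + 0.5
  cy1 <- n / 4 + 0.5
  cy2 <- 3 * n / 4 + 0.5
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - cx)^2 + (j - cy1)^2 <= radius^2) lm[i, j] <- 1L
      if ((i - cx)^2 + (j - cy2)^2 <= radius^2) lm[i, j] <- 2L
    }
  }
  phantom_spec(lm, list(tissue_compartment("blood", t1_blood_ms),
                        tissue_compartment("myocardium", t1_myo_ms)), ...)
}

#' Cardiac short-axis phantom
#'
#' A simplified mid-ventricular short-axis slice: circular blood pool,
#' surrounding myocardial annulus, and an optional transmural scar wedge
#' in the annulus. With `contraction > 0` the annulus radii are scaled per
#' cardiac phase by `1 - contraction * sin(pi * p / (n_phases - 1))`
#' (systolic narrowing, back to baseline), exercising phase-resolved
#' bookkeeping; the phantom is static by default like the physical one.
#'
#' @param n Grid side (voxels).
#' @param r_blood Blood-pool radius (voxels).
#' @param r_epi Epicardial radius of the annulus (voxels).
#' @param scar_angle_deg Angular width of the scar wedge (0 disables scar).
#' @param t1_blood_ms,t1_myo_ms,t1_scar_ms Compartment T1 values (ms);
#'   post-contrast defaults with scar shorter than remote myocardium.
#' @param contraction Peak fractional radius reduction over the cycle.
#' @param n_phases Number of cardiac phases (needed when `contraction > 0`).
#' @param ... Noise arguments forwarded to [phantom_spec()].
#' @return A [phantom_spec()] with compartments `"blood"` (1),
#'   `"myocardium"` (2) and, if enabled, `"scar"` (3).
#' @export
phantom_cardiac <- function(n = 128L, r_blood = 18L, r_epi = 30L,
                            scar_angle_deg = 60, t1_blood_ms = 489,
                            t1_myo_ms = 910, t1_scar_ms = 350,
                            contraction = 0, n_phases = NULL, ...) {
  stopifnot(r_epi > r_blood, r_blood >= 2, n > 2 * r_epi)
  build_map <- function(scale) {
    rb <- r_blood * scale
    re <- r_epi * scale
    lm <- matrix(0L, n, n)
    c0 <- n / 2 + 0.5
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        r2 <- (i - c0)^2 + (j - c0)^2
        if (r2 <= rb^2) {
          lm[i, j] <- 1L
        } else if (r2 <= re^2) {
          ang <- atan2(j - c0, i - c0) * 180 / pi
          lm[i, j] <- if (scar_angle_deg > 0 &&
                          ang >= 0 && ang < scar_angle_deg) 3L else 2L
        }
      }
    }
    lm
  }
  comps <- list(tissue_compartment("blood", t1_blood_ms),
                tissue_compartment("myocardium", t1_myo_ms))
  if (scar_angle_deg > 0) {
    comps <- c(comps, list(tissue_compartment("scar", t1_scar_ms)))
  }
  maps <- NULL
  if (contraction > 0) {
    if (is.null(n_phases)) stop("`n_phases` required when contraction > 0")
    scales <- 1 - contraction * sin(pi * (seq_len(n_phases) - 1) / max(n_phases - 1, 1))
    maps <- lapply(scales, build_map)
  }
  phantom_spec(build_map(1), comps, label_maps_by_phase = maps, ...)
}

#' ROI masks for the built-in phantoms
#'
#' Returns the per-compartment masks of a phantom spec, eroded by
#' requiring full membership (exact label match), as logical matrices.
#'
#' @param spec A [phantom_spec()].
#' @return Named list of logical matrices, one per compartment label.
#' @export
phantom_masks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  out <- lapply(seq_along(spec$compartments),
                function(k) spec$label_map == k)
  names(out) <- spec$compartment_labels
  out
}
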