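#' ROI pair for contrast analysis
#'
#' @param myo_mask,blood_mask Non-empty, disjoint logical matrices (shared
#'   across phases) or lists of matrices (one per phase).
#' @param note Optional provenance note.
#' @return A `roi_pair` object.
#' @export
roi_pair <- function(myo_mask, blood_mask, note = NULL) {
  as_list <- function(m) if (is.list(m)) m else list(m)
  ml <- as_list(myo_mask); bl <- as_list(blood_mask)
  for (k in seq_along(ml)) {
    m <- ml[[k]]; b <- bl[[min(k, length(bl))]]
    stopifnot(is.logical(m), is.logical(b), all(dim(m) == dim(b)))
    if (!any(m) || !any(b)) stop("ROI masks must be non-empty")
    if (any(m & b)) stop("ROI masks must be disjoint")
  }
  structure(list(myo_mask = myo_mask, blood_mask = blood_mask, note = note),
            class = "roi_pair")
}

roi_for_phase <- function(rois, p) {
  pick <- function(m) if (is.list(m)) m[[p]] else m
  list(myo = pick(rois$myo_mask), blood = pick(rois$blood_mask))
}

#' Apparent contrast-to-noise ratio (aCNR)
#'
#' `aCNR = |mu_Myo - mu_Blood| / sqrt((sigma_Myo^2 + sigma_Blood^2) / 2)`
#' where `mu` and `sigma` are the mean and *spatial* standard deviation of
#' the signal within each ROI. Because the noise term is a within-ROI
#' spatial SD rather than a background estimate, values are comparable
#' across cardiac phases of one scan but not to conventional CNR
#' literature values. `NA` voxels (non-converged fits) are excluded.
#'
#' @param image Numeric matrix (one synthesized phase image).
#' @param rois A [roi_pair()] (shared masks) or a list
#'   `list(myo=, blood=)` of two logical matrices.
#' @param phase 1-based phase index used to select per-phase masks.
#' @return The aCNR value (dimensionless).
#' @export
#' @examples
#' img <- matrix(c(10, 10, 30, 30), 2)  # zero spatial SD -> error
acnr <- function(image, rois, phase = 1L) {
  stopifnot(is.matrix(image))
  if (inherits(rois, "roi_pair")) {
    r <- roi_for_phase(rois, phase)
  } else {
    r <- list(myo = rois$myo, blood = rois$blood)
  }
  x1 <- image[r$myo]; x2 <- image[r$blood]
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("each ROI needs at least 2 finite voxels (spatial SD undefined)")
  }
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  denom <- sqrt((s1^2 + s2^2) / 2)
  if (denom == 0) stop("zero spatial variability in both ROIs: aCNR undefined")
  abs(mean(x1) - mean(x2)) / denom
}

#' Per-phase aCNR of a synthesized stack
#'
#' @param stack A `synth_lge_stack` from [synthesize_lge()].
#' @param rois A [roi_pair()].
#' @return Numeric vector, one aCNR per cardiac phase.
#' @export
acnr_series <- function(stack, rois) {
  stopifnot(inherits(stack, "synth_lge_stack"))
  n_phases <- dim(stack$data)[1]
  vapply(seq_len(n_phases),
         function(p) acnr(stack$data[p, , ], rois, phase = p), numeric(1))
}

#' Repetition-noise contrast-to-noise ratio
#'
#' For repeated acquisitions the noise of the non-linearly processed
#' synthesized images is defined as the per-voxel variability across
#' repetitions: `noise(ROI) = mean over ROI voxels of SD across
#' repetitions`, and
#' `CNR = |mu_1 - mu_2| / sqrt((n_1^2 + n_2^2)/2)` with the ROI means `mu`
#' taken on the repetition-mean image. With identical repetitions (zero
#' noise) the CNR is undefined and reported as `Inf`.
#'
#' @param stacks List (length >= 2) of `synth_lge_stack` objects with
#'   identical geometry (the repetitions).
#' @param rois A [roi_pair()].
#' @return Numeric vector of per-phase CNR values.
#' @export
repetition_cnr <- function(stacks, rois) {
  stopifnot(is.list(stacks), length(stacks) >= 2L)
  dims <- lapply(stacks, function(s) dim(s$data))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("repetitions must share geometry")
  }
  d <- dims[[1]]
  n_phases <- d[1]
  arr <- array(NA_real_, c(length(stacks), d))
  for (r in seq_along(stacks)) arr[r, , , ] <- stacks[[r]]$data
  out <- numeric(n_phases)
  if (!inherits(rois, "roi_pair")) rois <- roi_pair(rois$myo, rois$blood)
  for (p in seq_len(n_phases)) {
    r <- roi_for_phase(rois, p)
    slice <- arr[, p, , ]                      # [repetition, row, col]
    mean_img <- apply(slice, c(2, 3), mean)
    sd_img <- apply(slice, c(2, 3), stats::sd)
    mu1 <- mean(mean_img[r$myo], na.rm = TRUE)
    mu2 <- mean(mean_img[r$blood], na.rm = TRUE)
    n1 <- mean(sd_img[r$myo], na.rm = TRUE)
    n2 <- mean(sd_img[r$blood], na.rm = TRUE)
    denom <- sqrt((n1^2 + n2^2) / 2)
    out[p] <- if (denom == 0) Inf else abs(mu1 - mu2) / denom
  }
  out
}

#' Coefficient of variation in percent
#'
#' `100 * SD(x) / mean(x)` with the sample (n-1) SD.
#'
#' @param series Non-empty numeric vector with non-zero mean.
#' @return CoV in percent.
#' @export
#' @examples
#' cov_percent(c(1, 2, 3))  # 50
cov_percent <- function(series) {
  series <- as.numeric(series)
  if (length(series) == 0L || any(!is.finite(series))) {
    stop("series must be non-empty and finite")
  }
  m <- mean(series)
  if (m == 0) stop("zero mean: CoV undefined")
  100 * stats::sd(series) / m
}

#' Linear interpolation to a fixed number of reconstruction phases
#'
#' Different heart rates yield different numbers of acquired cardiac
#' phases at fixed temporal resolution; for cross-subject comparison the
#' per-phase series is linearly interpolated onto `n_target` phases over
#' the normalized phase position \[0, 1\] (endpoints map to endpoints, no
#' extrapolation).
#'
#' @param series Numeric vector, length >= 2.
#' @param n_target Number of reconstruction phases (default 20).
#' @return Numeric vector of length `n_target`.
#' @export
#' @examples
#' interpolate_phases(c(0, 1))        # 20-point ramp
interpolate_phases <- function(series, n_target = 20L) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2L) stop("need at least 2 phases to interpolate")
  stopifnot(n_target >= 2L)
  x <- seq(0, 1, length.out = n)
  stats::approx(x, series, xout = seq(0, 1, length.out = n_target))$y
}

#' Full contrast report for a synthesized stack
#'
#' Bundles the per-phase aCNR, its 20-phase interpolation, the CoV of the
#' interpolated series, and (when repetitions are given) the per-phase
#' repetition-noise CNR with its CoV.
#'
#' @param stack A `synth_lge_stack` (or the first repetition).
#' @param rois A [roi_pair()].
#' @param repetitions Optional list of repetition `synth_lge_stack`s
#'   (including or excluding `stack`; used only for repetition CNR).
#' @param n_recon_phases Reconstruction phase count (default 20).
#' @return A `contrast_report` list: `per_phase_acnr`,
#'   `interpolated_acnr`, `cov_acnr_percent`, `phantom_cnr`,
#'   `cov_cnr_percent`, `n_phases`, `t_syn_ms`.
#' @export
contrast_report <- function(stack, rois, repetitions = NULL,
                            n_recon_phases = 20L) {
  stopifnot(inherits(stack, "synth_lge_stack"))
  a <- acnr_series(stack, rois)
  interp <- interpolate_phases(a, n_recon_phases)
  cnr <- NULL; cov_cnr <- NULL
  if (!is.null(repetitions)) {
    cnr <- repetition_cnr(repetitions, rois)
    cov_cnr <- if (all(is.finite(cnr))) cov_percent(cnr) else NA_real_
  }
  structure(list(per_phase_acnr = a,
                 interpolated_acnr = interp,
                 cov_acnr_percent = cov_percent(interp),
                 phantom_cnr = cnr,
                 cov_cnr_percent = cov_cnr,
                 n_phases = length(a),
                 t_syn_ms = stack$t_syn_ms),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("<contrast_report>\n")
  cat(sprintf("  %d acquired phases, t_syn = %.1f ms\n", x$n_phases, x$t_syn_ms))
  cat(sprintf("  aCNR: %.2f +/- %.2f (CoV %.2f%% over %d recon phases)\n",
              mean(x$per_phase_acnr), stats::sd(x$per_phase_acnr),
              x$cov_acnr_percent, length(x$interpolated_acnr)))
  if (!is.null(x$phantom_cnr)) {
    cat(sprintf("  repetition CNR: %.2f +/- %.2f (CoV %s%%)\n",
                mean(x$phantom_cnr), stats::sd(x$phantom_cnr),
                ifelse(is.na(x$cov_cnr_percent), "NA",
                       sprintf("%.2f", x$cov_cnr_percent))))
  }
  invisible(x)
}
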