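#' Sequence parameters of the Look-Locker FLASH acquisition
#'
#' Bundles the tunable parameters of the prospectively triggered,
#' continuously running FLASH readout used for phase-resolved
#' multi-inversion-time imaging. Defaults correspond to a 3T protocol:
#' TR 5 ms, 3 degree imaging flip angle, three inversion-pulse offsets,
#' an acquisition window covering 90% of the R-R interval, and recovery
#' to the pulsed steady state spanning two heart beats (so each inversion
#' contributes two points on the recovery curve per cardiac phase).
#'
#' @param tr_ms Repetition time of the FLASH pulse train (ms).
#' @param flip_deg Imaging flip angle (degrees), must lie in (0, 90).
#' @param lines_per_segment Readout lines acquired per phase per beat.
#'   Carried as metadata; the planner works with the segment-center time.
#' @param offset_times_ms Inversion-pulse offsets relative to the R-wave
#'   (ms). `NULL` (default) requests `n_offsets` evenly spaced offsets
#'   `(0, RR/n, 2 RR/n, ...)` resolved against `min(rr_ms)` at planning
#'   time.
#' @param n_offsets Number of inversion-pulse offsets; ignored when
#'   `offset_times_ms` is given explicitly.
#' @param acq_window_fraction Fraction of the R-R interval covered by the
#'   prospective acquisition window, in (0, 1].
#' @param inv_efficiency Inversion efficiency in \[0, 1\] (1 = complete
#'   inversion, the assumption under which the two-parameter fit holds).
#' @param recovery_beats Heart beats spanned by the recovery to the pulsed
#'   steady state (and hence inversion-curve samples per inversion pulse).
#'
#' @return An object of class `sequence_params` (a validated list).
#' @seealso [cardiac_timing()], [plan_acquisition()]
#' @export
#' @examples
#' sequence_params()                 # 3T-style defaults
#' sequence_params(tr_ms = 6.7, flip_deg = 6)  # 1.5T-style protocol
sequence_params <- function(tr_ms = 5, flip_deg = 3, lines_per_segment = 1L,
                            offset_times_ms = NULL, n_offsets = 3L,
                            acq_window_fraction = 0.9, inv_efficiency = 1,
                            recovery_beats = 2L) {
  stopifnot(is.numeric(tr_ms), length(tr_ms) == 1L, tr_ms > 0)
  if (!is.numeric(flip_deg) || length(flip_deg) != 1L ||
      flip_deg <= 0 || flip_deg >= 90) {
    stop("`flip_deg` must lie strictly between 0 and 90 degrees")
  }
  if (!is.null(offset_times_ms)) {
    stopifnot(is.numeric(offset_times_ms), length(offset_times_ms) >= 1L,
              all(offset_times_ms >= 0))
    n_offsets <- length(offset_times_ms)
  }
  stopifnot(n_offsets >= 1L)
  if (acq_window_fraction <= 0 || acq_window_fraction > 1) {
    stop("`acq_window_fraction` must lie in (0, 1]")
  }
  if (inv_efficiency < 0 || inv_efficiency > 1) {
    stop("`inv_efficiency` must lie in [0, 1]")
  }
  stopifnot(recovery_beats >= 1L, lines_per_segment >= 1L)
  structure(list(
    tr_ms = as.numeric(tr_ms),
    flip_deg = as.numeric(flip_deg),
    lines_per_segment = as.integer(lines_per_segment),
    offset_times_ms = if (is.null(offset_times_ms)) NULL else as.numeric(offset_times_ms),
    n_offsets = as.integer(n_offsets),
    acq_window_fraction = as.numeric(acq_window_fraction),
    inv_efficiency = as.numeric(inv_efficiency),
    recovery_beats = as.integer(recovery_beats)
  ), class = "sequence_params")
}

#' ECG timing of the acquisition
#'
#' Holds the measured (or simulated) R-R interval series and the temporal
#' resolution, and derives the number of cardiac phases that fit in the
#' prospective acquisition window:
#' `n_phases = floor(acq_window_fraction * min(rr_ms) / phase_duration_ms)`.
#'
#' @param rr_ms R-R interval durations (ms); a single value means a
#'   constant (simulated-ECG) heart rate.
#' @param phase_duration_ms Temporal resolution, i.e. duration of one
#'   cardiac-phase bin (ms).
#' @param acq_window_fraction Fraction of the R-R interval available for
#'   acquisition; used only to derive `n_phases` and must match the value
#'   in [sequence_params()] when planning.
#' @return An object of class `cardiac_timing` with fields `rr_ms`,
#'   `phase_duration_ms`, `n_phases`, `acq_window_fraction`.
#' @export
#' @examples
#' cardiac_timing(rr_ms = 1000, phase_duration_ms = 50)  # 18 phases at 60 bpm
cardiac_timing <- function(rr_ms, phase_duration_ms = 50,
                           acq_window_fraction = 0.9) {
  stopifnot(is.numeric(rr_ms), length(rr_ms) >= 1L, all(rr_ms > 0),
            is.numeric(phase_duration_ms), phase_duration_ms > 0,
            acq_window_fraction > 0, acq_window_fraction <= 1)
  n_phases <- floor(acq_window_fraction * min(rr_ms) / phase_duration_ms + 1e-9)
  if (n_phases < 1L) {
    stop("no cardiac phase fits in the acquisition window: ",
         "phase_duration_ms exceeds acq_window_fraction * min(rr_ms)")
  }
  structure(list(
    rr_ms = as.numeric(rr_ms),
    phase_duration_ms = as.numeric(phase_duration_ms),
    n_phases = as.integer(n_phases),
    acq_window_fraction = as.numeric(acq_window_fraction)
  ), class = "cardiac_timing")
}

#' Convenience constructor for a constant simulated heart rate
#'
#' @param bpm Heart rate in beats per minute.
#' @param phase_duration_ms,acq_window_fraction See [cardiac_timing()].
#' @return A `cardiac_timing` object with a single R-R interval.
#' @export
timing_from_bpm <- function(bpm, phase_duration_ms = 50,
                            acq_window_fraction = 0.9) {
  stopifnot(bpm > 0)
  cardiac_timing(60000 / bpm, phase_duration_ms, acq_window_fraction)
}

resolve_offsets <- function(params, timing) {
  rr <- min(timing$rr_ms)
  off <- params$offset_times_ms
  if (is.null(off)) {
    off <- (seq_len(params$n_offsets) - 1L) / params$n_offsets * rr
  }
  if (any(off < 0 | off >= rr)) {
    stop("inversion-pulse offsets must lie in [0, RR)")
  }
  off
}

#' Plan the per-phase inversion-time sampling
#'
#' Translates ECG timing and sequence parameters into the inversion-time
#' table realized by the prospectively triggered Look-Locker scheme. The
#' inversion pulse of each Look-Locker experiment is played `t_off` ms
#' after an R-wave; the continuous FLASH readout then samples every
#' cardiac phase once per beat while the magnetization recovers to the
#' pulsed steady state over `recovery_beats` beats. A phase whose bin
#' center precedes the inversion within the trigger beat is first sampled
#' in the following beat. Phase centers sit at `(i + 0.5) * phase_duration`
#' after the R-wave. With constant R-R this yields, per phase and offset,
#'
#'   `TI = (phase_center - t_off) mod RR + b * RR`,  `b = 0 .. recovery_beats-1`,
#'
#' i.e. `recovery_beats * n_offsets` inversion times per cardiac phase
#' (six for the default three offsets and two-beat recovery), with the two
#' samples of one inversion separated by exactly one R-R interval. With a
#' variable R-R series each beat contributes its own measured duration.
#'
#' @param params A [sequence_params()] object.
#' @param timing A [cardiac_timing()] object (its `acq_window_fraction`
#'   must equal the one in `params`).
#' @return An object of class `acquisition_plan`: a list with
#'   \describe{
#'     \item{ti}{long-format `data.frame` with columns `phase_index`
#'       (0-based), `offset_index` (0-based), `beat_index`
#'       (0-based recovery beat), `ti_ms`.}
#'     \item{ti_matrix}{`n_phases x (recovery_beats * n_offsets)` matrix of
#'       inversion times, sorted ascending within each phase (row).}
#'     \item{dummy_counts}{per-beat number of FLASH pulses without readout.}
#'     \item{phase_centers_ms}{phase-bin centers after the R-wave (ms).}
#'     \item{offset_times_ms}{the resolved inversion-pulse offsets (ms).}
#'   }
#' @export
#' @examples
#' plan <- plan_acquisition(sequence_params(), timing_from_bpm(60))
#' dim(plan$ti_matrix)   # 18 phases x 6 inversion times
plan_acquisition <- function(params, timing) {
  stopifnot(inherits(params, "sequence_params"), inherits(timing, "cardiac_timing"))
  if (abs(params$acq_window_fraction - timing$acq_window_fraction) > 1e-12) {
    stop("acq_window_fraction differs between params and timing")
  }
  offsets <- resolve_offsets(params, timing)
  n_phases <- timing$n_phases
  pd <- timing$phase_duration_ms
  centers <- (seq_len(n_phases) - 0.5) * pd
  nb <- params$recovery_beats
  n_off <- length(offsets)

  # Every offset experiment sees the same R-R sequence from its trigger
  # beat (beat 0 = rr_ms[1], then rr_ms recycled), so the sorted TI table
  # is invariant under offset permutation; with variable R-R each beat
  # contributes its own measured duration to the +RR terms.
  rr_seq <- rep_len(timing$rr_ms, nb + 1L)
  beat_start <- cumsum(c(0, rr_seq))

  rows <- vector("list", n_off * n_phases)
  for (o in seq_len(n_off)) {
    t_off <- offsets[o]
    t_inv <- t_off                      # inversion in the trigger beat
    for (i in seq_len(n_phases)) {
      pc <- centers[i]
      first_beat <- if (pc >= t_off) 0L else 1L
      b <- 0:(nb - 1L)
      sample_t <- beat_start[first_beat + b + 1L] + pc
      rows[[(o - 1L) * n_phases + i]] <- data.frame(
        phase_index = i - 1L, offset_index = o - 1L,
        beat_index = b, ti_ms = sample_t - t_inv)
    }
  }
  ti_long <- do.call(rbind, rows)
  if (any(ti_long$ti_ms <= 0)) {
    stop("planned inversion time is non-positive; check offsets vs phase centers")
  }
  ti_mat <- matrix(NA_real_, nrow = n_phases, ncol = nb * n_off)
  for (i in seq_len(n_phases)) {
    ti_mat[i, ] <- sort(ti_long$ti_ms[ti_long$phase_index == i - 1L])
  }
  structure(list(
    ti = ti_long[order(ti_long$phase_index, ti_long$ti_ms), ],
    ti_matrix = ti_mat,
    dummy_counts = dummy_pulse_counts(params, timing),
    phase_centers_ms = centers,
    offset_times_ms = offsets,
    params = params,
    timing = timing
  ), class = "acquisition_plan")
}

#' Dummy-pulse counts per beat
#'
#' After the acquisition window ends, FLASH pulses without readout are
#' played until the next R-wave so the pulsed recovery is never
#' interrupted: `count = floor((RR - acq_window_fraction * RR) / TR)` per
#' beat, evaluated with each beat's own measured R-R duration.
#'
#' @inheritParams plan_acquisition
#' @return Integer vector of per-beat dummy-pulse counts (same length as
#'   `timing$rr_ms`).
#' @export
#' @examples
#' dummy_pulse_counts(sequence_params(), cardiac_timing(c(1000, 1100)))
dummy_pulse_counts <- function(params, timing) {
  stopifnot(inherits(params, "sequence_params"), inherits(timing, "cardiac_timing"))
  # epsilon guards the floor against binary-fraction artifacts
  # (e.g. 1000 * (1 - 0.9) / 5 = 19.999...)
  as.integer(floor((timing$rr_ms * (1 - params$acq_window_fraction)) /
                     params$tr_ms + 1e-9))
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat("<acquisition_plan>\n")
  cat(sprintf("  %d cardiac phases x %d inversion times (%.1f ms resolution)\n",
              nrow(x$ti_matrix), ncol(x$ti_matrix), x$timing$phase_duration_ms))
  cat(sprintf("  offsets (ms): %s\n",
              paste(sprintf("%.1f", x$offset_times_ms), collapse = ", ")))
  cat(sprintf("  TI range: %.1f - %.1f ms\n", min(x$ti_matrix), max(x$ti_matrix)))
  invisible(x)
}

#' Export / import an acquisition plan as CSV
#'
#' The CSV carries the long-format table with columns `phase_index`,
#' `offset_index`, `beat_index`, `ti_ms` (times in ms, phases 0-based).
#'
#' @param plan An [plan_acquisition()] result.
#' @param path File path of the CSV.
#' @return `write_plan_csv` returns `path` invisibly; `read_plan_csv`
#'   returns the long-format `data.frame`.
#' @export
write_plan_csv <- function(plan, path) {
  stopifnot(inherits(plan, "acquisition_plan"))
  utils::write.csv(plan$ti, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan_csv
#' @export
read_plan_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("phase_index", "offset_index", "beat_index", "ti_ms")
  if (!all(need %in% names(df))) {
    stop("plan CSV must have columns ", paste(need, collapse = ", "))
  }
  df
}
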