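# Shared small fixtures, built in code at test time.

default_plan <- function(bpm = 60, ...) {
  plan_acquisition(sequence_params(...), timing_from_bpm(bpm))
}

# 16x16 two-sphere phantom: enough voxels for ROI statistics, cheap to fit
small_sphere_spec <- function(...) {
  phantom_two_sphere(n = 16L, radius = 3L, ...)
}

# Full zero-noise pipeline on the small phantom; returns everything.
run_small_pipeline <- function(bpm = 60, signal_model = "bloch",
                               null_label = "myocardium", ...) {
  plan <- default_plan(bpm = bpm)
  spec <- small_sphere_spec(...)
  stack <- generate_stack(spec, plan, signal_model = signal_model)[[1]]
  maps <- fit_volume(stack)
  masks <- phantom_masks(spec)
  t_syn <- synth_time_for_null(maps = maps, null_roi = masks[[null_label]])
  synth <- synthesize_lge(maps, t_syn)
  list(plan = plan, spec = spec, stack = stack, maps = maps,
       masks = masks, t_syn = t_syn, synth = synth)
}

# all masked voxel values of a [phase, row, col] array, phases pooled
roi_vals <- function(arr3, mask) {
  unlist(lapply(seq_len(dim(arr3)[1]), function(p) arr3[p, , ][mask]))
}

random_config <- function() {
  n_off <- sample(1:5, 1)
  rr <- if (stats::runif(1) < 0.3) {
    round(stats::runif(sample(2:4, 1), 700, 1200), 1)
  } else {
    round(stats::runif(1, 600, 1200), 1)
  }
  frac <- stats::runif(1, 0.7, 1.0)
  pd <- stats::runif(1, 30, 80)
  # keep n_phases <= 30 and >= 1
  pd <- max(pd, frac * min(rr) / 30)
  params <- sequence_params(
    tr_ms = stats::runif(1, 3, 8),
    flip_deg = stats::runif(1, 2, 10),
    offset_times_ms = sort(stats::runif(n_off, 0, 0.95 * min(rr))),
    acq_window_fraction = frac,
    recovery_beats = sample(1:3, 1))
  timing <- cardiac_timing(rr, pd, frac)
  list(params = params, timing = timing)
}
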