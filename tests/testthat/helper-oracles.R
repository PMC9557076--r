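# Independent oracles. These deliberately avoid the package's arithmetic:
# the planner oracle walks the pulse timeline beat by beat, the fit oracle
# is a profile grid search, the interpolation oracle evaluates each
# segment by hand.

# Brute-force event-list planner: place every inversion on the timeline,
# then scan forward beat by beat collecting the first `recovery_beats`
# phase-center sample times after it.
oracle_plan_ti <- function(params, timing) {
  rr_all <- timing$rr_ms
  f <- params$acq_window_fraction
  n_phases <- floor(f * min(rr_all) / timing$phase_duration_ms + 1e-9)
  centers <- (seq_len(n_phases) - 0.5) * timing$phase_duration_ms
  offsets <- params$offset_times_ms
  if (is.null(offsets)) {
    offsets <- (seq_len(params$n_offsets) - 1) / params$n_offsets * min(rr_all)
  }
  nb <- params$recovery_beats
  total_beats <- nb + 1L
  rr_seq <- rep_len(rr_all, total_beats + 5L)
  starts <- cumsum(c(0, rr_seq))
  tis <- vector("list", n_phases)
  for (o in seq_along(offsets)) {
    t_inv <- offsets[o]                # trigger beat is beat 0 per offset
    for (i in seq_len(n_phases)) {
      got <- 0L
      b <- 0L
      while (got < nb) {
        t_samp <- starts[b + 1L] + centers[i]
        if (t_samp > t_inv + 1e-12) {
          tis[[i]] <- c(tis[[i]], t_samp - t_inv)
          got <- got + 1L
        }
        b <- b + 1L
        if (b > total_beats + 4L) stop("oracle ran off the timeline")
      }
    }
  }
  do.call(rbind, lapply(tis, sort))
}

# Profile grid search for the two-parameter IR model: for each candidate
# T1* the optimal A is the linear least-squares solution; the best grid
# cell is refined with one-dimensional optimization.
oracle_fit_grid <- function(ti, y, n_grid = 800) {
  sse_of <- function(t1) {
    g <- 1 - 2 * exp(-ti / t1)
    a <- sum(y * g) / sum(g * g)
    sum((y - a * g)^2)
  }
  grid <- exp(seq(log(10), log(5000), length.out = n_grid))
  sse <- vapply(grid, sse_of, numeric(1))
  i <- which.min(sse)
  opt <- stats::optimize(sse_of, c(grid[max(i - 1, 1)],
                                   grid[min(i + 1, n_grid)]), tol = 1e-10)
  t1 <- opt$minimum
  g <- 1 - 2 * exp(-ti / t1)
  list(a = sum(y * g) / sum(g * g), t1_star_ms = t1, sse = opt$objective)
}

# Piecewise-linear interpolation evaluated segment by segment.
oracle_interp <- function(series, n_target) {
  n <- length(series)
  xs <- seq(0, 1, length.out = n)
  vapply(seq(0, 1, length.out = n_target), function(x) {
    if (x >= 1) return(series[n])
    j <- max(which(xs <= x + 1e-15))
    w <- (x - xs[j]) / (xs[j + 1] - xs[j])
    (1 - w) * series[j] + w * series[j + 1]
  }, numeric(1))
}

# Pulsed steady state by literal fixed-point iteration of the
# pulse-relaxation recursion.
oracle_pss <- function(t1, flip_deg, tr, m0 = 1, n_iter = 20000) {
  e1 <- exp(-tr / t1)
  ca <- cos(flip_deg * pi / 180)
  mz <- m0
  for (i in seq_len(n_iter)) mz <- m0 * (1 - e1) + mz * ca * e1
  mz
}

# Apparent T1 by fitting a densely sampled noiseless pulsed recovery
# (pure TR-grid recursion, no cardiac structure) with the grid oracle.
oracle_apparent_t1 <- function(t1, flip_deg, tr, n_pulses = 2000) {
  e1 <- exp(-tr / t1)
  ca <- cos(flip_deg * pi / 180)
  mz <- -oracle_pss(t1, flip_deg, tr)
  ti <- numeric(n_pulses)
  s <- numeric(n_pulses)
  for (k in seq_len(n_pulses)) {
    ti[k] <- k * tr
    mz <- 1 - e1 + mz * e1            # relax one TR (applied pre-pulse)
    s[k] <- mz                        # pre-pulse longitudinal magnetization
    mz <- mz * ca
  }
  keep <- seq(1, n_pulses, by = 7)    # thin the grid for speed
  oracle_fit_grid(ti[keep], s[keep])$t1_star_ms
}
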