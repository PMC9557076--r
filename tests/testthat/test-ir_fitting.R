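ti6 <- c(100, 300, 650, 1100, 1650, 2100)

test_that("model evaluates the inversion-recovery curve", {
  expect_equal(model_ir(400 * log(2), 123, 400), 0)
  expect_equal(model_ir(1e9, 7, 400), 7)
  expect_equal(model_ir(300, 200, 400), 200 * (1 - 2 * exp(-0.75)))
  expect_equal(model_ir(300, 200, 400), 11.05, tolerance = 1e-3)
  expect_error(model_ir(100, 1, -5))
})

test_that("exact-model data is recovered to solver tolerance", {
  plan <- default_plan(bpm = 60)
  for (ph in c(1, 10)) {
    ti <- plan$ti_matrix[ph, ]
    fit <- fit_ir_two_param(ti, model_ir(ti, 100, 500))
    expect_true(fit$converged)
    expect_equal(fit$a, 100, tolerance = 1e-6)
    expect_equal(fit$t1_star_ms, 500, tolerance = 1e-6)
  }
})

test_that("noisy fits agree with the grid-search oracle", {
  set.seed(501)
  for (rep in 1:8) {
    a <- stats::runif(1, 50, 200)
    t1 <- stats::runif(1, 250, 900)
    y <- model_ir(ti6, a, t1) + stats::rnorm(6, sd = 0.03 * a)
    fit <- fit_ir_two_param(ti6, y)
    ora <- oracle_fit_grid(ti6, y)
    expect_true(fit$converged)
    expect_equal(fit$t1_star_ms, ora$t1_star_ms, tolerance = 1e-3)
    expect_equal(fit$a, ora$a, tolerance = 1e-3)
    expect_lte(fit$sse, ora$sse * (1 + 1e-6))
  }
})

test_that("fit errors and degenerate inputs are handled", {
  expect_error(fit_ir_two_param(c(100, 200), c(1, 2)), "at least 3")
  expect_error(fit_ir_two_param(c(100, 90, 200), c(1, 2, 3)), "increasing")
  z <- fit_ir_two_param(ti6, rep(0, 6))
  expect_false(z$converged)
  expect_equal(z$sse, 0)
})

test_that("polarity restoration picks the SSE-minimizing flip count", {
  # no TI below the null point -> k = 0
  f0 <- restore_polarity(ti6, abs(model_ir(ti6, 100, 120)))
  expect_equal(f0$polarity_k, 0L)
  # A=100, T1*=500: null at 346.6 ms, TIs 100 and 300 precede it -> k = 2
  f2 <- restore_polarity(ti6, abs(model_ir(ti6, 100, 500)))
  expect_equal(f2$polarity_k, 2L)
  expect_equal(f2$t1_star_ms, 500, tolerance = 1e-6)
  expect_equal(f2$signed[1:2], model_ir(ti6[1:2], 100, 500))
  # degenerate all-zero input: k = 0, flagged non-physical
  fz <- restore_polarity(ti6, rep(0, 6))
  expect_equal(fz$polarity_k, 0L)
  expect_false(fz$converged)
  expect_error(restore_polarity(c(1, 2), c(1, 1)), "at least 3")
})

test_that("noiseless polarity choice equals the TI-below-null count", {
  set.seed(502)
  plan <- default_plan(bpm = 60)
  for (rep in 1:12) {
    t1 <- stats::runif(1, 150, 1500)
    a <- stats::runif(1, 10, 300)
    ti <- plan$ti_matrix[sample(nrow(plan$ti_matrix), 1), ]
    fit <- restore_polarity(ti, abs(model_ir(ti, a, t1)))
    expect_equal(fit$polarity_k, sum(ti < t1 * log(2)))
  }
})

test_that("fit is scale-equivariant and has no hidden TI anchoring", {
  set.seed(503)
  y <- model_ir(ti6, 80, 600) + stats::rnorm(6, sd = 2)
  f1 <- fit_ir_two_param(ti6, y)
  f2 <- fit_ir_two_param(ti6, 13 * y)
  expect_equal(f2$a, 13 * f1$a, tolerance = 1e-6)
  expect_equal(f2$t1_star_ms, f1$t1_star_ms, tolerance = 1e-6)
  # shifting all TIs: compare against the oracle on the shifted problem
  f3 <- fit_ir_two_param(ti6 + 250, y)
  ora <- oracle_fit_grid(ti6 + 250, y)
  expect_equal(f3$t1_star_ms, ora$t1_star_ms, tolerance = 1e-3)
})

test_that("median T1* bias stays below 2% at baseline SNR 20", {
  plan <- default_plan(bpm = 60)
  ph <- 9L
  ti <- plan$ti_matrix[ph, ]
  set.seed(504)
  for (t1 in c(350, 450, 550, 650)) {
    t1s_ref <- apparent_t1(t1, 3, 5)
    a_ref <- pulsed_steady_state(t1, 3, 5) * sin(3 * pi / 180)
    fits <- replicate(200, {
      y <- abs(model_ir(ti, a_ref, t1s_ref) + stats::rnorm(6, sd = a_ref / 20))
      restore_polarity(ti, y)$t1_star_ms
    })
    expect_lt(abs(stats::median(fits, na.rm = TRUE) - t1s_ref) / t1s_ref, 0.02)
  }
})

test_that("volume fitting is constant on compartments and phases at zero noise", {
  res <- run_small_pipeline()
  maps <- res$maps
  expect_true(all(roi_vals(maps$converged_map, res$masks$blood)))
  for (lab in c("blood", "myocardium")) {
    m <- res$masks[[lab]]
    per_phase <- apply(maps$t1_star_map, 1, function(sl) {
      v <- sl[m]
      expect_lt(diff(range(v)) / mean(v), 1e-6)   # spatially constant
      mean(v)
    })
    expect_lt(100 * stats::sd(per_phase) / mean(per_phase), 0.1)  # CoV < 0.1%
  }
  expect_error(fit_volume(res$stack, matrix(FALSE, 16, 16)), "empty mask")
})

test_that("volume fitting equals a direct per-voxel reimplementation", {
  # 200 seeded repetitions of a single T1=550 voxel, few phases
  plan <- plan_acquisition(sequence_params(),
                           timing_from_bpm(60, phase_duration_ms = 200))
  spec <- phantom_spec(matrix(1L, 1, 1),
                       list(tissue_compartment("t", 550)),
                       baseline_snr = 20, snr_reference = "t")
  stacks <- generate_stack(spec, plan, n_repetitions = 200, seed = 77)
  n_ph <- plan$timing$n_phases
  via_volume <- sapply(stacks, function(s)
    fit_volume(s)$t1_star_map[, 1, 1])
  direct <- sapply(stacks, function(s)
    vapply(seq_len(n_ph), function(p)
      restore_polarity(s$ti_table[p, ], s$data[p, , 1, 1])$t1_star_ms,
      numeric(1)))
  expect_identical(via_volume, direct)
  cov_vol <- apply(via_volume, 1, function(v) 100 * stats::sd(v) / mean(v))
  cov_dir <- apply(direct, 1, function(v) 100 * stats::sd(v) / mean(v))
  expect_identical(cov_vol, cov_dir)
})
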