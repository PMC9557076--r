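test_that("pulsed steady state matches the fixed-point recursion", {
  # identity limits
  expect_equal(pulsed_steady_state(910, 0, 5, m0 = 2), 2)
  expect_equal(pulsed_steady_state(500, 30, 1e7), 1, tolerance = 1e-6)
  # fixed-point iteration oracle
  expect_equal(pulsed_steady_state(910, 3, 5), oracle_pss(910, 3, 5),
               tolerance = 1e-10)
  expect_equal(pulsed_steady_state(910, 3, 5), 0.801, tolerance = 1e-3)
  expect_error(pulsed_steady_state(910, 90, 5), "flip_deg")
})

test_that("apparent T1 matches a dense-recovery fit oracle", {
  expect_equal(apparent_t1(910, 0, 5), 910)
  expect_equal(apparent_t1(910, 3, 5), 728.3, tolerance = 1e-4)
  expect_equal(apparent_t1(489, 3, 5), 431.2, tolerance = 1e-4)
  for (t1 in c(350, 910)) {
    expect_equal(apparent_t1(t1, 3, 5), oracle_apparent_t1(t1, 3, 5),
                 tolerance = 1e-3)
  }
  expect_lt(apparent_t1(910, 3, 5), 910)   # readout always shortens T1
})

test_that("pulse train signals follow the apparent-relaxation model", {
  plan <- default_plan(bpm = 60)
  for (t1 in c(489, 910)) {
    comp <- tissue_compartment("x", t1)
    tr <- simulate_pulse_train(comp, plan)
    a_ref <- pulsed_steady_state(t1, 3, 5) * sin(3 * pi / 180)
    t1s_ref <- apparent_t1(t1, 3, 5)
    # earliest sample is still deep in the inverted regime
    first <- tr[which.min(tr$ti_ms), ]
    expect_equal(first$signal,
                 a_ref * (1 - 2 * exp(-first$ti_ms / t1s_ref)),
                 tolerance = 0.01 * a_ref)
    # latest sample has re-approached the model's recovery curve
    last <- tr[which.max(tr$ti_ms), ]
    expect_equal(last$signal,
                 a_ref * (1 - 2 * exp(-last$ti_ms / t1s_ref)),
                 tolerance = 0.01 * a_ref)
    # per-phase two-parameter fits recover T1* within 1% of the closed form
    for (ph in c(0L, 8L, 17L)) {
      sel <- tr$phase_index == ph
      o <- order(tr$ti_ms[sel])
      fit <- fit_ir_two_param(tr$ti_ms[sel][o], tr$signal[sel][o])
      expect_true(fit$converged)
      expect_equal(fit$t1_star_ms, t1s_ref, tolerance = 0.01)
    }
  }
})

test_that("magnetization re-reaches steady state before the next inversion", {
  # consistency across offsets: every offset experiment starts from the
  # same pulsed steady state, so one global model explains all samples
  plan <- default_plan(bpm = 60)
  tr <- simulate_pulse_train(tissue_compartment("x", 910), plan)
  a_ref <- pulsed_steady_state(910, 3, 5) * sin(3 * pi / 180)
  t1s_ref <- apparent_t1(910, 3, 5)
  pred <- a_ref * (1 - 2 * exp(-tr$ti_ms / t1s_ref))
  expect_lt(max(abs(tr$signal - pred)), 0.01 * a_ref)
})

test_that("phantom spec validates labels and noise settings", {
  comp <- list(tissue_compartment("a", 500))
  expect_error(phantom_spec(matrix(2L, 2, 2), comp), "no compartment")
  expect_error(phantom_spec(matrix(1L, 2, 2), comp, noise_sd = 0.1,
                            baseline_snr = 20), "at most one")
  expect_error(phantom_spec(matrix(1L, 2, 2), comp, baseline_snr = 20,
                            snr_reference = "zz"), "snr_reference")
  expect_error(tissue_compartment("a", -5))
})

test_that("baseline SNR resolves to steady-state signal over noise SD", {
  spec <- small_sphere_spec(baseline_snr = 20, snr_reference = "myocardium")
  params <- sequence_params()
  sd_n <- resolve_noise_sd(spec, params)
  s0 <- pulsed_steady_state(910, 3, 5) * sin(3 * pi / 180)
  expect_equal(s0 / sd_n, 20)
  expect_equal(resolve_noise_sd(small_sphere_spec(), params), 0)
})

test_that("generated stacks are consistent with the pulse-train signals", {
  plan <- default_plan(bpm = 60)
  spec <- small_sphere_spec()
  stack <- generate_stack(spec, plan)[[1]]
  expect_equal(dim(stack$data)[1:2], c(18L, 6L))
  expect_equal(stack$ti_table, plan$ti_matrix)
  # ROI-mean equals the compartment pulse-train signal at zero noise
  tr <- simulate_pulse_train(tissue_compartment("blood", 489), plan)
  masks <- phantom_masks(spec)
  for (ph in c(1L, 9L)) {
    sel <- tr$phase_index == ph - 1L
    o <- order(tr$ti_ms[sel])
    want <- abs(tr$signal[sel][o])
    got <- vapply(seq_len(6), function(j)
      mean(stack$data[ph, j, , ][masks$blood]), numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("noise handling: seed guard, determinism, Rician magnitude", {
  plan <- default_plan(bpm = 60)
  spec <- small_sphere_spec(noise_sd = 0.002)
  expect_error(generate_stack(spec, plan), "seed")
  s1 <- generate_stack(spec, plan, n_repetitions = 2, seed = 5)
  s2 <- generate_stack(spec, plan, n_repetitions = 2, seed = 5)
  expect_identical(s1[[1]]$data, s2[[1]]$data)
  expect_false(identical(s1[[1]]$data, s1[[2]]$data))
  expect_true(all(s1[[1]]$data >= 0))
  # zero noise: repetitions bit-identical
  z <- generate_stack(small_sphere_spec(), plan, n_repetitions = 2)
  expect_identical(z[[1]]$data, z[[2]]$data)
})

test_that("ideal signal model reproduces the closed-form model exactly", {
  plan <- default_plan(bpm = 60)
  spec <- small_sphere_spec()
  stack <- generate_stack(spec, plan, signal_model = "ideal")[[1]]
  a_ref <- pulsed_steady_state(489, 3, 5) * sin(3 * pi / 180)
  t1s <- apparent_t1(489, 3, 5)
  masks <- phantom_masks(spec)
  for (ph in c(1L, 5L)) {
    got <- vapply(seq_len(6), function(j)
      mean(stack$data[ph, j, , ][masks$blood]), numeric(1))
    expect_equal(got, abs(model_ir(plan$ti_matrix[ph, ], a_ref, t1s)),
                 tolerance = 1e-12)
  }
})

test_that("per-phase label maps (contraction) are honored", {
  plan <- plan_acquisition(sequence_params(),
                           timing_from_bpm(60, phase_duration_ms = 200))
  n_ph <- plan$timing$n_phases
  spec <- phantom_cardiac(n = 32, r_blood = 5, r_epi = 9, scar_angle_deg = 0,
                          contraction = 0.2, n_phases = n_ph)
  stack <- generate_stack(spec, plan)[[1]]
  # systolic phases have fewer myocardial voxels than phase 0
  n_myo <- vapply(seq_len(n_ph), function(p)
    sum(stack$data[p, 1, , ] > 0), numeric(1))
  expect_lt(n_myo[ceiling(n_ph / 2)], n_myo[1])
})
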