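test_that("whole-cell current vanishes without agonist or driving force", {
  sch <- sat_scheme()
  rc <- recording_config(noise_sd_pA = 1, seed = 3)
  vp <- make_ramp_protocol("up", sample_rate = 500)
  tr0 <- simulate_whole_cell(sch, vp, make_constant_solution(0, 0), rc,
                             seed = 5)
  expect_lt(abs(mean(tr0$current_pA)), 3 * 1 / sqrt(nrow(tr0)))
  ## V == E_rev: noise only
  vph <- make_hold_protocol(0, 1, sample_rate = 500)
  trh <- simulate_whole_cell(sch, vph, make_constant_solution(100, 0), rc,
                             seed = 6)
  expect_lt(abs(mean(trh$current_pA)), 3 * 1 / sqrt(nrow(trh)))
  expect_lt(sd(trh$current_pA), 1.2)
})

test_that("long fixed-voltage simulation relaxes to the analytic equilibrium", {
  sch <- build_block_scheme(1, gating_params(beta_max = 900, alpha = 250),
                            block_params(1, Kd0 = 60, delta = 0.5))
  vph <- make_hold_protocol(-40, 1.5, sample_rate = 400)
  tr <- simulate_whole_cell(sch, vph, make_constant_solution(50, 80),
                            quiet_config(), seed = 2)
  p_final <- attr(tr, "p_final")
  occ <- equilibrium_occupancy(sch, -40, 50, 80)
  expect_equal(unname(p_final), occ$p, tolerance = 1e-4)
})

test_that("single-channel dwell times follow the generator rates", {
  alpha <- 200
  sch <- build_block_scheme(1, gating_params(beta_max = 2e4, alpha = alpha,
                                             EC50_gate = 1),
                            block_params(1, Kd0 = 1e9, delta = 0))
  rc <- recording_config(noise_sd_pA = 0.3)
  sim <- simulate_single_channel(sch, -30, 1000, 0, duration = 15, rc,
                                 seed = 42)
  op <- sim$events[sim$events$class == "open", ]
  expect_gt(nrow(op), 1000)
  se <- (1 / alpha) / sqrt(nrow(op))
  expect_lt(abs(mean(op$duration_s) - 1 / alpha), 1.96 * se * 1.3)
  ## open-channel amplitude at -30 mV is the configured unitary current
  expect_equal(abs(unique(op$amplitude_pA)), 2.8, tolerance = 1e-9)
})

test_that("blocked sojourn mean equals 1/koff at the holding potential", {
  koff0 <- 400
  sch <- sat_scheme(delta = 0.5, Kd0 = 50, koff0 = koff0)
  V <- -40
  rc <- recording_config(noise_sd_pA = 0)
  sim <- simulate_single_channel(sch, V, 1e5, 200, duration = 8, rc,
                                 seed = 7)
  blocked <- sim$events[sim$events$state == "OB", ]
  koff_v <- koff0 * exp(-(1 - 0.5) * 0.5 * V / phys_constants()$RT_F_mV)
  expect_gt(nrow(blocked), 300)
  se <- (1 / koff_v) / sqrt(nrow(blocked))
  expect_lt(abs(mean(blocked$duration_s) - 1 / koff_v), 2.5 * se)
})

test_that("stochastic state-time fractions match the stationary distribution", {
  sch <- build_block_scheme(1, gating_params(beta_max = 600, alpha = 300,
                                             EC50_gate = 30),
                            block_params(1, Kd0 = 80, delta = 0.4))
  sim <- simulate_single_channel(sch, 40, 60, 120, duration = 60,
                                 recording_config(noise_sd_pA = 0), seed = 9)
  obs <- tapply(sim$events$duration_s, sim$events$state, sum)
  obs <- obs / sum(obs)
  occ <- equilibrium_occupancy(sch, 40, 60, 120)
  exp_p <- setNames(occ$p, occ$state)[names(obs)]
  expect_true(all(abs(obs - exp_p) / exp_p < 0.10))
})

test_that("cohorts regenerate identically from the same seed", {
  sch <- sat_scheme()
  rc <- recording_config(noise_sd_pA = 2, amp_noise_cv = 0.05, seed = 21)
  co1 <- generate_cohort(2, sch, c(30, 100), c(-80, 80), rc,
                         sample_rate = 250)
  co2 <- generate_cohort(2, sch, c(30, 100), c(-80, 80), rc,
                         sample_rate = 250)
  expect_identical(co1$cells, co2$cells)
  for (k in seq_len(nrow(co1$sweeps))) {
    expect_identical(co1$sweeps$trace[[k]]$current_pA,
                     co2$sweeps$trace[[k]]$current_pA)
  }
  expect_error(generate_cohort(0, sch, 30, -80, rc), ">= 1")
  expect_error(generate_cohort(2, sch, numeric(0), -80, rc), "non-empty")
})

test_that("noise-free cohort recovers the analytic Kd(V) through the fits", {
  sch <- sat_scheme(delta = 0.4, Kd0 = 60)
  rc <- quiet_config(seed = 5)
  vg <- c(-80, -30, 30, 80)
  co <- generate_cohort(1, sch, c(6, 20, 60, 200, 600), vg, rc,
                        glycine = 1000, sample_rate = 500)
  ic <- ic50_voltage_table(cohort_dose_table(co), vgrid = vg)
  kd <- woodhull_kd(60, 0.4, ic$voltage_mV)
  expect_equal(ic$IC50, kd, tolerance = 1e-3)
  expect_equal(ic$nH, rep(1, nrow(ic)), tolerance = 0.02)
})
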