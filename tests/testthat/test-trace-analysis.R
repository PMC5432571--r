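make_long_trace <- function(scheme, conc, V_hold = 30, glycine = 1e5,
                            noise = 0.5, seed = 4) {
  lp <- make_long_protocol(glycine, conc)
  vp <- make_hold_protocol(V_hold, protocol_duration(lp), sample_rate = 200)
  simulate_whole_cell(scheme, vp, lp,
                      recording_config(noise_sd_pA = noise, seed = seed),
                      seed = seed)
}

test_that("percent inhibition is zero without blocker and 50% at Kd", {
  sch <- sat_scheme(delta = 0.5, Kd0 = 100)
  lp <- make_long_protocol(1e5, 0)
  m0 <- measure_inhibition_long(make_long_trace(sch, 0), lp)
  expect_lt(abs(m0$percent_inhibition), 2)
  kd30 <- woodhull_kd(100, 0.5, 30)
  m1 <- measure_inhibition_long(make_long_trace(sch, kd30), lp)
  expect_equal(m1$percent_inhibition, 50, tolerance = 2 / 50)
})

test_that("percent inhibition is invariant under uniform gain rescaling", {
  sch <- sat_scheme(delta = 0.5, Kd0 = 100)
  tr <- make_long_trace(sch, 150, noise = 0)
  m <- measure_inhibition_long(tr)
  tr2 <- tr
  tr2$current_pA <- tr2$current_pA * 3.7
  m2 <- measure_inhibition_long(tr2)
  expect_equal(m2$percent_inhibition, m$percent_inhibition, tolerance = 1e-12)
})

test_that("a flat zero trace has no reference current", {
  flat <- structure(
    tibble::tibble(time_s = seq(0, 17, by = 0.01),
                   current_pA = rnorm(1701, 0, 0.5),
                   voltage_mV = 30),
    sample_rate = 100, noise_sd_pA = 0.5,
    class = c("current_trace", "tbl_df", "tbl", "data.frame")
  )
  expect_error(measure_inhibition_long(flat), "no reference current")
})

ramp_pair <- function(scheme, conc, config, glycine = 1e5, seed = 11) {
  lapply(c("up", "down"), function(dir) {
    vp <- make_ramp_protocol(dir, sample_rate = 500)
    list(
      control = simulate_whole_cell(scheme, vp,
                                    make_constant_solution(glycine, 0, 2),
                                    config, seed = seed + (dir == "down")),
      drug = simulate_whole_cell(scheme, vp,
                                 make_constant_solution(glycine, conc, 2),
                                 config, seed = seed + 2 + (dir == "down"))
    )
  })
}

test_that("fraction remaining is 1 when drug equals control", {
  sch <- sat_scheme()
  vp <- make_ramp_protocol("up", sample_rate = 500)
  tr <- simulate_whole_cell(sch, vp, make_constant_solution(1e5, 0, 2),
                            quiet_config(), seed = 1)
  fr <- ramp_fraction_remaining(tr, tr, min_abs_current = 5)
  expect_true(all(abs(fr$fraction - 1) < 1e-12))
})

test_that("noise-free ramp fraction matches the blocking isotherm", {
  sch <- sat_scheme(delta = 0.5, Kd0 = 100)
  pr <- ramp_pair(sch, 100, quiet_config())
  fr <- ramp_fraction_remaining(
    list(pr[[1]]$control, pr[[2]]$control),
    list(pr[[1]]$drug, pr[[2]]$drug),
    min_abs_current = 5
  )
  kd <- woodhull_kd(100, 0.5, fr$voltage_mV)
  expect_equal(fr$fraction, 1 / (1 + 100 / kd), tolerance = 1e-3)
})

test_that("grid points near the reversal potential are masked", {
  sch <- sat_scheme()
  pr <- ramp_pair(sch, 100, recording_config(noise_sd_pA = 2, seed = 2))
  fr <- ramp_fraction_remaining(pr[[1]]$control, pr[[1]]$drug)
  expect_false(0 %in% fr$voltage_mV)
  expect_true(all(abs(fr$i_control_pA) >= attr(fr, "min_abs_current")))
})

test_that("mismatched protocols are rejected", {
  sch <- sat_scheme()
  up <- simulate_whole_cell(sch, make_ramp_protocol("up", 500),
                            make_constant_solution(1e5, 0, 2), quiet_config())
  dn <- simulate_whole_cell(sch, make_ramp_protocol("down", 500),
                            make_constant_solution(1e5, 0, 2), quiet_config())
  expect_error(ramp_fraction_remaining(up, dn), "mismatch")
})

test_that("rectification index separates ohmic, outward and inward channels", {
  rc <- recording_config(noise_sd_pA = 0.5, seed = 8)
  mk <- function(slope) {
    g <- gating_params(beta_max = 5e4, alpha = 5, EC50_gate = 1,
                       rect_slope = slope)
    sch <- build_block_scheme(1, g, block_params(1, Kd0 = 1e9, delta = 0))
    simulate_whole_cell(sch, make_ramp_protocol("up", 500),
                        make_constant_solution(1e5, 0, 2), rc, seed = 3)
  }
  expect_equal(rectification_index(mk(Inf)), 1, tolerance = 0.05)
  expect_gt(rectification_index(mk(40)), 1.2)     # outward
  expect_lt(rectification_index(mk(-40)), 0.8)    # inward
})

test_that("quality filter applies the input-resistance and run-down rules", {
  cells <- tibble::tibble(
    cell = c("a", "b", "c", "d"),
    Rin_MOhm = c(200, 100, 300, NA),
    run_down = c(0.10, 0.10, 0.35, 0.05)
  )
  qf <- quality_filter(cells)
  expect_identical(qf$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(qf$reason[2], "low_input_resistance")
  expect_identical(qf$reason[3], "run_down")
  expect_identical(qf$reason[4], "unmeasured")
})
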