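square_trace <- function(levels_pA, dwell_s, sample_rate = 10000, noise = 0,
                         seed = 1) {
  set.seed(seed)
  I <- rep(levels_pA, times = round(dwell_s * sample_rate))
  if (noise > 0) I <- I + rnorm(length(I), 0, noise)
  structure(
    tibble::tibble(time_s = seq_along(I) / sample_rate, current_pA = I,
                   voltage_mV = -30),
    sample_rate = sample_rate, noise_sd_pA = max(noise, 0.05),
    class = c("current_trace", "tbl_df", "tbl", "data.frame")
  )
}

test_that("idealization recovers clean square-wave events exactly", {
  dw <- c(0.010, 0.005, 0.020, 0.008, 0.015)
  lv <- c(0, -2.8, 0, -2.8, 0)
  tr <- square_trace(lv, dw)
  ev <- idealize(tr, baseline_pA = 0, open_amplitude_pA = -2.8)
  expect_identical(ev$level, c("shut", "open", "shut", "open", "shut"))
  expect_equal(ev$duration_s, dw, tolerance = 1e-9)
  ## all-baseline trace: no events
  ev0 <- idealize(square_trace(0, 0.05), 0, -2.8)
  expect_identical(nrow(ev0), 0L)
  ## inseparable levels rejected
  expect_error(idealize(square_trace(c(0, -0.5, 0), c(0.01, 0.01, 0.01),
                                     noise = 0.4), 0, -0.5),
               "not separable")
})

test_that("idealization of a noisy trace agrees with the generating events", {
  sch <- sat_scheme(delta = 0, Kd0 = 1e9)   # plain gating, no block
  rc <- recording_config(noise_sd_pA = 2.8 / 5)   # SNR 5
  sim <- simulate_single_channel(sch, -30, 1e5, 0, duration = 4, rc,
                                 seed = 31, sample_rate = 20000)
  ev <- idealize(sim$trace, 0, attr(sim$trace, "i_open_pA"))
  open_time_est <- sum(ev$duration_s[ev$level == "open"])
  open_time_true <- sum(sim$events$duration_s[sim$events$class == "open"])
  expect_lt(abs(open_time_est - open_time_true) / open_time_true, 0.05)
})

test_that("maximum-likelihood dwell fits recover rates", {
  set.seed(5)
  x <- rexp(500, 120)
  f1 <- fit_dwell_exponentials(x, 1)
  expect_equal(f1$rate, 1 / mean(x), tolerance = 1e-12)   # ML closed form
  ## two-component mixture: tau 1 ms and 50 ms, weights 0.7/0.3
  set.seed(8)
  n <- 2000
  comp <- runif(n) < 0.7
  x2 <- ifelse(comp, rexp(n, 1000), rexp(n, 20))
  f2 <- fit_dwell_exponentials(x2, 2)
  expect_lt(abs(f2$tau_s[1] - 0.001) / 0.001, 0.15)
  expect_lt(abs(f2$tau_s[2] - 0.050) / 0.050, 0.15)
  expect_lt(abs(f2$weight[1] - 0.7), 0.1)
  expect_error(fit_dwell_exponentials(numeric(0)), "no positive")
  expect_error(fit_dwell_exponentials(rexp(30, 1), 1), "at least 50")
  expect_error(fit_dwell_exponentials(rep(0.01, 300), 1), "degenerate")
})

test_that("the equal-misclassification t_crit balances the two components", {
  fit <- tibble::tibble(component = 1:2, rate = c(1000, 20),
                        tau_s = c(0.001, 0.05), weight = c(0.7, 0.3))
  tc <- t_crit_equal_misclass(fit)
  lhs <- 0.7 * exp(-1000 * tc)
  rhs <- 0.3 * (1 - exp(-20 * tc))
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_gt(tc, 0.001)
  expect_lt(tc, 0.05)
})

test_that("burst detection separates flicker gaps from inter-burst gaps", {
  ## no closings: one burst
  ev1 <- tibble::tibble(level = "open", duration_s = 0.5,
                        amplitude_pA = -2.8)
  b1 <- detect_bursts(ev1, t_crit = 0.01)
  expect_identical(nrow(b1), 1L)
  ## all gaps much longer than t_crit: every opening is its own burst
  ev2 <- tibble::tibble(
    level = rep(c("open", "shut"), 5),
    duration_s = rep(c(0.01, 1), 5)
  )
  b2 <- detect_bursts(ev2, t_crit = 0.05)
  expect_identical(nrow(b2), 5L)
  expect_true(all(b2$n_flicker_gaps == 0))
})

## slow gating, fast flicker: closed sojourns (0.5 s) are far longer than
## blocked sojourns (2 ms), the regime in which burst analysis is meaningful
flicker_scheme <- function(Kd0 = 250, koff0 = 500) {
  build_block_scheme(1, gating_params(beta_max = 2, alpha = 5, EC50_gate = 1),
                     block_params(1, Kd0 = Kd0, delta = 0, koff0 = koff0))
}

test_that("burst count of simulated flicker block matches the ground truth", {
  ## kon*c = 200/s, koff = 500/s
  sch <- flicker_scheme()   # kon0 = 2 /uM/s
  sim <- simulate_single_channel(sch, 0, 1e5, 100, duration = 40,
                                 recording_config(noise_sd_pA = 0), seed = 13)
  ## ground truth: bursts are openings separated by closed (C) sojourns
  st <- sim$events$state
  truth_bursts <- sum(st == "C" & c(FALSE, head(st, -1) != "C"))
  bt <- detect_bursts(sim$events, t_crit = 0.02)
  expect_lt(abs(nrow(bt) - truth_bursts) / truth_bursts, 0.10)
})

test_that("block rates are recovered from burst structure", {
  ## reciprocal identity on a crafted burst table
  crafted <- structure(
    tibble::tibble(burst = 1L, start_s = 0, end_s = 1, n_openings = 40L,
                   open_time_s = 0.4, n_flicker_gaps = 39L,
                   mean_flicker_gap_s = 0.002),
    class = c("burst_table", "tbl_df", "tbl", "data.frame")
  )
  est0 <- estimate_block_rates(crafted, blocker = 100)
  expect_equal(est0$koff_per_s, 500, tolerance = 1e-12)
  expect_error(estimate_block_rates(crafted, blocker = 0), "no blocker")

  sch <- flicker_scheme()   # kon0 = 2 /uM/s
  sim <- simulate_single_channel(sch, 0, 1e5, 100, duration = 40,
                                 recording_config(noise_sd_pA = 0), seed = 17)
  est <- estimate_block_rates(detect_bursts(sim$events, t_crit = 0.02), 100)
  expect_lt(abs(est$koff_per_s - 500) / 500, 0.20)
  expect_lt(abs(est$kon_per_uM_s - 2) / 2, 0.20)
})

test_that("koff is concentration-independent while flicker frequency scales", {
  sch <- flicker_scheme()
  res <- purrr::map(c(30, 100, 300), function(conc) {
    sim <- simulate_single_channel(sch, 0, 1e5, conc, duration = 50,
                                   recording_config(noise_sd_pA = 0),
                                   seed = 19 + conc)
    bt <- detect_bursts(sim$events, t_crit = 0.02)
    est <- estimate_block_rates(bt, conc)
    dplyr::mutate(est, conc = conc,
                  flicker_per_open_s = n_gaps / open_time_s)
  }) |> purrr::list_rbind()
  ## koff estimates agree within joint CI across a 10-fold range
  se <- res$koff_per_s / sqrt(res$n_gaps)
  expect_true(all(abs(res$koff_per_s - 500) < 3 * se + 0.05 * 500))
  ## kon (concentration-normalised flicker frequency) stays put
  expect_lt(diff(range(res$kon_per_uM_s)) / mean(res$kon_per_uM_s), 0.3)
  ## raw flicker frequency grows monotonically with concentration
  expect_true(all(diff(res$flicker_per_open_s) > 0))
})
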