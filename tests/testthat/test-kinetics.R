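test_that("thermal voltage RT/F matches its defining constants", {
  expect_equal(phys_constants()$RT_F_mV, 25.43, tolerance = 0.01 / 25.43)
  expect_error(phys_constants(-1), "positive")
})

test_that("Woodhull Kd(V) follows the exponential voltage dependence", {
  expect_identical(woodhull_kd(100, 0.65, 0), 100)
  expect_equal(woodhull_kd(100, 0.65, 80), 12.95, tolerance = 0.05 / 12.95)
  expect_equal(woodhull_kd(100, 0.16, -80), 165.4, tolerance = 0.5 / 165.4)
  kd <- woodhull_kd(100, 0.4, seq(-80, 80, by = 10))
  expect_true(all(diff(kd) < 0))            # strictly decreasing for delta > 0
  expect_error(woodhull_kd(100, 1.5, 0), "delta")
  expect_error(woodhull_kd(-5, 0.5, 0), "Kd0")
  expect_error(woodhull_kd(100, 0.5, NaN), "finite")
})

test_that("block schemes have the expected states and conductances", {
  s1 <- sat_scheme(n_sites = 1)
  expect_identical(s1$states$state, c("C", "O", "OB"))
  expect_identical(sum(s1$states$g == 0), 2L)   # C and exactly one blocked state
  s2 <- sat_scheme(n_sites = 2, g2 = 1)
  expect_identical(s2$states$state, c("C", "O", "OB", "OB2"))
  expect_identical(s2$states$g[s2$states$state == "OB"], 1)
  expect_identical(sum(s2$states$g == 0), 2L)   # only C and OB2 non-conducting
  expect_error(build_block_scheme(3, gating_params(), block_params(1)), "1 or 2")
  sd3 <- build_block_scheme(1, gating_params(desens_rate = 2),
                            block_params(1))
  expect_true("D" %in% sd3$states$state)
})

test_that("stationary occupancies solve the master equation", {
  ## symmetric gating: p(O) = 0.5 when opening and closing rates are equal
  sch <- build_block_scheme(1, gating_params(beta_max = 150, alpha = 150,
                                             EC50_gate = 1),
                            block_params(1, Kd0 = 100, delta = 0))
  occ <- equilibrium_occupancy(sch, V = 0, agonist = 1e7, blocker = 0)
  ## opening rate is beta_max * h with h = 1e7/(1e7 + 1); expect exactly that
  h <- 1e7 / (1e7 + 1)
  expect_equal(occ$p[occ$state == "O"], 150 * h / (150 + 150 * h),
               tolerance = 1e-9)
  expect_equal(sum(occ$p), 1, tolerance = 1e-10)

  ## blocker at Kd: blocked and open states equally occupied
  sch2 <- sat_scheme(delta = 0.65, Kd0 = 100)
  kd <- woodhull_kd(100, 0.65, 50)
  occ2 <- equilibrium_occupancy(sch2, V = 50, agonist = 1e5, blocker = kd)
  expect_equal(occ2$p[occ2$state == "OB"] / occ2$p[occ2$state == "O"], 1,
               tolerance = 1e-9)
})

test_that("stationary solve agrees with an independent eigen-decomposition", {
  sch <- build_block_scheme(
    2, gating_params(beta_max = 800, alpha = 300, EC50_gate = 40),
    block_params(2, Kd0 = c(150, 30), delta = 0.4, koff0 = c(700, 400))
  )
  for (cond in list(c(-60, 30, 50), c(40, 100, 300), c(0, 20, 80))) {
    Q <- rate_matrix(sch, cond[1], cond[2], cond[3])
    ev <- eigen(t(Q))
    k <- which.min(abs(ev$values))
    p_oracle <- Re(ev$vectors[, k])
    p_oracle <- p_oracle / sum(p_oracle)
    occ <- equilibrium_occupancy(sch, cond[1], cond[2], cond[3])
    expect_equal(occ$p, p_oracle, tolerance = 1e-8)
  }
})

test_that("fraction of current follows the open-channel block isotherms", {
  sch <- sat_scheme(delta = 0.65, Kd0 = 100)
  expect_equal(fraction_current(sch, 0, 1e5, 0), 1)
  expect_equal(fraction_current(sch, 0, 1e5, 100), 0.5, tolerance = 1e-4)
  ## two-site enumeration: (1 + c/K1) / (1 + c/K1 + c^2/(K1 K2))
  s2 <- build_block_scheme(2, sat_gating(),
                           block_params(2, Kd0 = c(1000, 10), delta = 0,
                                        g_singly_blocked = 1))
  expect_equal(fraction_current(s2, 0, 1e5, 100), 0.5238,
               tolerance = 5e-4)
})

test_that("fraction of current is non-increasing in blocker at every voltage", {
  sch <- build_block_scheme(1, gating_params(),
                            block_params(1, Kd0 = 60, delta = 0.5))
  for (V in c(-80, -30, 0, 40, 80)) {
    f <- fraction_current(sch, V, 30, c(0, 1, 10, 50, 200, 1000, 5000))
    expect_true(all(diff(f) <= 1e-12))
    expect_equal(f[1], 1)
  }
})

test_that("apparent IC50 equals Kd(V) scaled by the gating ratio", {
  ## with a resting state in the scheme, f = 1/(1 + c / (Kd (1 + alpha/beta)))
  g <- gating_params(beta_max = 4000, alpha = 100, EC50_gate = 34)
  sch <- build_block_scheme(1, g, block_params(1, Kd0 = 80, delta = 0.3))
  r <- g$alpha / (g$beta_max * 30 / (30 + 34))
  for (V in c(-60, 0, 60)) {
    kapp <- woodhull_kd(80, 0.3, V) * (1 + r)
    cgrid <- kapp * c(0.2, 1, 5)
    f <- fraction_current(sch, V, 30, cgrid)
    expect_equal(f, 1 / (1 + cgrid / kapp), tolerance = 1e-9)
  }
})

test_that("kinetic schemes survive a JSON round trip", {
  sch <- build_block_scheme(
    2, gating_params(beta_max = 900, alpha = 150, rect_slope = 35),
    block_params(2, Kd0 = c(400, 50), delta = 0.25, koff0 = 600,
                 voltage_split = 0.3, g_singly_blocked = 0.7)
  )
  sch2 <- scheme_from_json(scheme_to_json(sch))
  expect_equal(rate_matrix(sch2, -45, 60, 120), rate_matrix(sch, -45, 60, 120))
  expect_identical(sch2$states, sch$states)
})
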