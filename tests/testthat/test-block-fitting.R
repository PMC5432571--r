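test_that("Hill inhibition fit is exact on its own model family", {
  cc <- 10^seq(0, 2.5, length.out = 6)
  f <- 1 / (1 + (cc / 50)^1)
  ft <- fit_hill_inhibition(cc, f)
  expect_true(ft$converged)
  expect_equal(ft$c50, 50, tolerance = 1e-6)
  expect_equal(ft$nH, 1, tolerance = 1e-6)
  ## half inhibition at the fitted IC50, by construction of the curve
  expect_equal(predict(ft, ft$c50), 0.5, tolerance = 1e-12)
})

test_that("Hill activation fit recovers EC50 and the half-maximal response", {
  cc <- 10^seq(0, 3, length.out = 7)
  resp <- 850 / (1 + (34 / cc)^1.4)
  ft <- fit_hill_activation(cc, resp)
  expect_equal(ft$c50, 34, tolerance = 1e-6)
  expect_equal(ft$nH, 1.4, tolerance = 1e-6)
  expect_equal(ft$Imax, 850, tolerance = 1e-6)
  expect_equal(predict(ft, 34), 850 / 2, tolerance = 1e-6)
})

test_that("noisy activation data recover EC50 within 15%", {
  set.seed(2024)
  cc <- rep(10^seq(0.3, 2.7, length.out = 8), 8)   # 8 replicates
  resp <- 1000 / (1 + (34 / cc)^1.5) * rlnorm(length(cc), 0, 0.05)
  ft <- fit_hill_activation(cc, resp)
  expect_lt(abs(ft$c50 - 34) / 34, 0.15)
})

test_that("two-site block with a conducting singly-occupied state gives nH near 2", {
  s2 <- build_block_scheme(2, sat_gating(),
                           block_params(2, Kd0 = c(1000, 10), delta = 0,
                                        g_singly_blocked = 1))
  cc <- 10^seq(0, 3.5, length.out = 9)
  f <- fraction_current(s2, 0, 1e5, cc)
  ft <- fit_hill_inhibition(cc, f)
  expect_gt(ft$nH, 1.5)
  expect_lte(ft$nH, 2)
})

test_that("fitted IC50 is scale-equivariant and nH scale-invariant", {
  cc <- 10^seq(0, 2.5, length.out = 7)
  f <- 1 / (1 + (cc / 30)^1.6)
  f1 <- fit_hill_inhibition(cc, f)
  f2 <- fit_hill_inhibition(cc * 7.3, f)
  expect_equal(f2$c50 / f1$c50, 7.3, tolerance = 1e-6)
  expect_equal(f2$nH, f1$nH, tolerance = 1e-6)
})

test_that("least squares agrees with a brute-force grid search oracle", {
  set.seed(77)
  lgrid <- seq(log(2), log(400), length.out = 200)
  ngrid <- seq(0.3, 3, length.out = 200)
  cc <- 10^seq(0, 2.8, length.out = 8)
  for (k in 1:20) {
    ic50 <- exp(runif(1, log(5), log(200)))
    nh <- runif(1, 0.6, 2.2)
    f <- pmax(0, pmin(1.2, 1 / (1 + (cc / ic50)^nh) + rnorm(8, 0, 0.03)))
    rss <- outer(lgrid, ngrid, function(l, n) {
      vapply(seq_along(l), function(i) {
        sum((f - 1 / (1 + (cc / exp(l[i]))^n[i]))^2)
      }, 0)
    })
    ix <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    ft <- fit_hill_inhibition(cc, f)
    expect_lt(abs(log(ft$c50) - lgrid[ix[1]]), diff(lgrid[1:2]) * 1.5)
    expect_lt(abs(ft$nH - ngrid[ix[2]]), diff(ngrid[1:2]) * 1.5)
  }
})

test_that("per-voltage fits reproduce Kd(V) from noise-free isotherms", {
  vg <- c(-80, -70, -50, -30, 30, 50, 70, 80)
  cc <- c(3, 10, 30, 100, 300, 1000)
  tab <- tidyr::expand_grid(cell = "c1", voltage_mV = vg, conc_uM = cc) |>
    dplyr::mutate(fraction = 1 / (1 + conc_uM / woodhull_kd(40, 0.65, voltage_mV)))
  ic <- ic50_voltage_table(tab, vgrid = vg)
  expect_equal(ic$IC50, woodhull_kd(40, 0.65, ic$voltage_mV), tolerance = 1e-3)
  expect_equal(ic$nH, rep(1, 8), tolerance = 0.02)
  expect_error(ic50_voltage_table(tab[0, ], vgrid = vg), "empty")
  expect_warning(
    ic50_voltage_table(tab[tab$conc_uM < 15 | tab$voltage_mV != -80, ],
                       vgrid = vg),
    "fewer than 3"
  )
})

test_that("stoichiometry heuristic follows the Hill coefficient", {
  flat1 <- tibble::tibble(voltage_mV = c(-80, 0, 80), nH = c(1, 1, 1),
                          converged = TRUE)
  expect_identical(infer_stoichiometry(flat1)$n_sites, 1L)
  ## two-site generator: fitted nH across voltages
  s2 <- build_block_scheme(2, sat_gating(),
                           block_params(2, Kd0 = c(400, 20), delta = 0.3,
                                        g_singly_blocked = 1))
  cc <- 10^seq(0, 3.2, length.out = 8)
  nh <- vapply(c(-60, 0, 60), function(V) {
    fit_hill_inhibition(cc, fraction_current(s2, V, 1e5, cc))$nH
  }, 0)
  expect_identical(infer_stoichiometry(nh)$n_sites, 2L)
  ## boundary: mean exactly at the threshold resolves to one site
  expect_identical(infer_stoichiometry(c(1.3, 1.3, 1.3))$n_sites, 1L)
  expect_true(is.na(infer_stoichiometry(c(1.5, 1.2))$n_sites))
})
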