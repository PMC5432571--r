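test_that("Woodhull regression recovers delta exactly on noise-free data", {
  vv <- c(-80, -50, -20, 20, 50, 80)
  rtf <- phys_constants()$RT_F_mV
  tb <- tibble::tibble(voltage_mV = vv, IC50 = 77 * exp(-0.65 * vv / rtf))
  ft <- fit_woodhull(tb)
  expect_equal(ft$delta, 0.65, tolerance = 1e-10)
  expect_equal(ft$IC50_0, 77, tolerance = 1e-10)
  ## constant IC50: no voltage dependence
  ft0 <- fit_woodhull(tibble::tibble(voltage_mV = vv, IC50 = rep(50, 6)))
  expect_equal(ft0$delta, 0, tolerance = 1e-12)
  ## nonlinear variant agrees on exact data
  ftn <- fit_woodhull(tb, method = "nonlinear")
  expect_equal(ftn$delta, 0.65, tolerance = 1e-6)
  expect_error(fit_woodhull(tb[1, ]), "2 distinct voltages")
  expect_error(fit_woodhull(dplyr::mutate(tb, IC50 = -IC50)), "positive")
})

test_that("two-point closed form reproduces the printed voltage pairs", {
  ## deep-site receptor: IC50 166 uM at -80 mV vs 9 uM at +80 mV
  d_deep <- two_point_delta(166, -80, 9, 80)
  expect_equal(d_deep, 0.463, tolerance = 0.002 / 0.463)
  ft <- fit_woodhull(tibble::tibble(voltage_mV = c(-80, 80), IC50 = c(166, 9)))
  expect_equal(ft$IC50_0, 38.6, tolerance = 0.5 / 38.6)
  ## shallow-site receptor: 315 uM at -80 mV vs 197 uM at +80 mV
  expect_equal(two_point_delta(315, -80, 197, 80), 0.0745,
               tolerance = 0.001 / 0.0745)
  ## symmetry and identity
  expect_equal(two_point_delta(9, 80, 166, -80), d_deep)
  expect_equal(two_point_delta(100, -50, 100, 70), 0)
  expect_error(two_point_delta(100, 30, 50, 30), "differ")
})

test_that("regression on two points equals the closed form", {
  ft <- fit_woodhull(tibble::tibble(voltage_mV = c(-60, 40),
                                    IC50 = c(210, 35)))
  expect_equal(ft$delta, two_point_delta(210, -60, 35, 40), tolerance = 1e-12)
})

test_that("delta is invariant under rescaling all IC50 values", {
  vv <- c(-80, -30, 30, 80)
  tb <- tibble::tibble(voltage_mV = vv, IC50 = 50 * exp(-0.3 * vv / 25.434))
  f1 <- fit_woodhull(tb)
  f2 <- fit_woodhull(dplyr::mutate(tb, IC50 = IC50 * 13))
  expect_equal(f2$delta, f1$delta, tolerance = 1e-12)
})

test_that("per-cell aggregation reports mean, SEM and n", {
  ag <- aggregate_delta(c(0.1, 0.2, 0.3))
  expect_equal(ag$mean_delta, 0.2)
  expect_equal(ag$sem_delta, 0.0577, tolerance = 1e-3)
  expect_identical(ag$n, 3L)
  expect_equal(aggregate_delta(c(0.4, 0.4, 0.4))$sem_delta, 0)
  expect_true(is.na(aggregate_delta(0.25)$sem_delta))
  expect_error(aggregate_delta(numeric(0)), "no finite")
})

test_that("aggregated delta covers the truth in most seeded replicates", {
  ## 25-cell cohorts keep the +-2*SEM band near its nominal coverage (with
  ## few cells the Student-t correction alone drops coverage below 90%);
  ## 50 seeded replicates per generating depth, pooled across depths
  rtf <- phys_constants()$RT_F_mV
  vv <- c(-80, -70, -50, -30, 30, 50, 70, 80)
  hits <- 0L
  total <- 0L
  for (truth in c(0.16, 0.37, 0.65)) {
    set.seed(round(1000 * truth))
    for (rep in 1:50) {
      per_cell <- vapply(1:25, function(cell) {
        ic50 <- 60 * exp(-truth * vv / rtf) * rlnorm(length(vv), 0, 0.10)
        fit_woodhull(tibble::tibble(voltage_mV = vv, IC50 = ic50))$delta
      }, 0)
      ag <- aggregate_delta(per_cell)
      total <- total + 1L
      if (abs(ag$mean_delta - truth) <= 2 * ag$sem_delta) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("tidy and glance expose the fit in broom style", {
  ft <- fit_woodhull(tibble::tibble(voltage_mV = c(-80, 0, 80),
                                    IC50 = c(100, 40, 16)))
  td <- tidy(ft)
  expect_identical(td$term, c("delta", "IC50_0"))
  expect_identical(nrow(glance(ft)), 1L)
})
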