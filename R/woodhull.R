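#' Woodhull fit: fractional electrical distance from IC50(V)
#'
#' Estimates the fractional electrical distance `delta` (measured from the
#' external membrane surface) and the zero-voltage `IC50(0)` from per-voltage
#' IC50 values via the Woodhull relation
#' `IC50(V) = IC50(0) * exp(-delta * F * V / (R * T))`. The default method is
#' ordinary least squares of `log(IC50)` on `V` (the conventional
#' log-linearised "IC50 against membrane potential" plot); a nonlinear fit on
#' the IC50 scale is available for sensitivity analysis.
#'
#' @param ic50_by_voltage Tibble (or data frame) with columns `voltage_mV`
#'   and `IC50` (micromolar), one row per voltage; >= 2 distinct voltages.
#' @param temperature Absolute temperature, kelvin.
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#'
#' @return A `woodhull_fit` object with elements `delta`, `delta_se`,
#'   `IC50_0`, `IC50_0_se`, `temperature`, `n`, `method`.
#' @export
#' @examples
#' d <- tibble::tibble(voltage_mV = c(-80, 80), IC50 = c(166, 9))
#' fit_woodhull(d)$delta
fit_woodhull <- function(ic50_by_voltage, temperature = 295.15,
                         method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  tb <- as_tibble(ic50_by_voltage)
  if (!all(c("voltage_mV", "IC50") %in% names(tb))) {
    abort("`ic50_by_voltage` must have columns `voltage_mV` and `IC50`.")
  }
  tb <- filter(tb, is.finite(.data$voltage_mV), is.finite(.data$IC50))
  if (any(tb$IC50 <= 0)) abort("IC50 values must be positive.")
  if (length(unique(tb$voltage_mV)) < 2L) {
    abort("need at least 2 distinct voltages for a Woodhull fit.")
  }
  rtf <- phys_constants(temperature)$RT_F_mV
  if (method == "loglinear") {
    fit <- lm(log(IC50) ~ voltage_mV, data = tb)
    sl <- coef(fit)[["voltage_mV"]]
    ic <- coef(fit)[["(Intercept)"]]
    if (nrow(tb) > 2) {
      ## exact (zero-residual) fits are legitimate here; lm warns about them
      ses <- suppressWarnings(sqrt(diag(vcov(fit))))
    } else {
      ses <- c(NA_real_, NA_real_)  # exact two-point fit: no residual df
    }
    delta <- -sl * rtf
    out <- list(delta = delta, delta_se = unname(ses[2] * rtf),
                IC50_0 = exp(ic), IC50_0_se = unname(exp(ic) * ses[1]))
  } else {
    obj <- function(par) {
      sum((tb$IC50 - exp(par[2]) * exp(-par[1] * tb$voltage_mV / rtf))^2)
    }
    st <- fit_woodhull(tb, temperature, "loglinear")
    op <- optim(c(st$delta, log(st$IC50_0)), obj, method = "BFGS",
                control = list(reltol = 1e-14))
    out <- list(delta = op$par[1], delta_se = NA_real_,
                IC50_0 = exp(op$par[2]), IC50_0_se = NA_real_)
  }
  structure(c(out, list(temperature = temperature, n = nrow(tb),
                        method = method, data = tb)),
            class = "woodhull_fit")
}

#' @export
print.woodhull_fit <- function(x, ...) {
  cat("<woodhull_fit> delta = ", signif(x$delta, 4),
      ", IC50(0) = ", signif(x$IC50_0, 4), " uM (", x$n, " voltages, ",
      x$method, ")\n", sep = "")
  invisible(x)
}

#' Tidiers for glyrblock fit objects
#'
#' [tidy()] returns one row per parameter with estimates and standard errors;
#' [glance()] returns one-row fit summaries.
#'
#' @param x A `hill_fit` or `woodhull_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_glyrblock
NULL

#' @rdname tidy_glyrblock
#' @export
tidy.woodhull_fit <- function(x, ...) {
  tibble(
    term = c("delta", "IC50_0"),
    estimate = c(x$delta, x$IC50_0),
    std.error = c(x$delta_se, x$IC50_0_se)
  )
}

#' @rdname tidy_glyrblock
#' @export
glance.woodhull_fit <- function(x, ...) {
  tibble(n_voltages = x$n, temperature_K = x$temperature, method = x$method)
}

#' Two-point fractional electrical distance
#'
#' Closed-form Woodhull estimate from IC50 at two potentials:
#' `delta = (RT/F) * log(ic50_a / ic50_b) / (V_b - V_a)`. Symmetric in the
#' two points.
#'
#' @param ic50_a,ic50_b IC50 values, micromolar.
#' @param V_a,V_b The corresponding potentials, mV (`V_a != V_b`).
#' @param temperature Absolute temperature, kelvin.
#' @return The fractional electrical distance (scalar).
#' @export
#' @examples
#' two_point_delta(166, -80, 9, 80)
two_point_delta <- function(ic50_a, V_a, ic50_b, V_b, temperature = 295.15) {
  if (any(!is.finite(c(ic50_a, ic50_b, V_a, V_b))) ||
      ic50_a <= 0 || ic50_b <= 0) {
    abort("IC50 values must be positive and all inputs finite.")
  }
  if (V_a == V_b) abort("the two voltages must differ.")
  rtf <- phys_constants(temperature)$RT_F_mV
  rtf * log(ic50_a / ic50_b) / (V_b - V_a)
}

#' Aggregate per-cell fractional electrical distances
#'
#' Arithmetic mean and standard error of the mean over cells, the standard
#' way per-cell Woodhull estimates are reported. With a single cell the SEM
#' is undefined and reported as `NA`, not zero.
#'
#' @param fits A list of `woodhull_fit` objects, a tibble with a `delta`
#'   column, or a numeric vector of per-cell delta estimates.
#' @return A tibble with `mean_delta`, `sem_delta`, `n`.
#' @export
#' @examples
#' aggregate_delta(c(0.1, 0.2, 0.3))
aggregate_delta <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(map_dbl(fits, ~ inherits(.x, "woodhull_fit")) == 1)) {
    deltas <- map_dbl(fits, "delta")
  } else if (is.data.frame(fits)) {
    if (!"delta" %in% names(fits)) abort("`fits` must have a `delta` column.")
    deltas <- fits$delta
  } else if (is.numeric(fits)) {
    deltas <- fits
  } else {
    abort("`fits` must be woodhull_fit objects, a tibble with `delta`, or numeric.")
  }
  deltas <- deltas[is.finite(deltas)]
  if (length(deltas) == 0) abort("no finite delta estimates to aggregate.")
  n <- length(deltas)
  tibble(
    mean_delta = mean(deltas),
    sem_delta = if (n > 1) sd(deltas) / sqrt(n) else NA_real_,
    n = n
  )
}

#' Per-cell Woodhull fits from an IC50(V) table
#'
#' Convenience wrapper: one [fit_woodhull()] per cell of an
#' [ic50_voltage_table()] result (non-converged Hill rows dropped).
#'
#' @param ic50_table Output of [ic50_voltage_table()].
#' @param temperature Absolute temperature, kelvin.
#' @return A tibble: `cell`, `delta`, `delta_se`, `IC50_0`, `n_voltages`.
#' @export
woodhull_by_cell <- function(ic50_table, temperature = 295.15) {
  tb <- as_tibble(ic50_table)
  if ("converged" %in% names(tb)) tb <- filter(tb, .data$converged)
  tb |>
    group_by(.data$cell) |>
    dplyr::group_modify(function(d, key) {
      ft <- fit_woodhull(d, temperature = temperature)
      tibble(delta = ft$delta, delta_se = ft$delta_se,
             IC50_0 = ft$IC50_0, n_voltages = ft$n)
    }) |>
    ungroup()
}
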