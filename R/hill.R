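#' Fit the Hill inhibition equation to dose-inhibition data
#'
#' Nonlinear least squares of `f = Imax / (1 + (c / IC50)^nH)` to
#' fraction-remaining data. `Imax` is fixed at 1 by default (fractions are
#' already normalised to control). The fit is multi-started over
#' `nH in {0.5, 1, 2}` with a log-parameterised IC50, bounds
#' `nH in [0.2, 4]`, and the best converged start is returned.
#'
#' @param concs Blocker concentrations, micromolar (>= 3 distinct values).
#' @param fractions Fractions remaining, in `[0, 1.2]` (small noise excursions
#'   above 1 are tolerated).
#' @param weights Optional fit weights (e.g. `1/SE^2`); unweighted by default.
#' @param fix_imax Fix `Imax = 1` (default) or fit it.
#' @param nh_bounds Bounds on the Hill coefficient.
#'
#' @return A `hill_fit` object: estimates, standard errors, residual norm and
#'   a convergence flag. Access tidily via [tidy()] / [glance()].
#' @export
#' @examples
#' c6 <- 10^seq(0, 2.5, length.out = 6)
#' f <- 1 / (1 + (c6 / 50)^1)
#' tidy(fit_hill_inhibition(c6, f))
fit_hill_inhibition <- function(concs, fractions, weights = NULL,
                                fix_imax = TRUE, nh_bounds = c(0.2, 4)) {
  fit_hill(concs, fractions, weights, kind = "inhibition",
           fix_imax = fix_imax, nh_bounds = nh_bounds)
}

#' Fit the Hill activation equation to dose-response data
#'
#' Nonlinear least squares of `I = Imax / (1 + (EC50 / c)^nH)` with free
#' `Imax` (responses are in current units, not normalised).
#'
#' @param concs Agonist concentrations, micromolar (>= 3 distinct values).
#' @param responses Response amplitudes (e.g. pA).
#' @inheritParams fit_hill_inhibition
#' @return A `hill_fit` object.
#' @export
fit_hill_activation <- function(concs, responses, weights = NULL,
                                nh_bounds = c(0.2, 4)) {
  fit_hill(concs, responses, weights, kind = "activation",
           fix_imax = FALSE, nh_bounds = nh_bounds)
}

fit_hill <- function(concs, y, weights, kind, fix_imax, nh_bounds) {
  if (length(concs) != length(y)) abort("`concs` and response lengths differ.")
  ok <- is.finite(concs) & is.finite(y)
  concs <- concs[ok]; y <- y[ok]
  if (length(unique(concs)) < 3L) {
    abort("need at least 3 distinct concentrations to fit a Hill curve.")
  }
  if (any(concs <= 0)) abort("concentrations must be positive.")
  if (kind == "inhibition" && (any(y < 0) || any(y > 1.2))) {
    abort("inhibition fractions must lie in [0, 1.2].")
  }
  weights <- weights %||% rep(1, length(y))

  ## descending curve for inhibition, ascending for activation
  sgn <- if (kind == "inhibition") 1 else -1
  model <- function(par) {
    c50 <- exp(par[["lc50"]])
    nh <- par[["nh"]]
    imax <- if (fix_imax) 1 else par[["imax"]]
    imax / (1 + (concs / c50)^(sgn * nh))
  }
  obj <- function(par) sum(weights * (y - model(par))^2)

  ## crude initial c50: concentration nearest half-amplitude
  ymax0 <- if (fix_imax) 1 else max(y)
  lc0 <- log(concs[which.min(abs(y - ymax0 / 2))])
  lower <- c(lc50 = log(min(concs)) - log(1e4), nh = nh_bounds[1])
  upper <- c(lc50 = log(max(concs)) + log(1e4), nh = nh_bounds[2])
  if (!fix_imax) {
    lower <- c(lower, imax = 0)
    upper <- c(upper, imax = Inf)
  }
  best <- NULL
  for (nh0 in c(0.5, 1, 2)) {
    start <- c(lc50 = lc0, nh = nh0)
    if (!fix_imax) start <- c(start, imax = ymax0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(par) sqrt(weights) * (y - model(par)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  converged <- !is.null(best) && best$info %in% 1:4
  if (is.null(best)) {
    est <- c(lc50 = NA_real_, nh = NA_real_)
    se <- est
    dev <- NA_real_
  } else {
    est <- coef(best)
    se <- tryCatch(sqrt(diag(vcov(best))), error = function(e) {
      rep(NA_real_, length(est))
    })
    names(se) <- names(est)
    dev <- best$deviance
  }
  c50 <- exp(est[["lc50"]])
  c50_se <- c50 * se[["lc50"]]   # delta method on the log scale
  out <- list(
    kind = kind,
    c50 = c50, c50_se = c50_se,
    nH = est[["nh"]], nH_se = se[["nh"]],
    Imax = if (fix_imax) 1 else est[["imax"]],
    Imax_se = if (fix_imax) 0 else se[["imax"]],
    imax_fixed = fix_imax,
    rss = dev, n = length(y),
    converged = isTRUE(converged),
    data = tibble(conc_uM = concs, y = y, w = weights)
  )
  class(out) <- "hill_fit"
  out
}

#' Predict from a Hill fit
#' @param object A `hill_fit`.
#' @param conc Concentrations, micromolar.
#' @param ... Unused.
#' @return Predicted response at `conc`.
#' @export
predict.hill_fit <- function(object, conc, ...) {
  sgn <- if (object$kind == "inhibition") 1 else -1
  object$Imax / (1 + (conc / object$c50)^(sgn * object$nH))
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$kind == "inhibition") "IC50" else "EC50"
  cat("<hill_fit> ", x$kind, ": ", lab, " = ", signif(x$c50, 4), " uM, nH = ",
      signif(x$nH, 3), if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @rdname tidy_glyrblock
#' @export
tidy.hill_fit <- function(x, ...) {
  lab <- if (x$kind == "inhibition") "IC50" else "EC50"
  tibble(
    term = c(lab, "nH", "Imax"),
    estimate = c(x$c50, x$nH, x$Imax),
    std.error = c(x$c50_se, x$nH_se, x$Imax_se)
  )
}

#' @rdname tidy_glyrblock
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged, kind = x$kind)
}

#' Per-voltage Hill fits: the IC50(V) table
#'
#' Fits the Hill inhibition equation at each voltage of the grid, per cell
#' and (optionally) pooled over cells, from a tidy dose-inhibition table.
#' Voltages with fewer than 3 distinct concentrations for a cell are skipped
#' with a warning.
#'
#' @param table Tibble with columns `cell`, `voltage_mV`, `conc_uM`,
#'   `fraction` (see [cohort_dose_table()]).
#' @param vgrid Voltages to fit, mV. The default covers the grid at which
#'   per-voltage IC50 values are conventionally reported for these receptors.
#' @param pooled Also fit all cells pooled per voltage (`cell = "pooled"`).
#' @param ... Passed to [fit_hill_inhibition()].
#'
#' @return A tibble: `cell`, `voltage_mV`, `IC50`, `IC50_se`, `nH`, `nH_se`,
#'   `converged`, `n_conc`.
#' @export
ic50_voltage_table <- function(table,
                               vgrid = c(-80, -70, -50, -30, 30, 50, 70, 80),
                               pooled = FALSE, ...) {
  table <- as_tibble(table)
  need <- c("cell", "voltage_mV", "conc_uM", "fraction")
  if (!all(need %in% names(table))) {
    abort(paste0("`table` must have columns ", paste(need, collapse = ", "), "."))
  }
  table <- filter(table, .data$voltage_mV %in% vgrid)
  if (nrow(table) == 0) abort("empty dose-inhibition table on the requested voltage grid.")
  if (pooled) {
    table <- bind_rows(table, mutate(table, cell = "pooled"))
  }
  groups <- dplyr::distinct(table, .data$cell, .data$voltage_mV)
  rows <- pmap(groups, function(cell, voltage_mV) {
    d <- table[table$cell == cell & table$voltage_mV == voltage_mV, ]
    if (length(unique(d$conc_uM)) < 3L) {
      warn(paste0("skipping ", cell, " at ", voltage_mV,
                  " mV: fewer than 3 concentrations."))
      return(NULL)
    }
    ft <- fit_hill_inhibition(d$conc_uM, d$fraction, ...)
    tibble(cell = cell, voltage_mV = voltage_mV,
           IC50 = ft$c50, IC50_se = ft$c50_se,
           nH = ft$nH, nH_se = ft$nH_se,
           converged = ft$converged, n_conc = length(unique(d$conc_uM)))
  })
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0) abort("no voltage had enough concentrations to fit.")
  arrange(out, .data$cell, .data$voltage_mV)
}

#' Infer the block stoichiometry from Hill coefficients
#'
#' Heuristic translation of fitted Hill coefficients into an apparent number
#' of blocking molecules: a mean `nH` strictly above `threshold` (default
#' 1.3) suggests two blocking molecules, otherwise one. Values of `nH` above
#' 1 indicate apparent multi-molecule action but carry no strict mechanistic
#' guarantee; the result is labelled a heuristic.
#'
#' @param nh_by_voltage Tibble with columns `voltage_mV` and `nH` (optionally
#'   `converged`), e.g. from [ic50_voltage_table()], or a numeric vector of
#'   Hill coefficients.
#' @param threshold Decision threshold on the mean `nH`; ties (mean exactly
#'   equal to the threshold) resolve to 1 site (strict inequality).
#' @param min_voltages Minimum number of usable voltages.
#'
#' @return A list with `n_sites` (1, 2 or `NA` for undetermined), `mean_nH`
#'   and `rationale`.
#' @export
infer_stoichiometry <- function(nh_by_voltage, threshold = 1.3,
                                min_voltages = 3) {
  if (is.numeric(nh_by_voltage)) {
    nh <- nh_by_voltage
  } else {
    tb <- as_tibble(nh_by_voltage)
    if ("converged" %in% names(tb)) tb <- filter(tb, .data$converged)
    nh <- tb$nH
  }
  nh <- nh[is.finite(nh)]
  if (length(nh) < min_voltages) {
    return(list(n_sites = NA_integer_, mean_nH = NA_real_,
                rationale = "undetermined: fewer than the required usable fits"))
  }
  m <- mean(nh)
  n_sites <- if (m > threshold) 2L else 1L
  list(
    n_sites = n_sites, mean_nH = m,
    rationale = paste0(
      "heuristic: mean nH = ", signif(m, 3),
      if (m > threshold) paste0(" > ", threshold, " suggests ≥2 blocking molecules")
      else paste0(" <= ", threshold, " is consistent with a single blocking molecule")
    )
  )
}
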