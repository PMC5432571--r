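#' Estimate the noise floor of a trace
#'
#' Robust noise SD from first differences (median absolute deviation of
#' successive-sample differences divided by sqrt(2)), insensitive to the slow
#' signal component. Falls back to the recorded generator noise when the
#' trace carries one.
#'
#' @param trace A `current_trace`.
#' @return Estimated per-sample noise SD, pA.
#' @export
trace_noise_sd <- function(trace) {
  rec <- attr(trace, "noise_sd_pA")
  if (!is.null(rec) && is.finite(rec) && rec > 0) return(rec)
  stats::mad(diff(trace$current_pA)) / sqrt(2)
}

#' Percent inhibition from a long-protocol sweep
#'
#' Quantifies block from a glycine / glycine+blocker / glycine sweep as
#' `100 * (1 - I1 / I2)`, where `I1` is the mean current over the final part
#' of the co-application window (maximal inhibition) and `I2` the
#' quasi-stationary post-washout current. Referencing to the post-wash
#' current rather than the initial response makes the measure robust to
#' desensitisation during the sweep, and the ratio makes it invariant to any
#' uniform gain factor.
#'
#' @param trace A `current_trace` recorded under a long protocol.
#' @param protocol The `solution_protocol` of the sweep (defaults to the
#'   standard 2/10/5 s windows).
#' @param co_frac Final fraction of the co-application window averaged for
#'   `I1` (default 0.1).
#' @param wash_frac Final fraction of the washout window averaged for `I2`
#'   (default 0.4; the early washout is still relaxing).
#'
#' @return A tibble with `I1_pA`, `I2_pA`, `percent_inhibition`.
#' @export
measure_inhibition_long <- function(trace, protocol = make_long_protocol(30, 0),
                                    co_frac = 0.1, wash_frac = 0.4) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(protocol, "solution_protocol"))
  if (nrow(protocol) != 3L) abort("`protocol` must have the three long-protocol windows.")
  ends <- cumsum(protocol$duration_s)
  co_win <- c(ends[2] - co_frac * protocol$duration_s[2], ends[2])
  wash_win <- c(ends[3] - wash_frac * protocol$duration_s[3], ends[3])
  I1 <- mean(trace$current_pA[trace$time_s >= co_win[1] & trace$time_s <= co_win[2]])
  I2 <- mean(trace$current_pA[trace$time_s >= wash_win[1] & trace$time_s <= wash_win[2]])
  nfloor <- trace_noise_sd(trace)
  n2 <- sum(trace$time_s >= wash_win[1] & trace$time_s <= wash_win[2])
  if (!is.finite(I2) || abs(I2) < 5 * nfloor / sqrt(max(n2, 1))) {
    abort("no reference current: post-washout amplitude is below the noise floor.")
  }
  tibble(I1_pA = I1, I2_pA = I2,
         percent_inhibition = 100 * (1 - I1 / I2))
}

#' Fraction of current remaining along a voltage ramp
#'
#' Ratio of drug to control current on a fixed voltage grid. Control and drug
#' sweeps must share the voltage protocol; pass both ramp directions (lists
#' of traces) to average up- and down-ramps. Grid points where the control
#' current is within the noise band around the reversal potential are masked
#' (absent from the output), since the ratio is undefined there.
#'
#' @param control,drug A `current_trace` or list of `current_trace`s
#'   (matching directions, same voltage protocol).
#' @param min_abs_current Mask threshold, pA; defaults to 5 times the control
#'   noise floor.
#' @param v_step Voltage bin width, mV.
#'
#' @return A `fraction_remaining` tibble: `voltage_mV`, `fraction`,
#'   `i_control_pA`, `n_bins`, plus a `hysteresis` attribute (mean absolute
#'   up/down difference in `fraction`, `NA` for single-direction input).
#' @export
ramp_fraction_remaining <- function(control, drug, min_abs_current = NULL,
                                    v_step = 5) {
  if (inherits(control, "current_trace")) control <- list(control)
  if (inherits(drug, "current_trace")) drug <- list(drug)
  if (length(control) != length(drug)) {
    abort("`control` and `drug` must hold the same number of sweeps.")
  }
  bin_one <- function(ctr, drg) {
    stopifnot(inherits(ctr, "current_trace"), inherits(drg, "current_trace"))
    if (nrow(ctr) != nrow(drg) ||
        max(abs(ctr$voltage_mV - drg$voltage_mV)) > 1e-6) {
      abort("voltage protocol mismatch between control and drug sweeps.")
    }
    vb <- round(ctr$voltage_mV / v_step) * v_step
    tibble(v = vb, ic = ctr$current_pA, id = drg$current_pA) |>
      group_by(v) |>
      summarise(i_control = mean(.data$ic), i_drug = mean(.data$id),
                n = n(), .groups = "drop")
  }
  binned <- map2(control, drug, bin_one) |> list_rbind()
  if (is.null(min_abs_current)) {
    min_abs_current <- 5 * max(map_dbl(control, trace_noise_sd))
  }
  out <- binned |>
    group_by(.data$v) |>
    summarise(
      fraction = mean(.data$i_drug) / mean(.data$i_control),
      i_control_pA = mean(.data$i_control),
      n_bins = n(),
      hyst = if (n() > 1) {
        mean(abs(.data$i_drug / .data$i_control -
                   mean(.data$i_drug / .data$i_control)))
      } else NA_real_,
      .groups = "drop"
    ) |>
    filter(abs(.data$i_control_pA) >= min_abs_current) |>
    select(voltage_mV = "v", "fraction", "i_control_pA", "n_bins", "hyst")
  hysteresis <- if (length(control) > 1) {
    mean(out$hyst, na.rm = TRUE)
  } else NA_real_
  out <- select(out, -"hyst")
  structure(out, hysteresis = hysteresis,
            min_abs_current = min_abs_current,
            class = c("fraction_remaining", class(out)))
}

#' Rectification index of a ramp sweep
#'
#' Ratio `|I(+80)| / |I(-80)|` from the endpoint holds of a ramp trace;
#' values above 1 flag outward rectification, below 1 inward.
#'
#' @param control A `current_trace` from a ramp protocol.
#' @param v_extremes Endpoint voltages, mV.
#' @return The rectification index (scalar).
#' @export
rectification_index <- function(control, v_extremes = c(-80, 80)) {
  stopifnot(inherits(control, "current_trace"))
  near <- function(v) abs(control$voltage_mV - v) < 1e-6
  if (!any(near(v_extremes[1])) || !any(near(v_extremes[2]))) {
    abort("trace does not contain both ramp endpoint voltages.")
  }
  i_neg <- mean(control$current_pA[near(v_extremes[1])])
  i_pos <- mean(control$current_pA[near(v_extremes[2])])
  abs(i_pos) / abs(i_neg)
}

#' Filter cells on recording-quality criteria
#'
#' Applies the standard exclusion rules: cells with input resistance below
#' 150 MOhm or run-down above 30% across repeated applications are dropped.
#' Cells with missing quality fields are dropped with reason `"unmeasured"`.
#'
#' @param cells A tibble with columns `Rin_MOhm` and `run_down` (fraction),
#'   e.g. the `cells` table of a [generate_cohort()] object.
#' @param min_Rin_MOhm Minimum input resistance, MOhm.
#' @param max_run_down Maximum tolerated run-down fraction.
#'
#' @return The input tibble with logical `keep` and character `reason`
#'   columns appended.
#' @export
#' @examples
#' quality_filter(tibble::tibble(Rin_MOhm = c(200, 100), run_down = c(0.1, 0.1)))
quality_filter <- function(cells, min_Rin_MOhm = 150, max_run_down = 0.30) {
  cells <- as_tibble(cells)
  if (!all(c("Rin_MOhm", "run_down") %in% names(cells))) {
    abort("`cells` must have columns `Rin_MOhm` and `run_down`.")
  }
  mutate(cells,
    reason = dplyr::case_when(
      is.na(.data$Rin_MOhm) | is.na(.data$run_down) ~ "unmeasured",
      .data$Rin_MOhm < min_Rin_MOhm ~ "low_input_resistance",
      .data$run_down > max_run_down ~ "run_down",
      TRUE ~ NA_character_
    ),
    keep = is.na(.data$reason)
  )
}

#' Tidy dose-inhibition table from a synthetic cohort
#'
#' Runs [ramp_fraction_remaining()] for every (cell, concentration) pair of a
#' cohort, averaging up- and down-ramps, and evaluates the curves on the
#' cohort's analysis voltage grid (nearest masked-grid bin within
#' `v_match_tol`). The result is the tidy input of [ic50_voltage_table()].
#'
#' @param cohort A [generate_cohort()] object.
#' @param voltages Analysis voltages, mV; defaults to the grid stored in the
#'   cohort truth block.
#' @param v_match_tol Maximum distance between an analysis voltage and a ramp
#'   bin, mV.
#' @param min_abs_current Passed to [ramp_fraction_remaining()].
#'
#' @return A tibble with columns `cell`, `voltage_mV`, `conc_uM`, `fraction`.
#' @export
cohort_dose_table <- function(cohort, voltages = NULL, v_match_tol = 2.6,
                              min_abs_current = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  voltages <- voltages %||% cohort$truth$voltages
  sw <- cohort$sweeps
  combos <- dplyr::distinct(sw, .data$cell, .data$conc_uM)
  rows <- pmap(combos, function(cell, conc_uM) {
    ctr <- sw$trace[sw$cell == cell & sw$conc_uM == conc_uM & sw$role == "control"]
    drg <- sw$trace[sw$cell == cell & sw$conc_uM == conc_uM & sw$role == "drug"]
    fr <- ramp_fraction_remaining(ctr, drg, min_abs_current = min_abs_current)
    idx <- map_dbl(voltages, function(v) {
      d <- abs(fr$voltage_mV - v)
      if (min(d) > v_match_tol) NA_integer_ else which.min(d)
    })
    tibble(cell = cell, voltage_mV = voltages, conc_uM = conc_uM,
           fraction = fr$fraction[idx])
  })
  filter(list_rbind(rows), is.finite(.data$fraction))
}
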