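#' Voltage ramp protocol
#'
#' Standard ramp protocol: a 500 ms hold at one extreme, a 1 s linear ramp to
#' the other extreme, and a 500 ms hold there (total 2 s). `direction = "up"`
#' runs from -80 to +80 mV; `"down"` is its mirror image under V -> -V.
#'
#' @param direction `"up"` or `"down"`.
#' @param sample_rate Sampling rate in Hz.
#' @param v_low,v_high Ramp extremes, mV.
#' @param hold_s,ramp_s Hold and ramp durations, s.
#'
#' @return A `voltage_protocol`: tibble of segments with columns
#'   `duration_s`, `v_start`, `v_end` and attribute `sample_rate`.
#' @export
#' @examples
#' vp <- make_ramp_protocol("up")
#' protocol_voltage(vp, c(0.25, 1.0, 1.9))
make_ramp_protocol <- function(direction = c("up", "down"), sample_rate = 1000,
                               v_low = -80, v_high = 80,
                               hold_s = 0.5, ramp_s = 1) {
  direction <- match.arg(direction)
  if (hold_s <= 0 || ramp_s <= 0 || sample_rate <= 0) {
    abort("durations and sample rate must be positive.")
  }
  a <- if (direction == "up") v_low else v_high
  b <- if (direction == "up") v_high else v_low
  seg <- tibble(
    duration_s = c(hold_s, ramp_s, hold_s),
    v_start = c(a, a, b),
    v_end = c(a, b, b)
  )
  structure(seg, sample_rate = sample_rate, direction = direction,
            class = c("voltage_protocol", class(seg)))
}

#' Constant-voltage protocol
#'
#' @param V_hold Holding potential, mV.
#' @param duration_s Duration, s.
#' @param sample_rate Sampling rate, Hz.
#' @return A `voltage_protocol` with a single segment.
#' @export
make_hold_protocol <- function(V_hold, duration_s, sample_rate = 200) {
  if (duration_s <= 0 || sample_rate <= 0) {
    abort("duration and sample rate must be positive.")
  }
  seg <- tibble(duration_s = duration_s, v_start = V_hold, v_end = V_hold)
  structure(seg, sample_rate = sample_rate, direction = "hold",
            class = c("voltage_protocol", class(seg)))
}

#' Evaluate a voltage protocol at given times
#'
#' Linear interpolation inside each segment; times at or beyond the end take
#' the final voltage.
#'
#' @param protocol A `voltage_protocol`.
#' @param t Times, s.
#' @return Voltages at `t`, mV.
#' @export
protocol_voltage <- function(protocol, t) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  ends <- cumsum(protocol$duration_s)
  starts <- c(0, head(ends, -1))
  v <- numeric(length(t))
  t2 <- pmin(pmax(t, 0), ends[length(ends)])
  idx <- findInterval(t2, starts, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), nrow(protocol))
  frac <- (t2 - starts[idx]) / protocol$duration_s[idx]
  protocol$v_start[idx] + frac * (protocol$v_end[idx] - protocol$v_start[idx])
}

#' Total duration of a protocol, s
#' @param protocol A `voltage_protocol` or `solution_protocol`.
#' @return Duration in seconds.
#' @export
protocol_duration <- function(protocol) sum(protocol$duration_s)

#' Long drug-application solution protocol
#'
#' Three contiguous windows of agonist application: glycine alone (2 s),
#' glycine plus blocker co-application (10 s), then glycine alone again (5 s)
#' to follow washout. Concentrations in micromolar.
#'
#' @param glycine Glycine concentration, micromolar.
#' @param nfa Blocker (niflumic acid) concentration in the middle window.
#' @param durations_s Durations of the three windows, s.
#'
#' @return A `solution_protocol`: tibble with columns `duration_s`,
#'   `glycine_uM`, `nfa_uM`.
#' @export
#' @examples
#' make_long_protocol(30, 300)
make_long_protocol <- function(glycine, nfa, durations_s = c(2, 10, 5)) {
  if (any(!is.finite(c(glycine, nfa))) || glycine < 0 || nfa < 0) {
    abort("concentrations must be finite and >= 0.")
  }
  if (length(durations_s) != 3L || any(durations_s <= 0)) {
    abort("`durations_s` must be three positive durations.")
  }
  seg <- tibble(
    duration_s = durations_s,
    glycine_uM = rep(glycine, 3),
    nfa_uM = c(0, nfa, 0)
  )
  structure(seg, class = c("solution_protocol", class(seg)))
}

#' Constant-solution protocol
#'
#' Single window of fixed agonist/blocker concentrations, used with ramp
#' voltage protocols where the solutions do not change during the sweep.
#'
#' @param glycine,nfa Concentrations, micromolar.
#' @param duration_s Window duration, s.
#' @return A `solution_protocol`.
#' @export
make_constant_solution <- function(glycine, nfa = 0, duration_s = 2) {
  if (any(!is.finite(c(glycine, nfa))) || glycine < 0 || nfa < 0) {
    abort("concentrations must be finite and >= 0.")
  }
  seg <- tibble(duration_s = duration_s, glycine_uM = glycine, nfa_uM = nfa)
  structure(seg, class = c("solution_protocol", class(seg)))
}

#' Evaluate a solution protocol at given times
#'
#' Solution exchange is treated as instantaneous at window boundaries.
#'
#' @param protocol A `solution_protocol`.
#' @param t Times, s.
#' @return A tibble with columns `glycine_uM`, `nfa_uM` at each `t`.
#' @export
protocol_solution <- function(protocol, t) {
  stopifnot(inherits(protocol, "solution_protocol"))
  ends <- cumsum(protocol$duration_s)
  starts <- c(0, head(ends, -1))
  t2 <- pmin(pmax(t, 0), ends[length(ends)] - 1e-12)
  idx <- findInterval(t2, starts)
  idx <- pmin(pmax(idx, 1L), nrow(protocol))
  tibble(glycine_uM = protocol$glycine_uM[idx], nfa_uM = protocol$nfa_uM[idx])
}
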