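#' Idealize a single-channel trace by half-amplitude threshold
#'
#' Classifies each sample as open or shut by whichever of the two levels
#' (baseline and open amplitude) is nearer — equivalent to a half-amplitude
#' threshold crossing — and merges events shorter than `min_samples` into
#' their neighbours. Requires a level separation of at least 3 noise SDs.
#'
#' @param trace A `current_trace` at fixed potential.
#' @param baseline_pA Shut-level current, pA.
#' @param open_amplitude_pA Open-level current, pA (signed).
#' @param min_samples Minimum event length in samples (default 2); shorter
#'   events are absorbed by the preceding event.
#'
#' @return An `idealized_events` tibble: `level` ("open"/"shut"),
#'   `duration_s`, `amplitude_pA`, with alternating levels.
#' @export
idealize <- function(trace, baseline_pA = 0, open_amplitude_pA,
                     min_samples = 2) {
  stopifnot(inherits(trace, "current_trace"))
  noise <- trace_noise_sd(trace)
  sep <- abs(open_amplitude_pA - baseline_pA)
  if (sep < 3 * noise) {
    abort("open and shut levels are not separable (< 3 noise SD apart).")
  }
  sr <- attr(trace, "sample_rate") %||% (1 / stats::median(diff(trace$time_s)))
  thr <- (baseline_pA + open_amplitude_pA) / 2
  if (open_amplitude_pA > baseline_pA) {
    open <- trace$current_pA > thr
  } else {
    open <- trace$current_pA < thr
  }
  r <- rle(open)
  ## merge runs shorter than min_samples into the previous event
  while (any(r$lengths < min_samples) && length(r$lengths) > 1) {
    i <- which(r$lengths < min_samples)[1]
    j <- if (i == 1) 2L else i - 1L
    r$lengths[j] <- r$lengths[j] + r$lengths[i]
    r$lengths <- r$lengths[-i]
    r$values <- r$values[-i]
    r <- rle(inverse.rle(r))
  }
  if (length(r$lengths) == 1 && !r$values[1]) {
    return(structure(tibble(level = character(), duration_s = numeric(),
                            amplitude_pA = numeric()),
                     class = c("idealized_events", "tbl_df", "tbl", "data.frame")))
  }
  ev <- tibble(
    level = ifelse(r$values, "open", "shut"),
    duration_s = r$lengths / sr,
    amplitude_pA = ifelse(r$values, open_amplitude_pA, baseline_pA)
  )
  structure(ev, sample_rate = sr,
            class = c("idealized_events", class(ev)))
}

#' Maximum-likelihood exponential (mixture) fit of dwell times
#'
#' One component: the ML rate is the reciprocal sample mean (closed form).
#' Two components: expectation-maximisation on the exponential mixture,
#' initialised by a quantile split.
#'
#' @param durations Dwell durations, s (>= 50 for one component, >= 200 for
#'   two).
#' @param n_components 1 or 2.
#' @param max_iter,tol EM iteration controls.
#'
#' @return A tibble with columns `component`, `rate` (1/s), `tau_s`,
#'   `weight`, plus attributes `loglik` and `converged`.
#' @export
fit_dwell_exponentials <- function(durations, n_components = 1,
                                   max_iter = 500, tol = 1e-10) {
  durations <- durations[is.finite(durations) & durations > 0]
  if (length(durations) == 0) abort("no positive finite dwell durations supplied.")
  if (!n_components %in% c(1, 2)) abort("`n_components` must be 1 or 2.")
  need <- if (n_components == 1) 50 else 200
  if (length(durations) < need) {
    abort(paste0("need at least ", need, " dwells for ", n_components,
                 " component(s)."))
  }
  if (sd(durations) < 1e-15) {
    abort("degenerate dwell sample: all durations identical.")
  }
  if (n_components == 1) {
    rate <- 1 / mean(durations)
    out <- tibble(component = 1L, rate = rate, tau_s = 1 / rate, weight = 1)
    return(structure(out,
                     loglik = sum(stats::dexp(durations, rate, log = TRUE)),
                     converged = TRUE, class = class(out)))
  }
  ## 2-component EM, split at the median for initial responsibilities
  lo <- durations <= stats::median(durations)
  rate <- c(1 / mean(durations[lo]), 1 / mean(durations[!lo]))
  wt <- c(mean(lo), mean(!lo))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- wt[1] * stats::dexp(durations, rate[1])
    d2 <- wt[2] * stats::dexp(durations, rate[2])
    tot <- d1 + d2
    ll <- sum(log(tot))
    g1 <- d1 / tot
    wt <- c(mean(g1), mean(1 - g1))
    rate <- c(sum(g1) / sum(g1 * durations),
              sum(1 - g1) / sum((1 - g1) * durations))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  ord <- order(rate, decreasing = TRUE)  # fast component first
  out <- tibble(component = 1:2, rate = rate[ord], tau_s = 1 / rate[ord],
                weight = wt[ord])
  structure(out, loglik = ll, converged = converged, class = class(out))
}

#' Critical gap duration at equal misclassification
#'
#' Given a two-component shut-time fit (fast flicker gaps, slow inter-burst
#' gaps), returns the `t_crit` at which the expected number of long gaps
#' classified as short equals the expected number of short gaps classified as
#' long: `w_f * exp(-t/tau_f) = w_s * (1 - exp(-t/tau_s))`.
#'
#' @param shut_fit A two-component [fit_dwell_exponentials()] result.
#' @return `t_crit` in seconds.
#' @export
t_crit_equal_misclass <- function(shut_fit) {
  if (nrow(shut_fit) != 2) abort("`shut_fit` must have two components.")
  wf <- shut_fit$weight[1]; rf <- shut_fit$rate[1]
  ws <- shut_fit$weight[2]; rs <- shut_fit$rate[2]
  f <- function(t) wf * exp(-rf * t) - ws * (1 - exp(-rs * t))
  uniroot(f, interval = c(1 / rf * 1e-3, 1 / rs * 50), tol = 1e-12)$root
}

#' Detect bursts of openings separated by long shut periods
#'
#' Shut periods shorter than `t_crit` are intra-burst flicker gaps (blocked
#' sojourns under channel block); shut periods of `t_crit` or longer
#' terminate a burst. A recording with no shut periods is a single burst.
#'
#' @param events An `idealized_events` tibble (alternating open/shut), or the
#'   `events` tibble of [simulate_single_channel()] (its `class` column is
#'   used).
#' @param t_crit Critical gap duration, s. If `NULL`, derived from a
#'   two-component shut-time fit via [t_crit_equal_misclass()].
#'
#' @return A `burst_table` tibble: `burst`, `start_s`, `end_s`, `n_openings`,
#'   `open_time_s`, `n_flicker_gaps`, `mean_flicker_gap_s`; attribute
#'   `t_crit`.
#' @export
detect_bursts <- function(events, t_crit = NULL) {
  ev <- as_tibble(events)
  if (!"level" %in% names(ev) && "class" %in% names(ev)) {
    ev$level <- ev$class
  }
  if (!all(c("level", "duration_s") %in% names(ev))) {
    abort("`events` must have columns `level` (or `class`) and `duration_s`.")
  }
  ev <- filter(ev, .data$level %in% c("open", "shut"))
  ## collapse consecutive same-level events (e.g. O and OB both shut)
  grp <- cumsum(c(TRUE, ev$level[-1] != ev$level[-nrow(ev)]))
  ev <- ev |>
    mutate(grp = grp) |>
    group_by(.data$grp) |>
    summarise(level = dplyr::first(.data$level),
              duration_s = sum(.data$duration_s), .groups = "drop")
  if (!any(ev$level == "open")) abort("no openings in the event list.")
  if (is.null(t_crit)) {
    shut <- ev$duration_s[ev$level == "shut"]
    t_crit <- t_crit_equal_misclass(fit_dwell_exponentials(shut, 2))
  }
  ev$t_start <- cumsum(c(0, head(ev$duration_s, -1)))
  ## burst boundaries: long shut periods
  is_long_shut <- ev$level == "shut" & ev$duration_s >= t_crit
  burst_id <- cumsum(is_long_shut)
  keep <- !is_long_shut
  evb <- ev[keep, ]
  evb$burst <- burst_id[keep] + 1L
  out <- evb |>
    group_by(.data$burst) |>
    summarise(
      start_s = min(.data$t_start),
      end_s = max(.data$t_start + .data$duration_s),
      n_openings = sum(.data$level == "open"),
      open_time_s = sum(.data$duration_s[.data$level == "open"]),
      n_flicker_gaps = sum(.data$level == "shut"),
      mean_flicker_gap_s = if (any(.data$level == "shut")) {
        mean(.data$duration_s[.data$level == "shut"])
      } else NA_real_,
      .groups = "drop"
    ) |>
    filter(.data$n_openings > 0) |>
    mutate(burst = dplyr::row_number())
  structure(out, t_crit = t_crit, class = c("burst_table", class(out)))
}

#' Estimate blocking and unblocking rates from burst structure
#'
#' Under open-channel block, intra-burst flicker gaps are blocked sojourns:
#' the unblocking rate is the reciprocal mean flicker-gap duration,
#' `koff = 1 / mean(gap)`, and the blocking rate per unit concentration is
#' the flicker-gap frequency per open time, `kon = (gaps per second of open
#' time) / [blocker]`.
#'
#' @param bursts A `burst_table` from [detect_bursts()].
#' @param blocker Blocker concentration, micromolar (> 0).
#' @param min_gaps Minimum number of flicker gaps required.
#'
#' @return A tibble with `kon_per_uM_s`, `koff_per_s`, `n_gaps`,
#'   `open_time_s`.
#' @export
estimate_block_rates <- function(bursts, blocker, min_gaps = 30) {
  stopifnot(inherits(bursts, "burst_table") || is.data.frame(bursts))
  if (!is.finite(blocker) || blocker <= 0) {
    abort("no blocker present: `blocker` must be > 0.")
  }
  n_gaps <- sum(bursts$n_flicker_gaps)
  if (n_gaps < min_gaps) {
    abort(paste0("need at least ", min_gaps, " flicker gaps (got ", n_gaps, ")."))
  }
  gap_time <- sum(bursts$n_flicker_gaps * bursts$mean_flicker_gap_s,
                  na.rm = TRUE)
  open_time <- sum(bursts$open_time_s)
  tibble(
    kon_per_uM_s = (n_gaps / open_time) / blocker,
    koff_per_s = n_gaps / gap_time,
    n_gaps = n_gaps,
    open_time_s = open_time
  )
}
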