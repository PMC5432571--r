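#' Recording configuration for the synthetic generator
#'
#' Describes the "cell and rig" around the kinetic scheme: channel count,
#' unitary current, reversal potential, additive recording noise, per-sweep
#' multiplicative amplitude noise (gain drift), run-down, cell-to-cell
#' maximal-current variability and the master seed. The unitary current is
#' anchored at -30 mV and scales linearly with driving force `(V - E_rev)`.
#'
#' @param unitary_current_pA Unitary current amplitude at -30 mV, pA
#'   (default 2.8).
#' @param n_channels Number of channels per cell.
#' @param E_rev Reversal potential, mV (default 0, near-symmetric chloride).
#' @param noise_sd_pA Additive Gaussian noise SD per sample, pA.
#' @param amp_noise_cv Log-SD of the per-sweep multiplicative amplitude
#'   factor (0 disables).
#' @param run_down_per_sweep Fractional amplitude loss per successive sweep.
#' @param Imax_cell_cv Log-SD of the lognormal cell-to-cell amplitude factor.
#' @param seed Master integer seed; recorded in every output manifest.
#'
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(unitary_current_pA = 2.8, n_channels = 100,
                             E_rev = 0, noise_sd_pA = 2, amp_noise_cv = 0,
                             run_down_per_sweep = 0, Imax_cell_cv = 0.2,
                             seed = 1L) {
  if (noise_sd_pA < 0 || amp_noise_cv < 0 || Imax_cell_cv < 0 ||
      run_down_per_sweep < 0 || run_down_per_sweep >= 1) {
    abort("noise and variability parameters must be >= 0 (run-down < 1).")
  }
  if (n_channels < 1) abort("`n_channels` must be >= 1.")
  structure(
    list(unitary_current_pA = unitary_current_pA, n_channels = n_channels,
         E_rev = E_rev, noise_sd_pA = noise_sd_pA,
         amp_noise_cv = amp_noise_cv,
         run_down_per_sweep = run_down_per_sweep,
         Imax_cell_cv = Imax_cell_cv, seed = as.integer(seed)),
    class = "recording_config"
  )
}

#' Unitary current at a membrane potential
#'
#' Linear driving-force scaling of the unitary current from its -30 mV
#' anchor: negative (inward) at potentials below `E_rev`.
#'
#' @param V Membrane potential(s), mV.
#' @param config A [recording_config()].
#' @return Unitary current, pA.
#' @export
unitary_current <- function(V, config) {
  -config$unitary_current_pA * (V - config$E_rev) / (-30 - config$E_rev)
}

## Precompile the transition list of a scheme at fixed concentrations so the
## ODE right-hand side reduces to rate = base * exp(vcoef * V / RT_F).
compile_rates <- function(scheme, agonist, blocker) {
  b <- scheme$block
  g <- scheme$gating
  rtf <- phys_constants(scheme$temperature)$RT_F_mV
  sts <- scheme$states$state
  kinds <- scheme$transitions$kind
  base <- numeric(length(kinds))
  vcoef <- numeric(length(kinds))
  for (k in seq_along(kinds)) {
    base[k] <- switch(kinds[k],
      opening     = g$beta_max * agonist_occupancy(agonist, g),
      closing     = g$alpha,
      block_on_1  = b$kon0[1] * blocker,
      block_off_1 = b$koff0[1],
      block_on_2  = b$kon0[2] * blocker,
      block_off_2 = b$koff0[2],
      desens      = g$desens_rate,
      resens      = g$resens_rate
    )
    vcoef[k] <- switch(kinds[k],
      block_on_1  = ,
      block_on_2  = b$voltage_split * b$delta / rtf,
      block_off_1 = ,
      block_off_2 = -(1 - b$voltage_split) * b$delta / rtf,
      0
    )
  }
  list(base = base, vcoef = vcoef,
       from = match(scheme$transitions$from, sts),
       to = match(scheme$transitions$to, sts),
       n = length(sts), g = scheme$states$g)
}

master_eq_rhs <- function(t, p, parms) {
  V <- protocol_voltage(parms$vprot, t)
  r <- parms$cr$base * exp(parms$cr$vcoef * V)
  flow <- r * p[parms$cr$from]
  dp <- numeric(parms$cr$n)
  for (k in seq_along(flow)) {
    dp[parms$cr$from[k]] <- dp[parms$cr$from[k]] - flow[k]
    dp[parms$cr$to[k]] <- dp[parms$cr$to[k]] + flow[k]
  }
  list(dp)
}

## Exact solution p(t) = exp(t Q^T) p0 at fixed conditions via the
## eigendecomposition of the (small) generator; columns = states, one row per
## relative time in `dt`. Falls back to expm-by-squaring if the generator is
## defective.
propagate_constant <- function(scheme, V, cr, p0, dt) {
  r <- cr$base * exp(cr$vcoef * V)
  Q <- matrix(0, cr$n, cr$n)
  for (k in seq_along(r)) {
    Q[cr$from[k], cr$to[k]] <- Q[cr$from[k], cr$to[k]] + r[k]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  A <- t(Q)
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(ev) && is.finite(rcond(ev$vectors))
      && rcond(ev$vectors) > 1e-10) {
    c0 <- solve(ev$vectors, p0)
    out <- t(Re(ev$vectors %*% (exp(outer(ev$values, dt)) * c0)))
  } else {
    ## scaling-and-squaring matrix exponential per unique step
    out <- matrix(NA_real_, length(dt), cr$n)
    for (i in seq_along(dt)) {
      out[i, ] <- as.numeric(expm_ss(A * dt[i]) %*% p0)
    }
  }
  pmin(pmax(out, 0), 1)
}

expm_ss <- function(M, order = 8) {
  s <- max(0, ceiling(log2(max(1, norm(M, "1")))))
  Ms <- M / 2^s
  E <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in 1:order) {
    term <- term %*% Ms / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Simulate a whole-cell current trace
#'
#' Integrates the master equation of the kinetic scheme along a voltage and a
#' solution protocol (deterministic macroscopic limit, `deSolve::lsoda`,
#' integration restarted at each solution-window boundary) and converts the
#' conducting occupancy to current:
#' `I(t) = n_channels * i_unit(V) * rect(V) * sum(g_i p_i(t)) * amp + noise`.
#' All channels start closed; the initial holds of the standard protocols are
#' long enough to reach quasi-equilibrium before the informative part of the
#' sweep.
#'
#' @param scheme A [build_block_scheme()] object.
#' @param vprot A `voltage_protocol`.
#' @param sprot A `solution_protocol` covering at least the same duration.
#' @param config A [recording_config()].
#' @param seed Integer seed for this sweep's noise (`NULL` leaves the RNG
#'   state alone).
#' @param amp_scale Extra multiplicative amplitude factor (e.g. the cell's
#'   drawn Imax factor); the per-sweep lognormal gain factor from
#'   `config$amp_noise_cv` is applied on top.
#'
#' @return A `current_trace`: tibble with columns `time_s`, `current_pA`,
#'   `voltage_mV`, plus attributes `sample_rate`, `p_final` (terminal state
#'   occupancies), `amp_used` and `seed`.
#' @export
simulate_whole_cell <- function(scheme, vprot, sprot, config,
                                seed = NULL, amp_scale = 1) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(vprot, "voltage_protocol"),
            inherits(sprot, "solution_protocol"),
            inherits(config, "recording_config"))
  dur <- protocol_duration(vprot)
  if (protocol_duration(sprot) < dur - 1e-9) {
    abort("solution protocol is shorter than the voltage protocol.")
  }
  sr <- attr(vprot, "sample_rate")
  times <- (0:round(dur * sr)) / sr   # exact boundary hits, no seq() drift
  if (!is.null(seed)) set.seed(seed)
  amp <- amp_scale *
    (if (config$amp_noise_cv > 0) rlnorm(1, 0, config$amp_noise_cv) else 1)

  n <- nrow(scheme$states)
  p <- c(1, rep(0, n - 1))           # all channels closed at t = 0
  occ <- matrix(NA_real_, length(times), n)
  win_ends <- cumsum(sprot$duration_s)
  win_starts <- c(0, head(win_ends, -1))
  for (w in seq_len(nrow(sprot))) {
    sel <- which(times >= win_starts[w] - 1e-12 & times <= min(win_ends[w], dur) + 1e-12)
    if (length(sel) == 0) next
    tt <- times[sel]
    ## integrate from the true window start; samples at (or marginally
    ## before) the boundary take the window-start state
    t0 <- max(win_starts[w], 0)
    tt_int <- c(t0, tt[tt > t0 + 1e-12])
    cr <- compile_rates(scheme, sprot$glycine_uM[w], sprot$nfa_uM[w])
    vv <- protocol_voltage(vprot, tt_int)
    if (max(vv) - min(vv) < 1e-9) {
      ## constant voltage: exact eigendecomposition propagator, robust to
      ## arbitrarily stiff rate constants
      sol <- propagate_constant(scheme, vv[1], cr, p, tt_int - t0)
    } else {
      ode_sol <- deSolve::ode(y = p, times = tt_int, func = master_eq_rhs,
                              parms = list(vprot = vprot, cr = cr),
                              method = "lsoda", rtol = 1e-8, atol = 1e-10)
      if (attr(ode_sol, "istate")[1] < 0) {
        abort("master-equation integration failed (step-size instability).")
      }
      sol <- ode_sol[, -1, drop = FALSE]
    }
    idx <- match(tt, tt_int)
    idx[is.na(idx)] <- 1L
    occ[sel, ] <- sol[idx, , drop = FALSE]
    p <- as.numeric(sol[nrow(sol), ])
    if (win_ends[w] >= dur) break
  }
  V <- protocol_voltage(vprot, times)
  g_occ <- as.numeric(occ %*% scheme$states$g)
  rect <- rectification_factor(V, scheme$gating)
  I <- config$n_channels * unitary_current(V, config) * rect * g_occ * amp
  if (config$noise_sd_pA > 0) I <- I + rnorm(length(I), 0, config$noise_sd_pA)
  tr <- tibble(time_s = times, current_pA = I, voltage_mV = V)
  structure(tr, sample_rate = sr, p_final = setNames(p, scheme$states$state),
            amp_used = amp, seed = seed, noise_sd_pA = config$noise_sd_pA,
            direction = attr(vprot, "direction"),
            class = c("current_trace", class(tr)))
}

#' Simulate a single-channel recording
#'
#' Exact stochastic (Gillespie) simulation of the continuous-time Markov
#' chain at fixed potential and concentrations, returning the event list and
#' a sampled noisy trace. The rendered amplitude of a state is
#' `g * i_unit(V_hold) * rect(V_hold)`; with the default (non-rectifying)
#' gating the open-channel amplitude at -30 mV is the configured 2.8 pA.
#'
#' @param scheme A [build_block_scheme()] object.
#' @param V_hold Holding potential, mV.
#' @param agonist,blocker Concentrations, micromolar.
#' @param duration_s Simulated duration, s.
#' @param config A [recording_config()].
#' @param seed Integer seed.
#' @param sample_rate Trace sampling rate, Hz.
#' @param start_state Initial state id (default `"C"`).
#'
#' @return A list with `events` (tibble: `state`, `class` open/shut,
#'   `duration_s`, `amplitude_pA`) and `trace` (a `current_trace`).
#' @export
simulate_single_channel <- function(scheme, V_hold, agonist, blocker,
                                    duration_s, config, seed = NULL,
                                    sample_rate = 10000, start_state = "C") {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(config, "recording_config"))
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  Q <- rate_matrix(scheme, V_hold, agonist, blocker)
  sts <- scheme$states$state
  gg <- setNames(scheme$states$g, sts)
  i_open <- unitary_current(V_hold, config) *
    rectification_factor(V_hold, scheme$gating)
  cur <- match(start_state, sts)
  if (is.na(cur)) abort("`start_state` is not a state of the scheme.")
  t_now <- 0
  st_seq <- integer(0)
  dw_seq <- numeric(0)
  while (t_now < duration_s) {
    out <- Q[cur, ]
    out[cur] <- 0
    tot <- sum(out)
    dwell <- if (tot > 0) rexp(1, tot) else (duration_s - t_now)
    dwell <- min(dwell, duration_s - t_now)
    st_seq <- c(st_seq, cur)
    dw_seq <- c(dw_seq, dwell)
    t_now <- t_now + dwell
    if (t_now >= duration_s || tot == 0) break
    cur <- sample.int(length(sts), 1, prob = out)
  }
  events <- tibble(
    state = sts[st_seq],
    class = ifelse(gg[st_seq] > 0, "open", "shut"),
    duration_s = dw_seq,
    amplitude_pA = gg[st_seq] * i_open
  )
  times <- seq(0, duration_s, by = 1 / sample_rate)
  ends <- cumsum(dw_seq)
  idx <- findInterval(times, c(0, head(ends, -1)), rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), length(st_seq))
  I <- gg[st_seq[idx]] * i_open
  if (config$noise_sd_pA > 0) I <- I + rnorm(length(I), 0, config$noise_sd_pA)
  tr <- tibble(time_s = times, current_pA = as.numeric(I),
               voltage_mV = rep(V_hold, length(times)))
  tr <- structure(tr, sample_rate = sample_rate, seed = seed,
                  noise_sd_pA = config$noise_sd_pA,
                  i_open_pA = i_open, direction = "hold",
                  class = c("current_trace", class(tr)))
  list(events = events, trace = tr)
}

#' Generate a synthetic cohort of recorded cells
#'
#' For each cell: a control and a drug ramp pair (up- and down-ramps) at each
#' blocker concentration, optional long-protocol sweeps, a drawn maximal
#' current factor and quality metadata (input resistance, run-down). The
#' generating scheme and configuration are stored alongside the data, and a
#' given `(config, seed)` regenerates the cohort bit-identically. All
#' randomness descends from `config$seed` through per-cell and per-sweep
#' substream seeds.
#'
#' @param n_cells Number of cells, >= 1.
#' @param scheme The ground-truth [build_block_scheme()] object.
#' @param conc_grid Blocker concentrations, micromolar (non-empty).
#' @param voltages Analysis voltage grid, mV (non-empty); stored as metadata
#'   for the downstream per-voltage fits.
#' @param config A [recording_config()].
#' @param glycine Agonist concentration, micromolar.
#' @param sample_rate Ramp sampling rate, Hz.
#' @param include_long Also simulate a long-protocol sweep pair (holds -30
#'   and +30 mV) at the median blocker concentration.
#'
#' @return A `synthetic_cohort`: list with `cells` (tibble of cell metadata),
#'   `sweeps` (tibble: `cell`, `conc_uM`, `role`, `direction`, `trace`
#'   list-column), `long_sweeps` (or `NULL`), `truth` (scheme, config,
#'   glycine, voltages, seed).
#' @export
generate_cohort <- function(n_cells, scheme, conc_grid, voltages, config,
                            glycine = 30, sample_rate = 1000,
                            include_long = FALSE) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(config, "recording_config"))
  if (length(n_cells) != 1L || !is.finite(n_cells) || n_cells < 1) {
    abort("`n_cells` must be >= 1.")
  }
  if (length(conc_grid) < 1 || length(voltages) < 1) {
    abort("`conc_grid` and `voltages` must be non-empty.")
  }
  if (any(conc_grid <= 0)) abort("blocker concentrations must be positive.")
  n_cells <- as.integer(n_cells)
  set.seed(config$seed)
  cell_seed <- sample.int(.Machine$integer.max - 1L, n_cells)
  cells <- tibble(
    cell = paste0("cell", seq_len(n_cells)),
    Imax_scale = rlnorm(n_cells, 0, config$Imax_cell_cv),
    Rin_MOhm = rlnorm(n_cells, log(500), 0.35),
    run_down = runif(n_cells, 0, 0.2),
    seed = cell_seed
  )
  vp_up <- make_ramp_protocol("up", sample_rate)
  vp_dn <- make_ramp_protocol("down", sample_rate)
  sweeps <- vector("list", n_cells)
  long_sweeps <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    set.seed(cell_seed[ci])
    n_sweeps <- length(conc_grid) * 4L + 4L
    sw_seed <- sample.int(.Machine$integer.max - 1L, n_sweeps)
    k <- 0L
    rows <- list()
    for (conc in conc_grid) {
      for (role in c("control", "drug")) {
        sprot <- make_constant_solution(glycine,
                                        if (role == "drug") conc else 0,
                                        duration_s = protocol_duration(vp_up))
        for (vp in list(vp_up, vp_dn)) {
          k <- k + 1L
          tr <- simulate_whole_cell(scheme, vp, sprot, config,
                                    seed = sw_seed[k],
                                    amp_scale = cells$Imax_scale[ci])
          rows[[length(rows) + 1L]] <- tibble(
            cell = cells$cell[ci], conc_uM = conc, role = role,
            direction = attr(vp, "direction"), trace = list(tr)
          )
        }
      }
    }
    sweeps[[ci]] <- list_rbind(rows)
    if (include_long) {
      lconc <- sort(conc_grid)[ceiling(length(conc_grid) / 2)]
      lrows <- list()
      for (vh in c(-30, 30)) {
        k <- k + 1L
        lp <- make_long_protocol(glycine, lconc)
        vpl <- make_hold_protocol(vh, protocol_duration(lp), sample_rate = 200)
        tr <- simulate_whole_cell(scheme, vpl, lp, config,
                                  seed = sw_seed[k],
                                  amp_scale = cells$Imax_scale[ci])
        lrows[[length(lrows) + 1L]] <- tibble(
          cell = cells$cell[ci], conc_uM = lconc, V_hold = vh,
          trace = list(tr)
        )
      }
      long_sweeps[[ci]] <- list_rbind(lrows)
    }
  }
  structure(
    list(
      cells = cells,
      sweeps = list_rbind(sweeps),
      long_sweeps = if (include_long) list_rbind(long_sweeps) else NULL,
      truth = list(scheme = scheme, config = config, glycine = glycine,
                   voltages = voltages, conc_grid = conc_grid,
                   seed = config$seed)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$cells), " cells, ",
      nrow(x$sweeps), " ramp sweeps, seed ", x$truth$seed, "\n", sep = "")
  invisible(x)
}
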