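#' Physical constants for electrophysiology
#'
#' Faraday constant, gas constant and the working absolute temperature,
#' together with the derived thermal voltage RT/F in millivolts. All
#' voltage-dependent expressions in the package use `RT_F_mV` so that membrane
#' potentials can be kept in mV throughout.
#'
#' @param temperature Absolute temperature in kelvin. The default 295.15 K
#'   (22 degrees C) is a conventional room-temperature value for patch-clamp
#'   work; at this temperature RT/F = 25.43 mV.
#'
#' @return A list with elements `F` (C/mol), `R` (J/mol/K), `T` (K) and
#'   `RT_F_mV` (mV).
#' @export
#' @examples
#' phys_constants()$RT_F_mV
phys_constants <- function(temperature = 295.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be a single positive finite number (kelvin).")
  }
  Fc <- 96485.33212
  Rc <- 8.314462618
  list(F = Fc, R = Rc, T = temperature,
       RT_F_mV = 1000 * Rc * temperature / Fc)
}

#' Woodhull dissociation constant at a membrane potential
#'
#' Voltage dependence of the dissociation constant of a charged open-channel
#' blocker binding at fractional electrical distance `delta` from the external
#' membrane surface: `Kd(V) = Kd0 * exp(-delta * F * V / (R * T))`. With the
#' convention V = intracellular minus extracellular, `delta > 0` makes block
#' by an external anionic blocker stronger at positive potentials.
#'
#' @param Kd0 Dissociation constant at 0 mV (micromolar), positive scalar.
#' @param delta Fractional electrical distance in `[0, 1]`.
#' @param V Membrane potential(s) in mV; vectorised.
#' @param temperature Absolute temperature in kelvin.
#'
#' @return Kd at each `V`, in the units of `Kd0`.
#' @export
#' @examples
#' woodhull_kd(100, 0.65, V = c(-80, 0, 80))
woodhull_kd <- function(Kd0, delta, V, temperature = 295.15) {
  if (!is.numeric(Kd0) || length(Kd0) != 1L || !is.finite(Kd0) || Kd0 <= 0) {
    abort("`Kd0` must be a single positive finite number.")
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0 || delta > 1) {
    abort("`delta` must be a single finite number in [0, 1].")
  }
  if (!is.numeric(V) || length(V) < 1L || any(!is.finite(V))) {
    abort("`V` must be finite numeric (mV).")
  }
  pc <- phys_constants(temperature)
  Kd0 * exp(-delta * V / pc$RT_F_mV)
}

#' Blocker parameters for an open-channel block scheme
#'
#' Equilibrium and kinetic parameters of pore block. `Kd0` holds the
#' zero-voltage dissociation constant(s): a single value used for every site,
#' or one value per site (stepwise macroscopic constants K1, K2 of the first
#' and second binding events). Association rates follow from `kon0 =
#' koff0 / Kd0`. The Woodhull voltage factor `exp(delta*F*V/RT)` is split
#' between the on- and off-rates by `voltage_split` (equilibrium is
#' split-invariant; kinetics are not).
#'
#' @param n_sites Number of blocking sites, 1 or 2.
#' @param Kd0 Zero-voltage dissociation constant(s), micromolar. Length 1 or
#'   `n_sites`.
#' @param delta Fractional electrical distance from the external surface,
#'   in `[0, 1]`.
#' @param koff0 Dissociation rate at 0 mV, per second (per site).
#' @param voltage_split Fraction of the Woodhull factor placed on the on-rate
#'   (`kon(V) = kon0 * exp(split*delta*F*V/RT)`), the rest on the off-rate.
#' @param g_singly_blocked Relative conductance of the singly-occupied state
#'   of the two-site scheme, in `[0, 1]`. Default 1: only the doubly occupied
#'   state is non-conducting.
#'
#' @return An object of class `block_params`.
#' @export
block_params <- function(n_sites = 1, Kd0 = 100, delta = 0.5, koff0 = 500,
                         voltage_split = 0.5, g_singly_blocked = 1) {
  if (!n_sites %in% c(1L, 2L)) {
    abort("`n_sites` must be 1 or 2.")
  }
  n_sites <- as.integer(n_sites)
  if (!length(Kd0) %in% c(1L, n_sites) || any(!is.finite(Kd0)) || any(Kd0 <= 0)) {
    abort("`Kd0` must be positive, length 1 or `n_sites`.")
  }
  Kd0 <- rep_len(Kd0, n_sites)
  if (!is.finite(delta) || delta < 0 || delta > 1) {
    abort("`delta` must lie in [0, 1].")
  }
  if (any(!is.finite(koff0)) || any(koff0 <= 0)) abort("`koff0` must be positive.")
  koff0 <- rep_len(koff0, n_sites)
  if (!is.finite(voltage_split) || voltage_split < 0 || voltage_split > 1) {
    abort("`voltage_split` must lie in [0, 1].")
  }
  if (!is.finite(g_singly_blocked) || g_singly_blocked < 0 || g_singly_blocked > 1) {
    abort("`g_singly_blocked` must lie in [0, 1].")
  }
  structure(
    list(n_sites = n_sites, Kd0 = Kd0, delta = delta,
         kon0 = koff0 / Kd0, koff0 = koff0,
         voltage_split = voltage_split,
         g_singly_blocked = g_singly_blocked),
    class = "block_params"
  )
}

#' Gating parameters for agonist-activated channels
#'
#' Agonist gating is collapsed to a single concentration-dependent opening
#' rate `beta([A]) = beta_max * [A]^n_gate / ([A]^n_gate + EC50_gate^n_gate)`
#' against a constant closing rate `alpha`. Rectification of the macroscopic
#' current is a separate Boltzmann permeation factor (see
#' [rectification_factor()]) that multiplies the conducting occupancy and
#' therefore cancels in drug/control ratios; it does not alter the kinetic
#' scheme. Desensitisation, when enabled, adds a slowly recovering
#' non-conducting state entered from the open state.
#'
#' @param beta_max Maximal opening rate (1/s).
#' @param alpha Closing rate (1/s).
#' @param EC50_gate Agonist concentration of half-maximal opening-rate
#'   occupancy (micromolar).
#' @param n_gate Hill slope of the agonist occupancy factor.
#' @param rect_Vhalf,rect_slope Boltzmann midpoint (mV) and slope (mV) of the
#'   rectification factor; `rect_slope > 0` gives outward rectification,
#'   `< 0` inward, and a non-finite slope disables rectification (ohmic).
#' @param desens_rate Entry rate into the desensitised state (1/s); 0 disables.
#' @param resens_rate Recovery rate out of the desensitised state (1/s).
#'
#' @return An object of class `gating_params`.
#' @export
gating_params <- function(beta_max = 4000, alpha = 100, EC50_gate = 34,
                          n_gate = 1, rect_Vhalf = 0, rect_slope = Inf,
                          desens_rate = 0, resens_rate = 0.5) {
  vals <- c(beta_max = beta_max, alpha = alpha, EC50_gate = EC50_gate,
            n_gate = n_gate, desens_rate = desens_rate,
            resens_rate = resens_rate)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("gating rates and agonist parameters must be finite and >= 0.")
  }
  if (EC50_gate <= 0 || n_gate <= 0) {
    abort("`EC50_gate` and `n_gate` must be positive.")
  }
  structure(
    list(beta_max = beta_max, alpha = alpha, EC50_gate = EC50_gate,
         n_gate = n_gate, rect_Vhalf = rect_Vhalf, rect_slope = rect_slope,
         desens_rate = desens_rate, resens_rate = resens_rate),
    class = "gating_params"
  )
}

#' Boltzmann rectification factor
#'
#' Voltage-dependent permeation factor in (0, 1] applied to the conducting
#' occupancy when converting it to current. Returns 1 everywhere when the
#' slope is not finite.
#'
#' @param V Membrane potential(s), mV.
#' @param gating A [gating_params()] object.
#' @return Numeric factor(s) in (0, 1].
#' @export
rectification_factor <- function(V, gating) {
  if (!is.finite(gating$rect_slope)) return(rep(1, length(V)))
  plogis((V - gating$rect_Vhalf) / gating$rect_slope)
}

agonist_occupancy <- function(agonist, gating) {
  a <- agonist^gating$n_gate
  a / (a + gating$EC50_gate^gating$n_gate)
}

#' Build a gating + open-channel-block kinetic scheme
#'
#' Constructs the continuous-time Markov scheme used throughout the package.
#' With one blocking site the states are C (closed), O (open) and OB
#' (open-blocked, non-conducting); with two sites an additional OB2 state is
#' appended and the singly occupied state OB conducts with relative
#' conductance `block$g_singly_blocked`. When `gating$desens_rate > 0` a
#' desensitised state D (entered from O) is added. Entry rates into blocked
#' states carry the blocker concentration; the O/OB (and OB/OB2) equilibrium
#' constants reproduce the Woodhull `Kd(V)` exactly.
#'
#' @param n_sites Number of blocking sites (1 or 2).
#' @param gating A [gating_params()] object.
#' @param block A [block_params()] object; its `n_sites` must agree.
#' @param temperature Absolute temperature, kelvin.
#'
#' @return An object of class `kinetic_scheme` with elements `states`
#'   (tibble: `state`, `g`), `transitions` (tibble: `from`, `to`, `kind`),
#'   `gating`, `block` and `temperature`.
#' @export
#' @examples
#' sch <- build_block_scheme(1, gating_params(), block_params(1, Kd0 = 100, delta = 0.65))
#' sch$states
build_block_scheme <- function(n_sites, gating, block,
                               temperature = 295.15) {
  if (length(n_sites) != 1L || !n_sites %in% c(1, 2)) {
    abort("`n_sites` must be 1 or 2.")
  }
  n_sites <- as.integer(n_sites)
  stopifnot(inherits(gating, "gating_params"), inherits(block, "block_params"))
  if (block$n_sites != n_sites) {
    abort("`block$n_sites` must equal `n_sites`.")
  }
  states <- tibble(state = c("C", "O"), g = c(0, 1))
  trans <- tibble(from = c("C", "O"), to = c("O", "C"),
                  kind = c("opening", "closing"))
  states <- bind_rows(states, tibble(
    state = "OB",
    g = if (n_sites == 2L) block$g_singly_blocked else 0
  ))
  trans <- bind_rows(trans, tibble(
    from = c("O", "OB"), to = c("OB", "O"),
    kind = c("block_on_1", "block_off_1")
  ))
  if (n_sites == 2L) {
    states <- bind_rows(states, tibble(state = "OB2", g = 0))
    trans <- bind_rows(trans, tibble(
      from = c("OB", "OB2"), to = c("OB2", "OB"),
      kind = c("block_on_2", "block_off_2")
    ))
  }
  if (gating$desens_rate > 0) {
    states <- bind_rows(states, tibble(state = "D", g = 0))
    trans <- bind_rows(trans, tibble(
      from = c("O", "D"), to = c("D", "O"),
      kind = c("desens", "resens")
    ))
  }
  structure(
    list(states = states, transitions = trans, gating = gating,
         block = block, temperature = temperature),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", nrow(x$states), " states, ",
      x$block$n_sites, " blocking site(s), delta = ", x$block$delta,
      ", T = ", x$temperature, " K\n", sep = "")
  print(x$states)
  invisible(x)
}

transition_rate <- function(scheme, kind, V, agonist, blocker) {
  g <- scheme$gating
  b <- scheme$block
  rtf <- phys_constants(scheme$temperature)$RT_F_mV
  wf_on <- exp(b$voltage_split * b$delta * V / rtf)
  wf_off <- exp(-(1 - b$voltage_split) * b$delta * V / rtf)
  switch(kind,
    opening     = g$beta_max * agonist_occupancy(agonist, g),
    closing     = g$alpha,
    block_on_1  = b$kon0[1] * blocker * wf_on,
    block_off_1 = b$koff0[1] * wf_off,
    block_on_2  = b$kon0[2] * blocker * wf_on,
    block_off_2 = b$koff0[2] * wf_off,
    desens      = g$desens_rate,
    resens      = g$resens_rate,
    abort(paste0("unknown transition kind: ", kind))
  )
}

#' Transition-rate matrix of a scheme at given conditions
#'
#' Generator matrix Q with `Q[i, j]` the rate from state i to state j and
#' rows summing to zero.
#'
#' @param scheme A [build_block_scheme()] object.
#' @param V Membrane potential, mV (scalar).
#' @param agonist,blocker Concentrations, micromolar (scalars, >= 0).
#' @return A square numeric matrix with state names as dimnames.
#' @export
rate_matrix <- function(scheme, V, agonist, blocker) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(!is.finite(c(V, agonist, blocker))) || agonist < 0 || blocker < 0) {
    abort("`V`, `agonist` and `blocker` must be finite; concentrations >= 0.")
  }
  sts <- scheme$states$state
  Q <- matrix(0, length(sts), length(sts), dimnames = list(sts, sts))
  for (k in seq_len(nrow(scheme$transitions))) {
    tr <- scheme$transitions[k, ]
    Q[tr$from, tr$to] <- transition_rate(scheme, tr$kind, V, agonist, blocker)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary state occupancies of a kinetic scheme
#'
#' Solves the stationary master equation `t(Q) p = 0`, `sum(p) = 1` by a
#' dense least-squares solve of the augmented system.
#'
#' @inheritParams rate_matrix
#' @return A tibble with columns `state`, `g` and `p` (probabilities summing
#'   to 1 within 1e-10).
#' @export
#' @examples
#' sch <- build_block_scheme(1, gating_params(beta_max = 100, alpha = 100),
#'                           block_params(1, Kd0 = 100, delta = 0))
#' equilibrium_occupancy(sch, V = 0, agonist = 1e6, blocker = 0)
equilibrium_occupancy <- function(scheme, V, agonist, blocker) {
  Q <- rate_matrix(scheme, V, agonist, blocker)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- tryCatch(qr.solve(A, b), error = function(e) {
    abort(paste0("stationary solve failed (degenerate rate matrix): ",
                 conditionMessage(e)))
  })
  if (any(!is.finite(p)) || abs(sum(p) - 1) > 1e-8 || any(p < -1e-8)) {
    abort("stationary solve produced an invalid distribution; the scheme may be disconnected.")
  }
  p <- unname(pmax(p, 0))
  p <- p / sum(p)
  tibble(state = scheme$states$state, g = scheme$states$g, p = p)
}

#' Fraction of current remaining in the presence of blocker
#'
#' Equilibrium conducting occupancy with blocker relative to blocker-free
#' control, `sum(g_i p_i(c)) / sum(g_i p_i(0))`. Equals 1 at zero blocker and
#' is non-increasing in blocker concentration. The rectification factor
#' cancels and is not applied here.
#'
#' @param scheme A [build_block_scheme()] object.
#' @param V Membrane potential(s), mV.
#' @param agonist Agonist concentration, micromolar (scalar).
#' @param blocker Blocker concentration(s), micromolar. `V` and `blocker` are
#'   recycled to a common length.
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' sch <- build_block_scheme(1, gating_params(), block_params(1, Kd0 = 50, delta = 0.3))
#' fraction_current(sch, V = 0, agonist = 30, blocker = c(0, 50, 500))
fraction_current <- function(scheme, V, agonist, blocker) {
  nn <- max(length(V), length(blocker))
  V <- rep_len(V, nn)
  blocker <- rep_len(blocker, nn)
  map_dbl(seq_len(nn), function(i) {
    ctrl <- equilibrium_occupancy(scheme, V[i], agonist, 0)
    g_ctrl <- sum(ctrl$g * ctrl$p)
    if (g_ctrl <= 0) {
      abort("zero conducting occupancy in control; cannot form a fraction.")
    }
    occ <- equilibrium_occupancy(scheme, V[i], agonist, blocker[i])
    sum(occ$g * occ$p) / g_ctrl
  })
}

#' Serialize a kinetic scheme to JSON
#'
#' @param scheme A [build_block_scheme()] object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  obj <- list(
    states = scheme$states,
    transitions = scheme$transitions,
    params = list(gating = unclass(scheme$gating),
                  block = unclass(scheme$block)),
    constants = phys_constants(scheme$temperature)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a kinetic scheme from JSON
#'
#' @param json A JSON string or path to a JSON file produced by
#'   [scheme_to_json()].
#' @return A `kinetic_scheme` object.
#' @export
scheme_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  g <- do.call(gating_params, obj$params$gating[
    intersect(names(obj$params$gating), names(formals(gating_params)))])
  bp <- obj$params$block
  b <- block_params(n_sites = bp$n_sites, Kd0 = bp$Kd0, delta = bp$delta,
                    koff0 = bp$koff0, voltage_split = bp$voltage_split,
                    g_singly_blocked = bp$g_singly_blocked)
  build_block_scheme(bp$n_sites, g, b, temperature = obj$constants$T)
}
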