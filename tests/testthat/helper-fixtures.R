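## Shared fixtures. Gating with a vanishing closed-state occupancy makes the
## analytic open-channel identities (IC50 == Kd, 50% block at c == Kd) exact
## to the tolerances tested.
sat_gating <- function(...) {
  gating_params(beta_max = 5e4, alpha = 5, EC50_gate = 1, ...)
}

sat_scheme <- function(delta = 0.65, Kd0 = 40, n_sites = 1, g2 = 1,
                       koff0 = 500, ...) {
  build_block_scheme(
    n_sites,
    sat_gating(...),
    block_params(n_sites, Kd0 = Kd0, delta = delta, koff0 = koff0,
                 g_singly_blocked = g2)
  )
}

quiet_config <- function(...) {
  recording_config(noise_sd_pA = 0, amp_noise_cv = 0, Imax_cell_cv = 0, ...)
}

## One reduced two-subtype pulling scan over levels 2'-6', shared by the
## porescan unit tests and the acceptance property suite (computed once).
.scan_cache <- new.env(parent = emptyenv())
cached_pore_scan <- function() {
  if (!is.null(.scan_cache$res)) return(.scan_cache$res)
  lig <- build_nfa()
  p1 <- build_pore("alpha1")
  p2 <- build_pore("alpha2")
  res <- compare_profiles(p1, p2, lig, z_from = level_z(p1, 2),
                          z_to = level_z(p1, 6), step = 1.5,
                          stop_after = 20, maxit = 15, seed = 11)
  .scan_cache$res <- res
  res
}
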