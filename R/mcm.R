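#' Monte-Carlo energy minimization (MCM)
#'
#' Generic minimizer alternating random perturbation, local gradient
#' minimization and Metropolis acceptance, with the stop rule of the pulling
#' protocol: the run terminates when `stop_after` consecutive local
#' minimizations fail to decrease the best energy found. The best-so-far
#' energy trace is monotonically non-increasing by construction, and the
#' best pose is always returned.
#'
#' @param fn Objective function of a numeric parameter vector (kcal/mol for
#'   molecular poses, but any scalar objective works).
#' @param x0 Starting parameter vector.
#' @param step Perturbation half-widths per parameter (uniform moves),
#'   recycled to `length(x0)`.
#' @param stop_after Consecutive non-improving minimizations that end the
#'   run (default 100).
#' @param temperature_K Metropolis temperature, kelvin (default 600).
#' @param seed Optional integer seed.
#' @param maxit Iteration cap of each local minimization.
#' @param max_minimizations Hard cap on total minimizations (safety).
#'
#' @return A list with `par` (best parameters), `value` (best energy),
#'   `n_minimizations`, `n_since_best` (always `stop_after` on normal
#'   termination), `trace` (tibble: minimization, value, best).
#' @export
#' @examples
#' bowl <- function(x) sum((x - c(1, -2))^2)
#' mc_minimize(bowl, c(5, 5), step = 1, stop_after = 20, seed = 1)$par
mc_minimize <- function(fn, x0, step = 0.5, stop_after = 100,
                        temperature_K = 600, seed = NULL, maxit = 40,
                        max_minimizations = 5000) {
  if (!is.null(seed)) set.seed(seed)
  step <- rep_len(step, length(x0))
  kT <- 0.0019872041 * temperature_K   # kcal/mol
  local_min <- function(x) {
    op <- optim(x, fn, method = "BFGS",
                control = list(maxit = maxit, reltol = 1e-9))
    list(par = op$par, value = op$value)
  }
  cur <- local_min(x0)
  best <- cur
  n_min <- 1L
  since_best <- 0L
  tr <- list(tibble(minimization = 1L, value = cur$value, best = best$value))
  while (since_best < stop_after && n_min < max_minimizations) {
    ## occasional large moves help escape jammed poses
    kick <- if (runif(1) < 0.2) 4 else 1
    cand0 <- cur$par + runif(length(x0), -1, 1) * step * kick
    cand <- local_min(cand0)
    n_min <- n_min + 1L
    if (cand$value < best$value - 1e-9) {
      best <- cand
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    ## Metropolis acceptance of the new current point
    if (cand$value <= cur$value ||
        runif(1) < exp(-(cand$value - cur$value) / kT)) {
      cur <- cand
    }
    tr[[length(tr) + 1L]] <- tibble(minimization = n_min, value = cand$value,
                                    best = best$value)
  }
  list(par = best$par, value = best$value, n_minimizations = n_min,
       n_since_best = since_best, trace = list_rbind(tr))
}

## Pose parameterization: par = (tx, ty, tz, rx, ry, rz, torsions...).
## The rigid-body rotation pivots about the ligand's N1 atom, so the plane
## constraint depends only on tz.
pose_ligand <- function(ligand, par, template_xyz, template_phi) {
  n_tor <- length(ligand$torsions)
  phi <- par[6 + seq_len(n_tor)]
  xyz <- apply_torsions_xyz(template_xyz, ligand$torsions, template_phi, phi)
  Rm <- rotvec_matrix(par[4:6])
  pivot <- template_xyz[ligand$n1, ]
  xyz <- sweep(sweep(xyz, 2, pivot) %*% t(Rm), 2, -(pivot + par[1:3]))
  set_ligand_xyz(ligand, xyz)
}

#' Profile levels of a pulling scan
#' @param z_from,z_to Scan range along the pore axis, Angstrom.
#' @param step Step, Angstrom (default 0.5).
#' @return Numeric vector of z levels, both ends included.
#' @export
profile_levels <- function(z_from, z_to, step = 0.5) {
  if (z_to < z_from) abort("`z_to` must not be below `z_from`.")
  seq(z_from, z_to, by = step)
}

#' Pull a ligand through the pore and record the energy profile
#'
#' Implements the pulling protocol: the ligand's N1 atom is constrained to a
#' plane normal to the pore axis at each level of a 0.5 Angstrom scan from
#' the cytoplasmic (below -2') to the extracellular (20') end, with a
#' flat-bottom radial constraint (6 Angstrom) preventing escape from the
#' pore and C-alpha pins preserving the fold. At each level the energy is
#' MC-minimized until `stop_after` consecutive minimizations do not improve
#' the best energy; the search at each level starts from the previous
#' level's best pose.
#'
#' @param pore A [build_pore()] model.
#' @param ligand A [build_nfa()] conformer (or compatible).
#' @param z_from,z_to Scan range, Angstrom (defaults: 1.5 Angstrom below the
#'   -2' level to the 20' level).
#' @param step Level spacing, Angstrom.
#' @param stop_after MCM stop rule per level.
#' @param seed Integer seed.
#' @param maxit Local-minimization iteration cap.
#'
#' @return An `energy_profile` tibble: `z`, `prime_level`, `E_total`,
#'   `E_vdw`, `E_elec`, `E_hbond`, `E_ligand`, `E_constraint`, `clash`;
#'   attribute `poses` holds the best pose per level.
#' @export
pull_profile <- function(pore, ligand, z_from = NULL, z_to = NULL,
                         step = 0.5, stop_after = 100, seed = 1,
                         maxit = 25, k_plane = 400) {
  stopifnot(inherits(pore, "pore_model"))
  z_from <- z_from %||% (level_z(pore, -2) - 1.5)
  z_to <- z_to %||% level_z(pore, 20)
  zr <- range(pore$levels$z)
  if (z_from < zr[1] - 3 || z_to > zr[2] + 3) {
    abort("scan range extends beyond the pore model.")
  }
  levels <- profile_levels(z_from, z_to, step)
  set.seed(seed)
  n_tor <- length(ligand$torsions)
  ## start: ligand on the axis at the first level, long axis along z
  lig0 <- orient_ligand_axis(ligand)
  start_par <- c(0, 0, z_from - ligand_xyz(lig0)[lig0$n1, 3],
                 0, 0, 0, ligand_torsion_angles(lig0))
  tmpl_xyz <- ligand_xyz(lig0)
  tmpl_phi <- ligand_torsion_angles(lig0)
  par <- start_par
  rows <- list()
  poses <- list()
  step_sizes <- c(rep(1, 3), rep(deg2rad(30), 3), rep(30, n_tor))
  for (li in seq_along(levels)) {
    zl <- levels[li]
    cons <- make_constraints(plane_z = zl, radial_max = 6, pins = TRUE,
                             k_plane = k_plane)
    obj <- compile_pose_energy(pore, lig0, cons, z_window = zl + c(-16, 16))
    par[3] <- par[3] + (if (li == 1) 0 else step)
    res <- mc_minimize(obj, par, step = step_sizes, stop_after = stop_after,
                       seed = sample.int(.Machine$integer.max - 1L, 1),
                       maxit = maxit)
    ## a second, shorter search from the canonical axis-aligned placement
    ## guards against jammed poses propagating from level to level
    fresh <- start_par
    fresh[3] <- zl - tmpl_xyz[lig0$n1, 3]
    res2 <- mc_minimize(obj, fresh, step = step_sizes,
                        stop_after = max(5L, ceiling(stop_after / 2)),
                        seed = sample.int(.Machine$integer.max - 1L, 1),
                        maxit = maxit)
    if (res2$value < res$value) res <- res2
    ## polish the best pose so the reported point is a true local minimum
    ## (drives the soft-constraint penalty to its equilibrium, near zero)
    pol <- optim(res$par, obj, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-11))
    par <- if (pol$value < res$value) pol$par else res$par
    best_lig <- pose_ligand(lig0, par, tmpl_xyz, tmpl_phi)
    ie <- interaction_energy(pore, best_lig, cons)
    if (li == 1 && ie$clash) {
      abort("could not place the ligand at the first level without a clash.")
    }
    ee <- setNames(ie$terms$energy, ie$terms$term)
    rows[[li]] <- tibble(
      z = zl, prime_level = zl / 1.5 - 2,
      E_total = ie$total, E_vdw = ee[["vdw"]], E_elec = ee[["elec"]],
      E_hbond = ee[["hbond"]], E_ligand = ee[["ligand_internal"]],
      E_constraint = ee[["constraint"]], clash = ie$clash
    )
    poses[[li]] <- best_lig
  }
  out <- list_rbind(rows)
  structure(out, poses = poses, subtype = pore$subtype, seed = seed,
            class = c("energy_profile", class(out)))
}

## rotate the ligand so its longest axis lies along z (pulling direction)
orient_ligand_axis <- function(ligand) {
  xyz <- ligand_xyz(ligand)
  cc <- sweep(xyz, 2, colMeans(xyz))
  ax <- svd(cc)$v[, 1]
  rot_axis <- crossv(ax, c(0, 0, 1))
  if (vnorm(rot_axis) < 1e-8) return(ligand)
  ang <- acos(pmin(pmax(sum(ax * c(0, 0, 1)), -1), 1))
  Rm <- rotvec_matrix(unitv(rot_axis) * ang)
  set_ligand_xyz(ligand, cc %*% t(Rm))
}

#' Write an energy profile as TSV
#' @param profile An `energy_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path, progress = FALSE)
  invisible(path)
}

#' Dock a second ligand above the 9' constriction
#'
#' Starting from a single-ligand complex at the 13' level, MC-minimizes a
#' two-ligand complex with both N1 atoms constrained above the 9' leucine
#' ring (one-sided floor constraint) and within the 6 Angstrom radial
#' flat-bottom. Reports the decomposed energy, the inter-ligand van der
#' Waals energy and the hydrogen-bond inventory of the complex.
#'
#' @param pore A [build_pore()] model (the two-molecule block concerns the
#'   alpha1-type pore).
#' @param ligand A [build_nfa()] conformer.
#' @param level Prime level of the first ligand (default 13).
#' @param stop_after,maxit MCM controls.
#' @param seed Integer seed.
#'
#' @return A list with `ligands` (list of two posed conformers), `energy`
#'   (decomposition from [interaction_energy()]), `interligand_vdw`
#'   (kcal/mol), `hbonds` (from [hbond_contacts()]).
#' @export
dock_two_ligands <- function(pore, ligand, level = 13, stop_after = 50,
                             maxit = 30, seed = 1) {
  set.seed(seed)
  z1 <- level_z(pore, level)
  z9 <- level_z(pore, 9)
  lig0 <- orient_ligand_axis(ligand)
  ## flatten the long axis into the xy plane for in-pore stacking
  Rm <- rotvec_matrix(c(0, deg2rad(90), 0))
  lig0 <- set_ligand_xyz(lig0, ligand_xyz(lig0) %*% t(Rm))
  tmpl_xyz <- ligand_xyz(lig0)
  tmpl_phi <- ligand_torsion_angles(lig0)
  n_tor <- length(lig0$torsions)
  n1z <- tmpl_xyz[lig0$n1, 3]
  np <- 6 + n_tor

  ## stage 1: place the first ligand at the target level
  pr1 <- pull_profile(pore, ligand, z_from = z1, z_to = z1, step = 0.5,
                      stop_after = stop_after, maxit = maxit,
                      seed = sample.int(.Machine$integer.max - 1L, 1))
  l1 <- attr(pr1, "poses")[[1]]

  ## stage 2: MC-minimize the second ligand in the field of pore + ligand 1,
  ## with both central nitrogens confined above the 9\' ring and within the
  ## docking band of the site; small moves keep the search local to the
  ## stacked complex being built
  pseudo <- pore
  l1a <- l1$atoms
  pseudo$atoms <- bind_rows(
    pore$atoms,
    tibble(chain = 0L, resno = 0L, resname = "NFA", prime = NA_integer_,
           bead = "LIG", x = l1a$x, y = l1a$y, z = l1a$z,
           ## quarter charges: ligand-ligand electrostatics are screened
           ## fourfold (eps = 4r), as in the two-ligand evaluators
           charge = 0.25 * l1a$charge, radius = l1a$radius, eps = l1a$eps,
           hbd = l1a$hb_donor_h, hba = l1a$hb_acceptor)
  )
  cons2 <- make_constraints(radial_max = 6, floor_z = z9 + 0.5,
                            ceiling_z = z1 + 2.5, pins = TRUE, k_plane = 100)
  obj2 <- compile_pose_energy(pseudo, lig0, cons2)
  start2 <- c(0, 0, z1 + 3.5 - n1z, 0, 0, deg2rad(180), tmpl_phi)
  res2 <- mc_minimize(obj2, start2,
                      step = c(rep(0.5, 3), rep(deg2rad(15), 3),
                               rep(15, n_tor)),
                      stop_after = stop_after,
                      seed = sample.int(.Machine$integer.max - 1L, 1),
                      maxit = maxit)

  ## stage 3: joint local refinement of the complex
  cons <- make_constraints(radial_max = 6, floor_z = z9 + 0.5,
                           ceiling_z = z1 + 2.5, pins = TRUE, k_plane = 100)
  obj12 <- compile_pose_energy2(pore, lig0, cons)
  l1_par <- pose_par_from_xyz(lig0, l1, tmpl_xyz, tmpl_phi)
  joint <- optim(c(l1_par, res2$par), obj12, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10))
  l1 <- pose_ligand(lig0, joint$par[1:np], tmpl_xyz, tmpl_phi)
  l2 <- pose_ligand(lig0, joint$par[np + 1:np], tmpl_xyz, tmpl_phi)
  ie <- interaction_energy(pore, list(l1, l2), cons)
  l2a <- l2$atoms
  inter <- pair_energy(ligand_xyz(l1), l1$atoms, ligand_xyz(l2),
                       dplyr::rename(l2a, hbd = "hb_donor_h",
                                     hba = "hb_acceptor"))
  list(ligands = list(l1, l2), energy = ie,
       interligand_vdw = inter$vdw,
       hbonds = hbond_contacts(pore, list(l1, l2)),
       mcm = res2[c("value", "n_minimizations", "n_since_best")])
}

## Recover pose parameters of a posed conformer relative to the template:
## translation of N1 plus the rotation (via Kabsch) and its torsions.
pose_par_from_xyz <- function(lig0, posed, tmpl_xyz, tmpl_phi) {
  phi <- ligand_torsion_angles(posed)
  t_xyz <- apply_torsions_xyz(tmpl_xyz, lig0$torsions, tmpl_phi, phi)
  pivot <- tmpl_xyz[lig0$n1, ]
  A <- sweep(t_xyz, 2, pivot)
  pxyz <- ligand_xyz(posed)
  B <- sweep(pxyz, 2, pxyz[lig0$n1, ])
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  ## rotation vector from the rotation matrix
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
  if (ang < 1e-9) {
    rv <- c(0, 0, 0)
  } else {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    rv <- unitv(ax) * ang
  }
  tr <- pxyz[lig0$n1, ] - pivot
  c(tr, rv, phi)
}

#' Paired energy profiles of two pore models
#'
#' Scans two pore models that differ locally (e.g. the alpha1/alpha2 pair,
#' identical except for the 2' ring) over the same levels with pose sharing:
#' at every level each model is MC-minimized from its own chained pose, and
#' the best poses of both models (plus a fresh axis-aligned placement) are
#' then locally re-minimized in *each* model, the best result winning. Pose
#' sharing symmetrises the stochastic search, so the paired difference
#' between the profiles isolates the structural difference between the
#' models instead of sampling luck.
#'
#' @param pore_a,pore_b Two [build_pore()] models.
#' @param ligand A [build_nfa()] conformer.
#' @param z_from,z_to,step Scan range and spacing, Angstrom.
#' @param stop_after,maxit,seed,k_plane As in [pull_profile()].
#' @return A list of two `energy_profile` tibbles named after the model
#'   subtypes.
#' @export
compare_profiles <- function(pore_a, pore_b, ligand, z_from, z_to,
                             step = 0.5, stop_after = 100, maxit = 25,
                             seed = 1, k_plane = 400) {
  levels <- profile_levels(z_from, z_to, step)
  set.seed(seed)
  lig0 <- orient_ligand_axis(ligand)
  tmpl_xyz <- ligand_xyz(lig0)
  tmpl_phi <- ligand_torsion_angles(lig0)
  n_tor <- length(lig0$torsions)
  step_sizes <- c(rep(1, 3), rep(deg2rad(30), 3), rep(30, n_tor))
  start_par <- c(0, 0, levels[1] - tmpl_xyz[lig0$n1, 3], 0, 0, 0, tmpl_phi)
  pars <- list(a = start_par, b = start_par)
  pores <- list(a = pore_a, b = pore_b)
  rows <- list(a = list(), b = list())
  poses <- list(a = list(), b = list())
  for (li in seq_along(levels)) {
    zl <- levels[li]
    cons <- make_constraints(plane_z = zl, radial_max = 6, pins = TRUE,
                             k_plane = k_plane)
    objs <- map(pores, compile_pose_energy, ligand = lig0,
                constraints = cons, z_window = zl + c(-16, 16))
    if (li > 1) pars <- map(pars, function(p) { p[3] <- p[3] + step; p })
    found <- map2(objs, pars, function(obj, p) {
      mc_minimize(obj, p, step = step_sizes, stop_after = stop_after,
                  seed = sample.int(.Machine$integer.max - 1L, 1),
                  maxit = maxit)$par
    })
    fresh <- start_par
    fresh[3] <- zl - tmpl_xyz[lig0$n1, 3]
    cand <- c(unname(found), list(fresh))
    for (m in c("a", "b")) {
      pol <- map(cand, function(p) {
        optim(p, objs[[m]], method = "BFGS",
              control = list(maxit = 200, reltol = 1e-11))
      })
      best <- pol[[which.min(map_dbl(pol, "value"))]]
      pars[[m]] <- best$par
      posed <- pose_ligand(lig0, best$par, tmpl_xyz, tmpl_phi)
      ie <- interaction_energy(pores[[m]], posed, cons)
      ee <- setNames(ie$terms$energy, ie$terms$term)
      rows[[m]][[li]] <- tibble(
        z = zl, prime_level = zl / 1.5 - 2,
        E_total = ie$total, E_vdw = ee[["vdw"]], E_elec = ee[["elec"]],
        E_hbond = ee[["hbond"]], E_ligand = ee[["ligand_internal"]],
        E_constraint = ee[["constraint"]], clash = ie$clash
      )
      poses[[m]][[li]] <- posed
    }
  }
  out <- map2(rows, c("a", "b"), function(r, m) {
    pr <- list_rbind(r)
    structure(pr, poses = poses[[m]],
              subtype = pores[[m]]$subtype, seed = seed,
              class = c("energy_profile", class(pr)))
  })
  setNames(out, c(pore_a$subtype, pore_b$subtype))
}
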