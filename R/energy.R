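## Ligand-pore interaction energy: pairwise-additive 12-6 van der Waals,
## Coulomb electrostatics with distance-dependent dielectric (eps = r, i.e.
## E = 332*qi*qj/r^2 kcal/mol with r in Angstrom), a 10-12 H-bond term
## between donor/acceptor pairs, an 8 Angstrom nonbond cutoff with a smooth
## switching window, and capped repulsion with a clash flag below 0.1 A.

COULOMB_K <- 332.0636
NB_CUTOFF <- 8
NB_SWITCH <- 7

switch_factor <- function(d, r_on = NB_SWITCH, r_off = NB_CUTOFF) {
  x <- (r_off - d) / (r_off - r_on)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x * x * (3 - 2 * x)
}

#' Interaction energy of a ligand pose with a pore model
#'
#' Pairwise-additive energy of the ligand's atoms against the pore beads:
#' van der Waals (12-6), electrostatic (Coulomb with distance-dependent
#' dielectric), H-bond (10-12 between donors and acceptors), the ligand's
#' internal (torsion + intramolecular) energy, and the penalty energy of any
#' supplied constraints. The decomposition sums to the total exactly. Pairs
#' closer than 0.1 Angstrom are flagged as clashes and their repulsion is
#' evaluated at 0.1 Angstrom (capped).
#'
#' @param pore A [build_pore()] model.
#' @param ligand A `ligand_conformer` in its current pose. For two-ligand
#'   complexes pass a list of conformers; ligand-ligand terms are included.
#' @param constraints Optional list of constraints from [make_constraints()].
#' @return A list with `total` (kcal/mol), `terms` (tibble: `term`,
#'   `energy`), `clash` (logical).
#' @export
interaction_energy <- function(pore, ligand, constraints = NULL) {
  ligs <- if (inherits(ligand, "ligand_conformer")) list(ligand) else ligand
  stopifnot(inherits(pore, "pore_model"))
  e_vdw <- 0; e_elec <- 0; e_hb <- 0; e_int <- 0
  clash <- FALSE
  pa <- pore$atoms
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  for (lig in ligs) {
    lxyz <- ligand_xyz(lig)
    la <- lig$atoms
    pw <- pair_energy(lxyz, la, pxyz, pa)
    e_vdw <- e_vdw + pw$vdw; e_elec <- e_elec + pw$elec
    e_hb <- e_hb + pw$hb; clash <- clash || pw$clash
    e_int <- e_int + ligand_internal_energy(lig)
  }
  if (length(ligs) == 2) {
    l2 <- ligs[[2]]$atoms
    l2$bead <- "LIG"
    pw <- pair_energy(ligand_xyz(ligs[[1]]), ligs[[1]]$atoms,
                      ligand_xyz(ligs[[2]]),
                      dplyr::rename(l2, hbd = "hb_donor_h",
                                    hba = "hb_acceptor"),
                      elec_scale = 0.25)
    e_vdw <- e_vdw + pw$vdw; e_elec <- e_elec + pw$elec
    e_hb <- e_hb + pw$hb; clash <- clash || pw$clash
  }
  e_con <- sum(map_dbl(constraints %||% list(), constraint_energy,
                       ligands = ligs, pore = pore))
  terms <- tibble(
    term = c("vdw", "elec", "hbond", "ligand_internal", "constraint"),
    energy = c(e_vdw, e_elec, e_hb, e_int, e_con)
  )
  list(total = sum(terms$energy), terms = terms, clash = clash)
}

## all-pairs energies between a ligand atom set and a bead/atom set;
## `elec_scale` implements the stronger dielectric screening of
## ligand-ligand (like-charge) pairs in the water-filled pore (eps = 4r)
pair_energy <- function(lxyz, la, pxyz, pa, elec_scale = 1) {
  nl <- nrow(lxyz); np <- nrow(pxyz)
  d2 <- outer(rowSums(lxyz^2), rep(1, np)) +
    outer(rep(1, nl), rowSums(pxyz^2)) - 2 * lxyz %*% t(pxyz)
  d <- sqrt(pmax(d2, 0))
  clash <- any(d < 0.1)
  dcap <- pmax(d, 0.1)
  within <- d < NB_CUTOFF
  sw <- switch_factor(dcap)
  rmin <- outer(la$radius, pa$radius, `+`)
  epsij <- sqrt(outer(la$eps, pa$eps))
  rr <- (rmin / dcap)^6
  vdw <- sum((epsij * (rr^2 - 2 * rr) * sw)[within])
  qq <- outer(la$charge, pa$charge)
  elec <- elec_scale * sum((COULOMB_K * qq / dcap^2 * sw)[within])
  ## H-bonds: ligand explicit polar H vs acceptor beads; ligand acceptors vs
  ## donor beads (heavy-atom distance form)
  hb <- 0
  for (h in which(la$hb_donor_h)) {
    for (a in which(pa$hba)) {
      if (d[h, a] > 5) next
      hb <- hb + hbond_energy(NULL, lxyz[h, ], pxyz[a, ], eps_hb = 2.5,
                              r0 = 1.9)
    }
  }
  for (a in which(la$hb_acceptor)) {
    for (don in which(pa$hbd)) {
      if (d[a, don] > 5) next
      hb <- hb + hbond_energy(NULL, pxyz[don, ], lxyz[a, ], eps_hb = 2.5,
                              r0 = 2.9)
    }
  }
  list(vdw = vdw, elec = elec, hb = hb, clash = clash)
}

#' Constraints for pore-pulling and docking
#'
#' Builds the constraint set of the pulling protocol: a plane constraint
#' holding the ligand's N1 atom at a target z (parabolic), a flat-bottom
#' radial constraint allowing N1 to deviate up to 6 Angstrom from the pore
#' axis (parabolic outside), a one-sided floor constraint (parabolic below a
#' minimum z), and pin constraints tying the model C-alphas to their template
#' positions (penalty-free up to 1 Angstrom, then linear at 10 kcal/mol per
#' Angstrom).
#'
#' @param plane_z Target z for atom N1 (`NULL` to omit), Angstrom.
#' @param radial_max Flat-bottom radius about the axis, Angstrom.
#' @param floor_z One-sided lower bound on N1 z (`NULL` to omit).
#' @param ceiling_z One-sided upper bound on N1 z (`NULL` to omit).
#' @param pins Include C-alpha pin constraints.
#' @param k_plane,k_radial Parabolic force constants (kcal/mol/A^2).
#' @param pin_free,pin_slope Pin flat-bottom radius (Angstrom) and linear
#'   slope (kcal/mol/A).
#' @param ligand_index Which ligand(s) of a multi-ligand complex the N1
#'   constraints apply to (default: all).
#' @return A list of constraint objects.
#' @export
make_constraints <- function(plane_z = NULL, radial_max = 6, floor_z = NULL,
                             ceiling_z = NULL,
                             pins = TRUE, k_plane = 10, k_radial = 10,
                             pin_free = 1, pin_slope = 10,
                             ligand_index = NULL) {
  cons <- list()
  if (!is.null(plane_z)) {
    cons <- c(cons, list(list(kind = "plane", z = plane_z, k = k_plane,
                              ligand_index = ligand_index)))
  }
  if (!is.null(radial_max)) {
    cons <- c(cons, list(list(kind = "radial", rmax = radial_max,
                              k = k_radial, ligand_index = ligand_index)))
  }
  if (!is.null(floor_z)) {
    cons <- c(cons, list(list(kind = "floor", z = floor_z, k = k_plane,
                              ligand_index = ligand_index)))
  }
  if (!is.null(ceiling_z)) {
    cons <- c(cons, list(list(kind = "ceiling", z = ceiling_z, k = k_plane,
                              ligand_index = ligand_index)))
  }
  if (pins) {
    cons <- c(cons, list(list(kind = "pin", free = pin_free,
                              slope = pin_slope)))
  }
  cons
}

constraint_energy <- function(con, ligands, pore) {
  idx <- con$ligand_index %||% seq_along(ligands)
  if (con$kind == "pin") {
    ca <- filter(pore$atoms, .data$bead == "CA")
    tpl <- pore$template
    dev <- sqrt((ca$x - tpl$x)^2 + (ca$y - tpl$y)^2 + (ca$z - tpl$z)^2)
    return(sum(pmax(dev - con$free, 0) * con$slope))
  }
  e <- 0
  for (i in idx) {
    n1 <- ligand_xyz(ligands[[i]])[ligands[[i]]$n1, ]
    e <- e + switch(con$kind,
      plane = con$k * (n1[3] - con$z)^2,
      radial = {
        r <- sqrt(n1[1]^2 + n1[2]^2)
        con$k * max(r - con$rmax, 0)^2
      },
      floor = con$k * max(con$z - n1[3], 0)^2,
      ceiling = con$k * max(n1[3] - con$z, 0)^2,
      abort(paste0("unknown constraint kind: ", con$kind))
    )
  }
  e
}

#' Inventory of ligand-pore and ligand-ligand hydrogen-bond contacts
#'
#' Lists donor/acceptor pairs whose H...acceptor (explicit-H donors) or
#' donor...acceptor (bead donors) distance is below `max_dist`.
#'
#' @param pore A `pore_model`.
#' @param ligands A `ligand_conformer` or list of them.
#' @param max_dist Contact cutoff, Angstrom (default 2.6 for explicit-H
#'   donors; bead donors use `max_dist + 1`).
#' @return A tibble: `donor`, `acceptor`, `distance_A`, `resname`, `prime`.
#' @export
hbond_contacts <- function(pore, ligands, max_dist = 2.6) {
  if (inherits(ligands, "ligand_conformer")) ligands <- list(ligands)
  pa <- pore$atoms
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  rows <- list()
  for (li in seq_along(ligands)) {
    lig <- ligands[[li]]
    lxyz <- ligand_xyz(lig)
    for (don in which(pa$hbd)) {
      for (a in which(lig$atoms$hb_acceptor)) {
        dd <- sqrt(sum((pxyz[don, ] - lxyz[a, ])^2))
        if (dd <= max_dist + 1) {
          rows[[length(rows) + 1L]] <- tibble(
            donor = paste0(pa$resname[don], pa$resno[don], ".", pa$chain[don]),
            acceptor = paste0("lig", li, ":", lig$atoms$name[a]),
            distance_A = dd, resname = pa$resname[don], prime = pa$prime[don]
          )
        }
      }
    }
    for (h in which(lig$atoms$hb_donor_h)) {
      for (acc in which(pa$hba)) {
        dd <- sqrt(sum((lxyz[h, ] - pxyz[acc, ])^2))
        if (dd <= max_dist) {
          rows[[length(rows) + 1L]] <- tibble(
            donor = paste0("lig", li, ":", lig$atoms$name[h]),
            acceptor = paste0(pa$resname[acc], pa$resno[acc], ".",
                              pa$chain[acc]),
            distance_A = dd, resname = pa$resname[acc], prime = pa$prime[acc]
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(donor = character(), acceptor = character(),
                  distance_A = numeric(), resname = character(),
                  prime = integer()))
  }
  list_rbind(rows)
}
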