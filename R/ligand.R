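.glyrblock_cache <- new.env(parent = emptyenv())

## Ligand module: a flexible all-atom model of anionic niflumic acid
## (2-{[3-(trifluoromethyl)phenyl]amino}nicotinate), built from standard bond
## lengths and angles with rotatable torsions and a minimal internal force
## field (periodic torsion potentials, intramolecular van der Waals beyond
## 3 bonds, and an explicit N-H...O hydrogen-bond term).

nfa_zmatrix <- function(tCOO = 90, tCN = 180, tNPh = 0, tCF3 = 60) {
  list(
    list(name = "N1r"),
    list(name = "C2",  i = 1, bond = 1.345),
    list(name = "C3",  i = 2, j = 1, bond = 1.40, angle = 120),
    list(name = "C4",  i = 3, j = 2, k = 1, bond = 1.39, angle = 120, dihedral = 0),
    list(name = "C5",  i = 4, j = 3, k = 2, bond = 1.39, angle = 120, dihedral = 0),
    list(name = "C6",  i = 5, j = 4, k = 3, bond = 1.39, angle = 120, dihedral = 0),
    list(name = "C7",  i = 3, j = 2, k = 1, bond = 1.50, angle = 120, dihedral = 180),
    list(name = "O1",  i = 7, j = 3, k = 2, bond = 1.25, angle = 117, dihedral = tCOO),
    list(name = "O2",  i = 7, j = 3, k = 2, bond = 1.25, angle = 117, dihedral = tCOO + 180),
    list(name = "N1",  i = 2, j = 3, k = 4, bond = 1.37, angle = 120, dihedral = 180),
    list(name = "HN",  i = 10, j = 2, k = 3, bond = 1.01, angle = 116, dihedral = tCN - 180),
    list(name = "C1p", i = 10, j = 2, k = 3, bond = 1.40, angle = 131, dihedral = tCN),
    list(name = "C2p", i = 12, j = 10, k = 2, bond = 1.40, angle = 118, dihedral = tNPh),
    list(name = "C3p", i = 13, j = 12, k = 10, bond = 1.39, angle = 120, dihedral = 180),
    list(name = "C4p", i = 14, j = 13, k = 12, bond = 1.39, angle = 120, dihedral = 0),
    list(name = "C5p", i = 15, j = 14, k = 13, bond = 1.39, angle = 120, dihedral = 0),
    list(name = "C6p", i = 16, j = 15, k = 14, bond = 1.39, angle = 120, dihedral = 0),
    list(name = "C8",  i = 14, j = 13, k = 12, bond = 1.50, angle = 120, dihedral = 180),
    list(name = "F1",  i = 18, j = 14, k = 13, bond = 1.33, angle = 112, dihedral = tCF3),
    list(name = "F2",  i = 18, j = 14, k = 13, bond = 1.33, angle = 112, dihedral = tCF3 + 120),
    list(name = "F3",  i = 18, j = 14, k = 13, bond = 1.33, angle = 112, dihedral = tCF3 - 120),
    list(name = "H4",  i = 4, j = 3, k = 2, bond = 1.08, angle = 120, dihedral = 180),
    list(name = "H5",  i = 5, j = 4, k = 3, bond = 1.08, angle = 120, dihedral = 180),
    list(name = "H6",  i = 6, j = 5, k = 4, bond = 1.08, angle = 120, dihedral = 180),
    list(name = "H2p", i = 13, j = 12, k = 10, bond = 1.08, angle = 120, dihedral = tNPh + 180),
    list(name = "H4p", i = 15, j = 14, k = 13, bond = 1.08, angle = 120, dihedral = 180),
    list(name = "H5p", i = 16, j = 15, k = 14, bond = 1.08, angle = 120, dihedral = 180),
    list(name = "H6p", i = 17, j = 16, k = 15, bond = 1.08, angle = 120, dihedral = 180)
  )
}

nfa_bonds <- function() {
  pairs <- rbind(
    c("N1r", "C2"), c("C2", "C3"), c("C3", "C4"), c("C4", "C5"),
    c("C5", "C6"), c("C6", "N1r"),
    c("C3", "C7"), c("C7", "O1"), c("C7", "O2"),
    c("C2", "N1"), c("N1", "HN"), c("N1", "C1p"),
    c("C1p", "C2p"), c("C2p", "C3p"), c("C3p", "C4p"), c("C4p", "C5p"),
    c("C5p", "C6p"), c("C6p", "C1p"),
    c("C3p", "C8"), c("C8", "F1"), c("C8", "F2"), c("C8", "F3"),
    c("C4", "H4"), c("C5", "H5"), c("C6", "H6"),
    c("C2p", "H2p"), c("C4p", "H4p"), c("C5p", "H5p"), c("C6p", "H6p")
  )
  nm <- vapply(nfa_zmatrix(), function(r) r$name, "")
  tibble(i = match(pairs[, 1], nm), j = match(pairs[, 2], nm))
}

nfa_atom_properties <- function() {
  nm <- vapply(nfa_zmatrix(), function(r) r$name, "")
  el <- sub("[0-9].*$", "", nm)
  el[el == "HN"] <- "H"
  ## small ECEPP-style hydrogen radii: aromatic C-H...N contacts in the
  ## planar conformer are mildly attractive, not clashes
  radius <- c(C = 1.90, N = 1.80, O = 1.70, F = 1.60, H = 1.00)[el]
  eps <- c(C = 0.10, N = 0.12, O = 0.15, F = 0.08, H = 0.02)[el]
  radius[nm == "HN"] <- 0.90
  q <- setNames(rep(0, length(nm)), nm)
  q[c("O1", "O2")] <- -0.65
  q["C7"] <- 0.45
  q["N1r"] <- -0.40
  q["C2"] <- 0.35
  q["N1"] <- -0.35
  q["HN"] <- 0.25
  q["C8"] <- 0.45
  q[c("F1", "F2", "F3")] <- -0.17
  q["C3"] <- -0.05
  q[c("C4", "C5", "C6")] <- -0.10
  q[c("H4", "H5", "H6")] <- 0.10
  q["C1p"] <- 0.10
  q[c("C2p", "C4p", "C5p", "C6p")] <- -0.10
  q[c("H2p", "H4p", "H5p", "H6p")] <- 0.10
  q["C3p"] <- -0.05
  ## close the formal charge exactly on the carboxylate oxygens
  corr <- (-1 - sum(q)) / 2
  q[c("O1", "O2")] <- q[c("O1", "O2")] + corr
  tibble(
    name = nm, element = el, charge = unname(q),
    radius = unname(radius), eps = unname(eps),
    hb_donor_h = nm == "HN",
    hb_acceptor = nm %in% c("O1", "O2", "N1r")
  )
}

## Rotatable torsions: dihedral-defining quadruple (indices a-b-c-d), the
## atom set rotated with d about the b-c bond, and the periodic potential
## V(phi) = k2/2*(1 + s2*cos(2*phi)) + k3/2*(1 + s3*cos(3*phi)).
nfa_torsions <- function() {
  nm <- vapply(nfa_zmatrix(), function(r) r$name, "")
  ix <- function(x) match(x, nm)
  bonds <- nfa_bonds()
  moving_set <- function(b, c_, d) {
    ## atoms connected to d when bond b-c_ is cut
    adj <- matrix(FALSE, length(nm), length(nm))
    for (r in seq_len(nrow(bonds))) {
      adj[bonds$i[r], bonds$j[r]] <- TRUE
      adj[bonds$j[r], bonds$i[r]] <- TRUE
    }
    adj[b, c_] <- adj[c_, b] <- FALSE
    seen <- rep(FALSE, length(nm))
    stack <- d
    while (length(stack) > 0) {
      a <- stack[[1]]
      stack <- stack[-1]
      if (seen[a]) next
      seen[a] <- TRUE
      stack <- c(stack, which(adj[a, ] & !seen))
    }
    seen[c_] <- FALSE
    which(seen)
  }
  list(
    ## benzoate-type 2-fold potential: barrier 3 kcal/mol, minima at +-90
    list(name = "tCOO", atoms = ix(c("C2", "C3", "C7", "O1")),
         moving = moving_set(ix("C3"), ix("C7"), ix("O1")),
         k2 = 3, s2 = +1, k3 = 0, s3 = 0),
    ## conjugated anilino C2-N1: planar minima (0/180)
    list(name = "tCN", atoms = ix(c("C3", "C2", "N1", "C1p")),
         moving = moving_set(ix("C2"), ix("N1"), ix("C1p")),
         k2 = 8, s2 = -1, k3 = 0, s3 = 0),
    ## N1-phenyl: conjugated, planar minima
    list(name = "tNPh", atoms = ix(c("C2", "N1", "C1p", "C2p")),
         moving = moving_set(ix("N1"), ix("C1p"), ix("C2p")),
         k2 = 8, s2 = -1, k3 = 0, s3 = 0),
    ## CF3 rotor: nearly free; shallow 3-fold with one fluorine in-plane
    list(name = "tCF3", atoms = ix(c("C2p", "C3p", "C8", "F1")),
         moving = moving_set(ix("C3p"), ix("C8"), ix("F1")),
         k2 = 0, s2 = 0, k3 = 0.3, s3 = -1)
  )
}

#' Evaluate the periodic potential of a rotatable torsion
#' @param tor One element of `ligand$torsions`.
#' @param phi_deg Dihedral angle(s), degrees.
#' @return Energy in kcal/mol.
#' @export
torsion_potential <- function(tor, phi_deg) {
  phi <- deg2rad(phi_deg)
  tor$k2 / 2 * (1 + tor$s2 * cos(2 * phi)) +
    tor$k3 / 2 * (1 + tor$s3 * cos(3 * phi))
}

#' Current torsion angles of a ligand conformer, degrees
#' @param ligand A `ligand_conformer`.
#' @return Named numeric vector of dihedral angles.
#' @export
ligand_torsion_angles <- function(ligand) {
  xyz <- ligand_xyz(ligand)
  vapply(ligand$torsions, function(tor) {
    a <- tor$atoms
    dihedral_angle(xyz[a[1], ], xyz[a[2], ], xyz[a[3], ], xyz[a[4], ])
  }, 0)
}

#' Coordinates of a ligand conformer as a matrix
#' @param ligand A `ligand_conformer`.
#' @return An n x 3 matrix of coordinates, Angstrom.
#' @export
ligand_xyz <- function(ligand) {
  as.matrix(ligand$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a ligand conformer
#' @param ligand A `ligand_conformer`.
#' @param xyz An n x 3 coordinate matrix, Angstrom.
#' @return The updated `ligand_conformer`.
#' @export
set_ligand_xyz <- function(ligand, xyz) {
  ligand$atoms$x <- xyz[, 1]
  ligand$atoms$y <- xyz[, 2]
  ligand$atoms$z <- xyz[, 3]
  ligand
}

## Rotate torsion subtrees of a coordinate matrix to the target dihedral
## angles `phi` (degrees). Each dihedral is re-measured immediately before
## its rotation: torsions sharing atoms (e.g. the two bridge bonds) would
## otherwise disturb one another. `phi0` is accepted for call-site symmetry
## but the angles are always measured from the coordinates.
apply_torsions_xyz <- function(xyz, torsions, phi0, phi) {
  for (t in seq_along(torsions)) {
    tor <- torsions[[t]]
    a <- tor$atoms
    cur <- dihedral_angle(xyz[a[1], ], xyz[a[2], ], xyz[a[3], ], xyz[a[4], ])
    dphi <- deg2rad(phi[t] - cur)
    if (abs(dphi) < 1e-12) next
    b <- xyz[a[2], ]
    c_ <- xyz[a[3], ]
    Rm <- rotvec_matrix(unitv(b - c_) * dphi)
    mv <- tor$moving
    xyz[mv, ] <- sweep(sweep(xyz[mv, , drop = FALSE], 2, c_) %*% t(Rm), 2,
                       -c_)
  }
  xyz
}

#' Apply torsion angles to a ligand conformer
#'
#' Rotates each rotatable-bond subtree to the requested dihedral values
#' (degrees), starting from the current coordinates.
#'
#' @param ligand A `ligand_conformer`.
#' @param phi Numeric vector of target dihedrals, one per torsion (recycled
#'   names ignored; order of `ligand$torsions`).
#' @return The updated `ligand_conformer`.
#' @export
set_ligand_torsions <- function(ligand, phi) {
  xyz <- ligand_xyz(ligand)
  cur <- ligand_torsion_angles(ligand)
  set_ligand_xyz(ligand, apply_torsions_xyz(xyz, ligand$torsions, cur, phi))
}

## Precompute the static nonbonded machinery of a ligand: intramolecular
## vdW pair list (pairs more than 3 bonds apart, H-bonding pairs excluded)
## and the intramolecular donor/acceptor triples.
ligand_nb_params <- function(at, bonds, bond_sep) {
  hb_excl <- outer(at$hb_donor_h, at$hb_acceptor) |
    outer(at$hb_acceptor, at$hb_donor_h)
  pair <- which(upper.tri(bond_sep) & bond_sep >= 4 & !hb_excl,
                arr.ind = TRUE)
  hb <- list()
  for (h in which(at$hb_donor_h)) {
    dheavy <- c(bonds$j[bonds$i == h], bonds$i[bonds$j == h])[1]
    for (a in which(at$hb_acceptor)) {
      if (bond_sep[h, a] < 4) next
      hb[[length(hb) + 1L]] <- list(t = c(dheavy, h, a), eps = 5, r0 = 1.9)
    }
  }
  ## weak aromatic C-H...N(pyridine) contacts: stabilise the planar
  ## conformation of the 2-anilinopyridine core, as in the crystal
  ch <- which(at$element == "H" & !at$hb_donor_h)
  npyr <- which(at$name == "N1r")
  drop_pair <- matrix(FALSE, nrow(at), nrow(at))
  for (h in ch) {
    if (bond_sep[h, npyr] < 4) next
    dheavy <- c(bonds$j[bonds$i == h], bonds$i[bonds$j == h])[1]
    hb[[length(hb) + 1L]] <- list(t = c(dheavy, h, npyr), eps = 1.5, r0 = 2.2)
    drop_pair[h, npyr] <- drop_pair[npyr, h] <- TRUE
  }
  keep <- !drop_pair[cbind(pair[, 1], pair[, 2])]
  pair <- pair[keep, , drop = FALSE]
  list(i = pair[, 1], j = pair[, 2],
       rmin = at$radius[pair[, 1]] + at$radius[pair[, 2]],
       epsij = sqrt(at$eps[pair[, 1]] * at$eps[pair[, 2]]),
       hb = hb)
}

## Energy of a bare coordinate matrix given the static parameters; the
## charge-assisted intramolecular N-H...O(-) bond gets a deeper well.
ligand_energy_xyz <- function(xyz, torsions, nb) {
  e_tor <- 0
  for (tor in torsions) {
    a <- tor$atoms
    phi <- dihedral_angle(xyz[a[1], ], xyz[a[2], ], xyz[a[3], ], xyz[a[4], ])
    e_tor <- e_tor + torsion_potential(tor, phi)
  }
  dx <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
  d <- sqrt(.rowSums(dx^2, length(nb$i), 3L))
  rr <- (nb$rmin / pmax(d, 0.5))^6
  e_vdw <- sum(nb$epsij * (rr^2 - 2 * rr))
  e_hb <- 0
  for (hbd in nb$hb) {
    t3 <- hbd$t
    e_hb <- e_hb + hbond_energy(xyz[t3[1], ], xyz[t3[2], ], xyz[t3[3], ],
                                eps_hb = hbd$eps, r0 = hbd$r0)
  }
  e_tor + e_vdw + e_hb
}

## Internal (intramolecular) energy: torsion potentials + van der Waals for
## pairs more than 3 bonds apart + the intramolecular H-bond term.
ligand_internal_energy <- function(ligand) {
  ligand_energy_xyz(ligand_xyz(ligand), ligand$torsions, ligand$nb)
}

## Classic distance-only 10-12 hydrogen-bond term on the H...acceptor
## distance (for explicit-H donors) or the donor...acceptor heavy-atom
## distance (for united side-chain donors); orientation is constrained
## implicitly by the surrounding van der Waals terms.
hbond_energy <- function(donor, h, acceptor, eps_hb = 2.5, r0 = 1.9) {
  d <- sqrt(sum((acceptor - h)^2))
  if (d > 5) return(0)
  rr <- (r0 / max(d, 0.8))
  eps_hb * (5 * rr^12 - 6 * rr^10)
}

#' Build the anionic niflumic acid conformer
#'
#' Constructs the 28-atom anion from standard bond lengths and angles and
#' minimises its internal energy over the four rotatable torsions (Ph-COO
#' twist with a 2-fold 3 kcal/mol potential and minima at +-90 degrees, the
#' two bridge torsions with planar minima, and the CF3 rotor), multi-started
#' over both carboxylate twist signs and both anilino orientations. The
#' intramolecular N-H...O hydrogen bond closes in the minimised conformer,
#' which is nearly planar (small inter-ring angle). The bridging nitrogen
#' between the two rings is flagged as `N1`; net charge is -1 e.
#'
#' @param minimize Minimise the internal energy (default) or return the raw
#'   template geometry.
#'
#' @return A `ligand_conformer`: list with `atoms` (tibble: name, element,
#'   x/y/z Angstrom, charge, radius, eps, H-bond flags), `bonds`, `torsions`,
#'   `n1` (index of the bridging nitrogen), `internal_energy` (kcal/mol).
#' @export
#' @examples
#' lig <- build_nfa()
#' max(dist(ligand_xyz(lig)))   # maximal interatomic distance, Angstrom
build_nfa <- function(minimize = TRUE) {
  key <- if (minimize) "nfa_min" else "nfa_raw"
  if (!is.null(.glyrblock_cache[[key]])) return(.glyrblock_cache[[key]])
  zm <- nfa_zmatrix()
  xyz <- zmat_to_xyz(zm)
  at <- nfa_atom_properties()
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  bonds <- nfa_bonds()
  bond_sep <- bond_separation(nrow(at), bonds)
  lig <- structure(
    list(atoms = at, bonds = bonds, torsions = nfa_torsions(),
         bond_sep = bond_sep,
         nb = ligand_nb_params(at, bonds, bond_sep),
         n1 = match("N1", at$name), internal_energy = NA_real_),
    class = "ligand_conformer"
  )
  if (!minimize) {
    lig$internal_energy <- ligand_internal_energy(lig)
    .glyrblock_cache[[key]] <- lig
    return(lig)
  }
  xyz0 <- ligand_xyz(lig)
  phi0 <- ligand_torsion_angles(lig)
  obj <- function(phi) {
    ligand_energy_xyz(apply_torsions_xyz(xyz0, lig$torsions, phi0, phi),
                      lig$torsions, lig$nb)
  }
  best <- NULL
  for (tcoo in c(45, -45, 90)) {
    for (tcn in c(180, 0)) {
      for (tnph in c(0, 180)) {
        op <- optim(c(tcoo, tcn, tnph, 60), obj, method = "BFGS",
                    control = list(reltol = 1e-7, maxit = 80))
        if (is.null(best) || op$value < best$value) best <- op
      }
    }
  }
  op <- optim(best$par, obj, method = "BFGS",
              control = list(reltol = 1e-13, maxit = 500))
  if (op$value > best$value) op <- best
  lig <- set_ligand_xyz(lig, apply_torsions_xyz(xyz0, lig$torsions, phi0,
                                                op$par))
  lig$internal_energy <- op$value
  .glyrblock_cache[[key]] <- lig
  lig
}

#' @export
print.ligand_conformer <- function(x, ...) {
  cat("<ligand_conformer> ", nrow(x$atoms), " atoms, net charge ",
      round(sum(x$atoms$charge), 3), " e, max span ",
      round(max(stats::dist(ligand_xyz(x))), 2), " A\n", sep = "")
  invisible(x)
}

#' Angle between the two aromatic ring planes, degrees
#' @param ligand A `ligand_conformer`.
#' @return Angle in `[0, 90]` degrees.
#' @export
ring_plane_angle <- function(ligand) {
  xyz <- ligand_xyz(ligand)
  nm <- ligand$atoms$name
  n1 <- plane_normal(xyz[nm %in% c("N1r", "C2", "C3", "C4", "C5", "C6"), ])
  n2 <- plane_normal(xyz[nm %in% c("C1p", "C2p", "C3p", "C4p", "C5p", "C6p"), ])
  a <- rad2deg(acos(min(1, abs(sum(n1 * n2)))))
  a
}

#' Intramolecular N-H...O hydrogen-bond length
#' @param ligand A `ligand_conformer`.
#' @return The shorter H...O distance to the two carboxylate oxygens, Angstrom.
#' @export
nh_o_distance <- function(ligand) {
  xyz <- ligand_xyz(ligand)
  nm <- ligand$atoms$name
  min(sqrt(sum((xyz[nm == "HN", ] - xyz[nm == "O1", ])^2)),
      sqrt(sum((xyz[nm == "HN", ] - xyz[nm == "O2", ])^2)))
}
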