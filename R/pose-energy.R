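## Fast compiled pose-energy evaluators for the MCM search. These produce
## the same totals as interaction_energy() (asserted in the test suite) but
## operate on precomputed plain-matrix parameters, avoiding any data-frame
## work inside the optimization hot loop.

compile_ligand_static <- function(ligand) {
  list(
    xyz0 = ligand_xyz(ligand),
    phi0 = ligand_torsion_angles(ligand),
    torsions = ligand$torsions,
    nb = ligand$nb,
    n1 = ligand$n1,
    radius = ligand$atoms$radius,
    eps = ligand$atoms$eps,
    charge = ligand$atoms$charge,
    don_h = which(ligand$atoms$hb_donor_h),
    acc = which(ligand$atoms$hb_acceptor),
    n_tor = length(ligand$torsions)
  )
}

compile_pore_static <- function(pore, z_window = NULL) {
  pa <- pore$atoms
  if (!is.null(z_window)) {
    pa <- pa[pa$z >= z_window[1] & pa$z <= z_window[2], ]
  }
  list(
    xyz = as.matrix(pa[, c("x", "y", "z")]),
    radius = pa$radius,
    eps = pa$eps,
    charge = pa$charge,
    don = which(pa$hbd),
    acc = which(pa$hba),
    sumsq = rowSums(as.matrix(pa[, c("x", "y", "z")])^2)
  )
}

pose_xyz <- function(ls, par) {
  xyz <- apply_torsions_xyz(ls$xyz0, ls$torsions, ls$phi0,
                            par[6 + seq_len(ls$n_tor)])
  Rm <- rotvec_matrix(par[4:6])
  pivot <- ls$xyz0[ls$n1, ]
  sweep(sweep(xyz, 2, pivot) %*% t(Rm), 2, -(pivot + par[1:3]))
}

## torsion energy directly from the target angles
fast_torsion_energy <- function(torsions, phi) {
  e <- 0
  for (t in seq_along(torsions)) e <- e + torsion_potential(torsions[[t]], phi[t])
  e
}

fast_internal_energy <- function(ls, xyz, phi) {
  nb <- ls$nb
  dx <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
  d2 <- .rowSums(dx * dx, length(nb$i), 3L)
  d2[d2 < 0.25] <- 0.25
  y <- (nb$rmin * nb$rmin) / d2
  rr <- y * y * y
  e <- fast_torsion_energy(ls$torsions, phi) +
    sum(nb$epsij * (rr * rr - 2 * rr))
  for (hbd in nb$hb) {
    t3 <- hbd$t
    e <- e + hbond_energy(xyz[t3[1], ], xyz[t3[2], ], xyz[t3[3], ],
                          eps_hb = hbd$eps, r0 = hbd$r0)
  }
  e
}

## static rmin/eps/charge product matrices for a (ligand, bead-set) pair
pair_static <- function(ls, ps) {
  rmin <- outer(ls$radius, ps$radius, `+`)
  list(rmin = rmin, rmin2 = rmin * rmin,
       epsij = sqrt(outer(ls$eps, ps$eps)),
       qq = COULOMB_K * outer(ls$charge, ps$charge),
       txyz = t(ps$xyz), sumsq = ps$sumsq,
       ones_l = rep(1, length(ls$radius)), ones_p = rep(1, nrow(ps$xyz)),
       don = ps$don, acc = ps$acc)
}

fast_pair_terms <- function(lxyz, ls, st) {
  d2 <- outer(.rowSums(lxyz^2, nrow(lxyz), 3L), st$ones_p) +
    outer(st$ones_l, st$sumsq) - 2 * lxyz %*% st$txyz
  d2[d2 < 0.01] <- 0.01
  d <- sqrt(d2)
  sw <- switch_factor(d)
  y <- st$rmin2 / d2
  rr <- y * y * y
  e_vdw <- sum(st$epsij * (rr * rr - 2 * rr) * sw)
  e_elec <- sum(st$qq / d2 * sw)
  e_hb <- 0
  for (h in ls$don_h) {
    dd <- d[h, st$acc]
    keep <- dd < 5
    if (any(keep)) {
      rrh <- 1.9 / pmax(dd[keep], 0.8)
      e_hb <- e_hb + sum(2.5 * (5 * rrh^12 - 6 * rrh^10))
    }
  }
  for (a in ls$acc) {
    dd <- d[a, st$don]
    keep <- dd < 5
    if (any(keep)) {
      rrh <- 2.9 / pmax(dd[keep], 0.8)
      e_hb <- e_hb + sum(2.5 * (5 * rrh^12 - 6 * rrh^10))
    }
  }
  e_vdw + e_elec + e_hb
}

fast_constraints <- function(n1pos, cons) {
  e <- 0
  for (con in cons) {
    e <- e + switch(con$kind,
      plane = con$k * (n1pos[3] - con$z)^2,
      radial = con$k * max(sqrt(n1pos[1]^2 + n1pos[2]^2) - con$rmax, 0)^2,
      floor = con$k * max(con$z - n1pos[3], 0)^2,
      ceiling = con$k * max(n1pos[3] - con$z, 0)^2,
      pin = 0   # backbone rigid in the fast path
    )
  }
  e
}

## Returns fn(par) giving the same total as interaction_energy() for a
## single posed ligand under the given constraints.
compile_pose_energy <- function(pore, ligand, constraints, z_window = NULL) {
  ls <- compile_ligand_static(ligand)
  ps <- compile_pore_static(pore, z_window)
  st <- pair_static(ls, ps)
  tor_idx <- 6 + seq_len(ls$n_tor)
  function(par) {
    xyz <- pose_xyz(ls, par)
    fast_pair_terms(xyz, ls, st) +
      fast_internal_energy(ls, xyz, par[tor_idx]) +
      fast_constraints(xyz[ls$n1, ], constraints)
  }
}

## Two-ligand version: par = c(pose1, pose2).
compile_pose_energy2 <- function(pore, ligand, constraints) {
  ls <- compile_ligand_static(ligand)
  ps <- compile_pore_static(pore)
  st <- pair_static(ls, ps)
  ll_rmin <- outer(ls$radius, ls$radius, `+`)
  ll_eps <- sqrt(outer(ls$eps, ls$eps))
  ## ligand-ligand electrostatics screened fourfold (eps = 4r)
  ll_qq <- 0.25 * COULOMB_K * outer(ls$charge, ls$charge)
  ones <- rep(1, length(ls$radius))
  np <- 6 + ls$n_tor
  function(par) {
    p1 <- par[seq_len(np)]
    p2 <- par[np + seq_len(np)]
    x1 <- pose_xyz(ls, p1)
    x2 <- pose_xyz(ls, p2)
    st2 <- list(rmin = ll_rmin, rmin2 = ll_rmin * ll_rmin, epsij = ll_eps,
                qq = ll_qq, txyz = t(x2),
                sumsq = .rowSums(x2^2, nrow(x2), 3L), ones_l = ones,
                ones_p = ones, don = ls$don_h, acc = ls$acc)
    fast_pair_terms(x1, ls, st) + fast_pair_terms(x2, ls, st) +
      fast_pair_terms(x1, ls, st2) +
      fast_internal_energy(ls, x1, p1[6 + seq_len(ls$n_tor)]) +
      fast_internal_energy(ls, x2, p2[6 + seq_len(ls$n_tor)]) +
      fast_constraints(x1[ls$n1, ], constraints) +
      fast_constraints(x2[ls$n1, ], constraints)
  }
}
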