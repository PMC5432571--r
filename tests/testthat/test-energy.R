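test_that("interaction energy vanishes for a distant ligand", {
  pore <- build_pore("alpha1")
  lig <- build_nfa()
  far <- set_ligand_xyz(lig, sweep(ligand_xyz(lig), 2, c(100, 0, 0), `+`))
  ie <- interaction_energy(pore, far)
  inter <- sum(ie$terms$energy[ie$terms$term %in% c("vdw", "elec", "hbond")])
  expect_lt(abs(inter), 0.01)
  expect_false(ie$clash)
})

test_that("a neutral pair at the van der Waals optimum sits at -eps", {
  la <- tibble::tibble(name = "X", element = "C", charge = 0, radius = 1.9,
                       eps = 0.1, hb_donor_h = FALSE, hb_acceptor = FALSE)
  pa <- tibble::tibble(chain = 1L, resno = 1L, resname = "ALA", prime = 0L,
                       bead = "SC", x = 0, y = 0, z = 0, charge = 0,
                       radius = 2.0, eps = 0.15, hbd = FALSE, hba = FALSE)
  lxyz <- matrix(c(3.9, 0, 0), 1, 3)   # rmin = 1.9 + 2.0
  pw <- glyrblock:::pair_energy(lxyz, la, as.matrix(pa[, c("x", "y", "z")]), pa)
  expect_equal(pw$vdw, -sqrt(0.1 * 0.15), tolerance = 1e-12)
  expect_equal(pw$elec, 0)
  ## overlap flags a clash
  pw2 <- glyrblock:::pair_energy(matrix(c(0.05, 0, 0), 1, 3), la,
                                 as.matrix(pa[, c("x", "y", "z")]), pa)
  expect_true(pw2$clash)
})

test_that("the decomposition matches a naive all-pairs double loop", {
  pore <- build_pore("alpha2")
  lig <- build_nfa()
  pa <- pore$atoms
  set.seed(42)
  for (k in 1:10) {
    pose <- set_ligand_xyz(lig, sweep(
      ligand_xyz(lig) %*% t(glyrblock:::rotvec_matrix(runif(3, -1, 1))),
      2, c(runif(2, -3, 3), runif(1, 2, 30)), `+`))
    lxyz <- ligand_xyz(pose)
    vdw <- 0; elec <- 0
    for (i in seq_len(nrow(lxyz))) {
      for (j in seq_len(nrow(pa))) {
        d <- sqrt(sum((lxyz[i, ] - c(pa$x[j], pa$y[j], pa$z[j]))^2))
        d <- max(d, 0.1)
        if (d >= 8) next
        sw <- if (d <= 7) 1 else {
          x <- (8 - d); x^2 * (3 - 2 * x)
        }
        rr <- ((pose$atoms$radius[i] + pa$radius[j]) / d)^6
        vdw <- vdw + sqrt(pose$atoms$eps[i] * pa$eps[j]) * (rr^2 - 2 * rr) * sw
        elec <- elec + 332.0636 * pose$atoms$charge[i] * pa$charge[j] / d^2 * sw
      }
    }
    ie <- interaction_energy(pore, pose)
    ee <- setNames(ie$terms$energy, ie$terms$term)
    expect_equal(ee[["vdw"]], vdw, tolerance = 1e-8)
    expect_equal(ee[["elec"]], elec, tolerance = 1e-8)
    expect_equal(sum(ie$terms$energy), ie$total, tolerance = 1e-10)
  }
})

test_that("the compiled pose energy equals the reference decomposition", {
  pore <- build_pore("alpha1")
  lig <- build_nfa()
  cons <- make_constraints(plane_z = 12, radial_max = 6)
  fast <- glyrblock:::compile_pose_energy(pore, lig, cons)
  tmpl <- ligand_xyz(lig)
  phi0 <- ligand_torsion_angles(lig)
  set.seed(3)
  for (k in 1:10) {
    par <- c(runif(3, -3, 3), runif(3, -1, 1), phi0 + runif(4, -40, 40))
    posed <- glyrblock:::pose_ligand(lig, par, tmpl, phi0)
    slow <- interaction_energy(pore, posed, cons)$total
    expect_equal(fast(par), slow, tolerance = 1e-6 * max(1, abs(slow)))
  }
  ## two-ligand evaluator
  fast2 <- glyrblock:::compile_pose_energy2(pore, lig, cons)
  p1 <- c(0, 0, 20, 0, 0, 0, phi0)
  p2 <- c(1, 1, 24, 0, 0, 1, phi0)
  l1 <- glyrblock:::pose_ligand(lig, p1, tmpl, phi0)
  l2 <- glyrblock:::pose_ligand(lig, p2, tmpl, phi0)
  slow2 <- interaction_energy(pore, list(l1, l2), cons)$total
  expect_equal(fast2(c(p1, p2)), slow2, tolerance = 1e-8 * max(1, abs(slow2)))
})

test_that("pin constraints penalise backbone displacement linearly", {
  pore <- build_pore("alpha1")
  cons <- make_constraints(pins = TRUE, radial_max = NULL)
  lig <- build_nfa()
  expect_equal(interaction_energy(pore, lig, cons)$terms$energy[5], 0)
  ## displace every C-alpha by 1.5 Angstrom: 0.5 beyond the 1 A flat bottom
  shifted <- pore
  ca <- shifted$atoms$bead == "CA"
  shifted$atoms$x[ca] <- shifted$atoms$x[ca] + 1.5
  e_pin <- interaction_energy(shifted, lig, cons)$terms$energy[5]
  expect_equal(e_pin, sum(ca) * 0.5 * 10, tolerance = 1e-9)
})
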