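test_that("a 30 Angstrom scan at half-Angstrom steps has 61 levels", {
  expect_identical(length(profile_levels(0, 30, 0.5)), 61L)
  expect_error(profile_levels(10, 5), "below")
})

test_that("the pulled profile keeps constraints satisfied and favours alpha2", {
  sc <- cached_pore_scan()
  for (pr in sc) {
    expect_true(all(pr$E_constraint < 0.5))
    expect_true(all(pr$E_constraint >= 0))
    expect_false(any(pr$clash))
  }
  ## alanine 2' ring more attractive to the hydrophobic anion than glycine
  expect_lt(mean(sc$alpha2$E_total - sc$alpha1$E_total), 0)
})

test_that("electrostatics near the arginine ring attract the anion", {
  pore <- build_pore("alpha1")
  lig <- glyrblock:::orient_ligand_axis(build_nfa())
  xyz <- ligand_xyz(lig)
  xyz <- sweep(xyz, 2, xyz[lig$n1, ])
  placed <- set_ligand_xyz(lig, sweep(xyz, 2, c(0, 0, level_z(pore, 0)), `+`))
  ie <- interaction_energy(pore, placed)
  expect_lt(ie$terms$energy[ie$terms$term == "elec"], 0)
})

test_that("restarts from symmetry-rotated placements reach similar energies", {
  pore <- build_pore("alpha2")
  lig <- build_nfa()
  z6 <- level_z(pore, 6)
  best <- vapply(c(0, 144, 288), function(ang) {
    rot <- glyrblock:::rotvec_matrix(c(0, 0, glyrblock:::deg2rad(ang)))
    pr <- pore
    xyzp <- as.matrix(pr$atoms[, c("x", "y", "z")]) %*% t(rot)
    pr$atoms$x <- xyzp[, 1]; pr$atoms$y <- xyzp[, 2]; pr$atoms$z <- xyzp[, 3]
    pr$template <- dplyr::filter(pr$atoms, .data$bead == "CA")[,
      c("chain", "resno", "x", "y", "z")]
    out <- pull_profile(pr, lig, z_from = z6, z_to = z6, step = 0.5,
                        stop_after = 30, maxit = 15, seed = 5)
    min(out$E_total)
  }, 0)
  expect_lt(diff(range(best)), 1.5)
})

test_that("two ligands dock above the 9' ring with favourable contacts", {
  pore <- build_pore("alpha1")
  lig <- build_nfa()
  dock <- dock_two_ligands(pore, lig, level = 13, stop_after = 40,
                           maxit = 15, seed = 2)
  z9 <- level_z(pore, 9)
  n1z <- vapply(dock$ligands, function(l) ligand_xyz(l)[l$n1, 3], 0)
  expect_true(all(n1z > z9))
  expect_lt(dock$interligand_vdw, 0)       # hydrophobic ligand-ligand contact
  ## hydroxyl rings above the constriction donate H-bonds to the complex
  hb <- dock$hbonds
  expect_gt(nrow(hb), 0)
  expect_true(any(hb$resname %in% c("THR", "SER", "GLN") & hb$prime > 9))
})

test_that("a single ligand at the 6' level of alpha2 contacts the threonine ring", {
  pore <- build_pore("alpha2")
  lig <- build_nfa()
  z6 <- level_z(pore, 6)
  pr <- pull_profile(pore, lig, z_from = z6, z_to = z6, step = 0.5,
                     stop_after = 30, maxit = 15, seed = 8)
  pose <- attr(pr, "poses")[[which.min(pr$E_total)]]
  hb <- hbond_contacts(pore, pose, max_dist = 3)
  expect_true(any(hb$resname == "THR" & hb$prime %in% c(5, 6, 7)))
})
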