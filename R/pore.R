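## Pore module: idealized pentameric TM2 bundle (or a user-supplied PDB) in a
## coarse representation - one backbone bead per residue at the C-alpha plus
## one typed side-chain interaction centre - sufficient to reproduce the
## qualitative energetics of an anionic ligand inside the pore: the charged
## arginine ring at the cytoplasmic entrance, the hydroxyl rings (Thr 6'/13')
## that donate H-bonds, the hydrophobic 9' leucine constriction, and the
## glycine/alanine difference at level 2'.

## TM2 sequence, human alpha1 GlyR numbering 250-272 (prime level = resno - 252)
tm2_sequence <- function(subtype = c("alpha1", "alpha2")) {
  subtype <- match.arg(subtype)
  seq1 <- c("PRO", "ALA", "ARG", "VAL", "GLY", "LEU", "GLY", "ILE", "THR",
            "THR", "VAL", "LEU", "THR", "MET", "THR", "THR", "GLN", "SER",
            "SER", "GLY", "SER", "ARG", "ALA")
  if (subtype == "alpha2") seq1[5] <- "ALA"   # G254A at level 2'
  tibble(resno = 250:272, resname = seq1, prime = 250:272 - 252L)
}

## Side-chain bead parameters: distance of the interaction centre from the
## C-alpha (along the outward helix radial direction), vdW radius and well
## depth, charge, H-bond capability.
sidechain_params <- function() {
  tibble(
    resname = c("GLY", "ALA", "VAL", "LEU", "ILE", "THR", "SER", "MET",
                "GLN", "ARG", "PRO"),
    sc_len = c(NA, 1.5, 1.9, 2.6, 2.6, 1.7, 1.4, 2.9, 3.0, 3.5, 1.9),
    sc_radius = c(NA, 2.0, 2.3, 2.4, 2.4, 2.1, 1.9, 2.4, 2.3, 2.4, 2.3),
    sc_eps = c(NA, 0.15, 0.18, 0.20, 0.20, 0.15, 0.15, 0.22, 0.18, 0.18, 0.18),
    sc_charge = c(NA, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0),
    sc_hbd = c(NA, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
               TRUE, FALSE),
    sc_hba = c(NA, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
               FALSE, FALSE)
  )
}

#' Build a pentameric TM2 pore model
#'
#' Constructs five TM2 helices arranged with 5-fold symmetry about the pore
#' axis (+z toward the extracellular side). The default source is an
#' idealized alpha-helix (1.5 Angstrom rise and 100 degrees per residue)
#' with the helix bundle radius set so the 9' leucine ring leaves a free
#' radius of about 3.3 Angstrom; a PDB file with five chains containing the
#' TM2 segment can be supplied instead (requires the `bio3d` package). The
#' alpha2 model differs from alpha1 only by the G254A substitution at level
#' 2' in all five chains. Each residue contributes a backbone bead at the
#' C-alpha and (except glycine) a typed side-chain bead; glycine backbone
#' beads are marked as H-bond acceptors (pore-exposed backbone carbonyls).
#'
#' @param subtype `"alpha1"` or `"alpha2"`.
#' @param source `"idealized"` (default) or the path to a PDB file.
#' @param bundle_radius Distance of each helix axis from the pore axis,
#'   Angstrom.
#' @param helix_radius C-alpha helix radius, Angstrom.
#' @param rise,twist Helical rise (Angstrom) and twist (degrees) per residue.
#' @param flare Outward radial flare of the bundle above the 9' constriction
#'   (Angstrom of radius per Angstrom of height): the open pore is
#'   funnel-shaped, narrow at 9' and wide at the extracellular mouth.
#'
#' @return A `pore_model`: list with `atoms` (tibble: chain, resno, resname,
#'   prime, atom bead name, x/y/z, charge, radius, eps, hbd, hba), `levels`
#'   (prime-level map: prime, resno, resname, z), `axis` (origin + unit
#'   vector), `subtype`, `template` (C-alpha template coordinates for pin
#'   constraints).
#' @export
#' @examples
#' pore <- build_pore("alpha1")
#' pore$levels[pore$levels$prime %in% c(-2, 9, 13), ]
build_pore <- function(subtype = c("alpha1", "alpha2"), source = "idealized",
                       bundle_radius = 7.9, helix_radius = 2.3,
                       rise = 1.5, twist = 100, flare = 0.25) {
  subtype <- match.arg(subtype)
  seqtab <- tm2_sequence(subtype)
  if (!identical(source, "idealized")) {
    return(build_pore_from_pdb(source, subtype, seqtab))
  }
  scp <- sidechain_params()
  n_res <- nrow(seqtab)
  ## phase chosen so the canonical pore-facing stripe (-2',2',6',9',13',
  ## 17',20') straddles the inward radial direction
  theta0 <- -49 - twist * (261 - 250)   # centre the stripe at the 9' ring
  rows <- list()
  ca_tpl <- list()
  for (chain in 1:5) {
    phi <- deg2rad(72 * (chain - 1))
    u <- c(cos(phi), sin(phi), 0)        # pore axis -> helix axis
    v <- c(-sin(phi), cos(phi), 0)
    for (r in seq_len(n_res)) {
      i <- seqtab$resno[r] - 250
      th <- deg2rad(theta0 + twist * i)
      ## theta = 0 points from the helix axis toward the pore axis
      radial <- cos(th) * (-u) + sin(th) * v
      ## the open pore is funnel-shaped: the bundle flares outward above the
      ## 9' constriction toward the wide extracellular mouth
      zi <- rise * i
      r_bundle <- bundle_radius + flare * max(0, zi - rise * (261 - 250))
      centre <- r_bundle * u
      ca <- centre + helix_radius * radial + c(0, 0, zi)
      rn <- seqtab$resname[r]
      sc <- scp[scp$resname == rn, ]
      ## arginine side chains are long and flexible: their charged heads
      ## reach the pore lumen regardless of the C-alpha stripe phase
      sc_dir <- if (rn == "ARG") -unitv(c(ca[1], ca[2], 0)) else radial
      ## glycine exposes hydrated polar backbone: the structured water layer
      ## makes the ring bulky (C-alpha bead + ~1.2 A shell) yet a poor
      ## dispersion partner for a hydrophobic ligand (shallow well, no
      ## H-bond bonus)
      rows[[length(rows) + 1L]] <- tibble(
        chain = chain, resno = seqtab$resno[r], resname = rn,
        prime = seqtab$prime[r], bead = "CA",
        x = ca[1], y = ca[2], z = ca[3],
        charge = 0,
        radius = if (rn == "GLY") 3.4 else 2.2,
        eps = if (rn == "GLY") 0.04 else 0.10,
        hbd = FALSE, hba = FALSE
      )
      ca_tpl[[length(ca_tpl) + 1L]] <- c(ca, chain, seqtab$resno[r])
      if (!is.na(sc$sc_len)) {
        scpos <- ca + sc$sc_len * sc_dir
        rows[[length(rows) + 1L]] <- tibble(
          chain = chain, resno = seqtab$resno[r], resname = rn,
          prime = seqtab$prime[r], bead = "SC",
          x = scpos[1], y = scpos[2], z = scpos[3],
          charge = sc$sc_charge, radius = sc$sc_radius, eps = sc$sc_eps,
          hbd = sc$sc_hbd, hba = sc$sc_hba
        )
      }
    }
  }
  atoms <- list_rbind(rows)
  levels <- mutate(seqtab, z = rise * (.data$resno - 250))
  tpl <- do.call(rbind, ca_tpl)
  structure(
    list(atoms = atoms,
         levels = levels,
         axis = list(origin = c(0, 0, 0), direction = c(0, 0, 1)),
         subtype = subtype,
         template = tibble(chain = tpl[, 4], resno = tpl[, 5],
                           x = tpl[, 1], y = tpl[, 2], z = tpl[, 3])),
    class = "pore_model"
  )
}

## PDB-backed pore model: extracts the five TM2 segments, computes the pore
## axis from the per-level C-alpha centroids and re-expresses the model in
## the canonical frame (axis = +z, level -2' at z given by the idealized map).
build_pore_from_pdb <- function(path, subtype, seqtab) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB pore models requires the `bio3d` package.")
  }
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(bio3d::read.pdb(path), error = function(e) {
    abort(paste0("malformed PDB file: ", conditionMessage(e)))
  })
  ca <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$resno %in% seqtab$resno, ]
  chains <- unique(ca$chain)
  if (length(chains) != 5) {
    abort(paste0("expected 5 chains with the TM2 segment, found ",
                 length(chains), "."))
  }
  ## centroid line through per-residue rings defines the pore axis
  scp <- sidechain_params()
  rows <- list()
  for (ci in seq_along(chains)) {
    cc <- ca[ca$chain == chains[ci], ]
    cc <- cc[order(cc$resno), ]
    if (!all(seqtab$resno %in% cc$resno)) {
      abort("PDB chains do not cover the full TM2 segment (residues 250-272).")
    }
    for (r in seq_len(nrow(cc))) {
      rn0 <- seqtab$resname[match(cc$resno[r], seqtab$resno)]
      rows[[length(rows) + 1L]] <- tibble(
        chain = ci, resno = cc$resno[r], resname = rn0,
        prime = cc$resno[r] - 252L, bead = "CA",
        x = cc$x[r], y = cc$y[r], z = cc$z[r],
        charge = 0,
        radius = if (rn0 == "GLY") 3.4 else 2.2,
        eps = if (rn0 == "GLY") 0.04 else 0.10,
        hbd = FALSE, hba = FALSE
      )
    }
  }
  atoms <- list_rbind(rows)
  ## axis: fit line through per-residue ring centroids
  cents <- atoms |>
    group_by(.data$resno) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop")
  cm <- colMeans(as.matrix(cents[, c("x", "y", "z")]))
  sv <- svd(sweep(as.matrix(cents[, c("x", "y", "z")]), 2, cm))
  axis_dir <- sv$v[, 1]
  ## orient +z from -2' to 20'
  zlow <- as.numeric(cents[cents$resno == 250, c("x", "y", "z")])
  zhigh <- as.numeric(cents[cents$resno == 272, c("x", "y", "z")])
  if (sum((zhigh - zlow) * axis_dir) < 0) axis_dir <- -axis_dir
  ## canonical frame: origin at the -2' centroid projected on the axis
  proj <- function(p) {
    rel <- p - cm
    t_ <- sum(rel * axis_dir)
    cbind(t_)
  }
  b1 <- unitv(crossv(axis_dir, if (abs(axis_dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  b2 <- crossv(axis_dir, b1)
  z0 <- sum((zlow - cm) * axis_dir)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rel <- sweep(xyz, 2, cm)
  newxyz <- cbind(rel %*% b1, rel %*% b2, rel %*% axis_dir - z0)
  atoms$x <- newxyz[, 1]; atoms$y <- newxyz[, 2]; atoms$z <- newxyz[, 3]
  ## side-chain beads along the local inward direction
  sc_rows <- list()
  for (k in seq_len(nrow(atoms))) {
    sc <- scp[scp$resname == atoms$resname[k], ]
    if (nrow(sc) == 0 || is.na(sc$sc_len)) next
    caxyz <- c(atoms$x[k], atoms$y[k], atoms$z[k])
    inward <- -unitv(c(caxyz[1], caxyz[2], 0))
    pos <- caxyz + sc$sc_len * inward
    sc_rows[[length(sc_rows) + 1L]] <- mutate(
      atoms[k, ], bead = "SC", x = pos[1], y = pos[2], z = pos[3],
      charge = sc$sc_charge, radius = sc$sc_radius, eps = sc$sc_eps,
      hbd = sc$sc_hbd, hba = sc$sc_hba
    )
  }
  atoms <- bind_rows(atoms, list_rbind(sc_rows))
  levels <- atoms |>
    filter(.data$bead == "CA") |>
    group_by(.data$prime, .data$resno, .data$resname) |>
    summarise(z = mean(.data$z), .groups = "drop") |>
    arrange(.data$prime)
  structure(
    list(atoms = atoms, levels = levels,
         axis = list(origin = c(0, 0, 0), direction = c(0, 0, 1)),
         subtype = subtype,
         template = filter(atoms, .data$bead == "CA")[,
           c("chain", "resno", "x", "y", "z")]),
    class = "pore_model"
  )
}

#' @export
print.pore_model <- function(x, ...) {
  cat("<pore_model> ", x$subtype, ", 5 x ", length(unique(x$atoms$resno)),
      " residues, z range ", round(min(x$levels$z), 1), " to ",
      round(max(x$levels$z), 1), " A\n", sep = "")
  invisible(x)
}

#' z-coordinate of a prime level of a pore model
#' @param pore A `pore_model`.
#' @param prime Prime level(s), e.g. `9` for the 9' ring.
#' @return z in Angstrom.
#' @export
level_z <- function(pore, prime) {
  z <- pore$levels$z[match(prime, pore$levels$prime)]
  if (any(is.na(z))) abort("prime level outside the model range (-2' to 20').")
  z
}

#' Minimum free radius at a prime level
#'
#' Distance from the pore axis to the nearest bead surface within +-1.5
#' Angstrom of the level's z.
#'
#' @param pore A `pore_model`.
#' @param prime Prime level.
#' @return Free radius, Angstrom.
#' @export
pore_free_radius <- function(pore, prime) {
  zl <- level_z(pore, prime)
  a <- filter(pore$atoms, abs(.data$z - zl) < 1.5)
  min(sqrt(a$x^2 + a$y^2) - a$radius)
}

#' Write a pore model (and optionally ligand poses) as PDB
#' @param pore A `pore_model`.
#' @param path Output path.
#' @param ligands Optional list of `ligand_conformer` objects appended as
#'   HETATM records.
#' @return `path`, invisibly.
#' @export
write_pore_pdb <- function(pore, path, ligands = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  k <- 0
  for (i in seq_len(nrow(pore$atoms))) {
    a <- pore$atoms[i, ]
    k <- k + 1
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      k, if (a$bead == "CA") "CA" else "CB", a$resname,
      LETTERS[a$chain], a$resno, a$x, a$y, a$z), con)
  }
  for (lig in ligands %||% list()) {
    for (i in seq_len(nrow(lig$atoms))) {
      a <- lig$atoms[i, ]
      k <- k + 1
      writeLines(sprintf(
        "HETATM%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        k, substr(a$name, 1, 4), "NFA", "X", 1, a$x, a$y, a$z, a$element), con)
    }
  }
  invisible(path)
}
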