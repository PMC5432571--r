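## Small 3D geometry toolkit shared by the ligand and pore modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)
crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from a rotation vector (axis * angle, radians)
#' @param rv Length-3 rotation vector; its norm is the angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rotvec_matrix <- function(rv) {
  th <- vnorm(rv)
  if (th < 1e-12) return(diag(3))
  k <- rv / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Place atom D given positions of A, B, C and internal coordinates
## (bond length |CD|, angle B-C-D in degrees, dihedral A-B-C-D in degrees).
place_atom <- function(a, b, c_, bond, angle, dihedral) {
  ang <- deg2rad(angle)
  dih <- deg2rad(dihedral)
  bc <- unitv(c_ - b)
  ab <- unitv(b - a)
  n <- unitv(crossv(ab, bc))
  m <- crossv(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(dih),
               bond * sin(ang) * sin(dih))
  c_ + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

## Build Cartesian coordinates from a Z-matrix given as a list of rows
## (name, ref atoms i/j/k by index, bond, angle, dihedral).
zmat_to_xyz <- function(zm) {
  n <- length(zm)
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  if (n >= 2) xyz[2, ] <- c(zm[[2]]$bond, 0, 0)
  if (n >= 3) {
    r3 <- zm[[3]]
    base <- xyz[r3$i, ]
    u <- unitv(xyz[r3$j, ] - base)      # angle is measured j-i-new
    ang <- deg2rad(r3$angle)
    xyz[3, ] <- base + r3$bond * (cos(ang) * u + sin(ang) * c(0, 1, 0))
  }
  if (n >= 4) {
    for (m in 4:n) {
      r <- zm[[m]]
      xyz[m, ] <- place_atom(xyz[r$k, ], xyz[r$j, ], xyz[r$i, ],
                             r$bond, r$angle, r$dihedral)
    }
  }
  rownames(xyz) <- vapply(zm, function(r) r$name, "")
  xyz
}

#' Dihedral angle of four points, degrees in (-180, 180]
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Dihedral angle in degrees.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- crossv(b1, b2)
  n2 <- crossv(b2, b3)
  m1 <- crossv(n1, unitv(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

## Angle at vertex b (degrees)
angle_at <- function(a, b, c_) {
  u <- unitv(a - b)
  v <- unitv(c_ - b)
  rad2deg(acos(pmin(pmax(sum(u * v), -1), 1)))
}

## Best-fit plane normal of a point set (smallest principal axis)
plane_normal <- function(xyz) {
  cc <- sweep(xyz, 2, colMeans(xyz))
  unitv(svd(cc)$v[, 3])
}

## Bond-graph distance matrix (number of bonds between atoms)
bond_separation <- function(n, bonds) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (r in seq_len(nrow(bonds))) {
    D[bonds$i[r], bonds$j[r]] <- 1
    D[bonds$j[r], bonds$i[r]] <- 1
  }
  for (k in seq_len(n)) {       # Floyd-Warshall; n is small
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}
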