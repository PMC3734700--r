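# Internal helpers shared across modules.

# Covalent radii (Angstrom) for bond perception; values from the standard
# Cordero set, rounded. Enough elements for protein/ligand work.
.COV_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
  FE = 1.32, ZN = 1.22, MG = 1.41, "NA" = 1.66, K = 2.03, CA = 1.76,
  MN = 1.39, CU = 1.32, NI = 1.24, CO = 1.26, B = 0.84
)

.ELEMENTS <- names(.COV_RADII)

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# Position of atom D given reference atoms A-B-C, bond length |C-D|,
# angle B-C-D (degrees) and dihedral A-B-C-D (degrees). Standard NeRF
# internal-to-Cartesian construction.
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          -bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Torsion angle A-B-C-D in degrees, in (-180, 180].
torsion_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- unit(u); v <- unit(v)
  w <- pracma_cross(u, v)
  s <- vnorm(w)
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(pracma_cross(u, p))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

fmt_num <- function(x, digits = 4) formatC(x, format = "f", digits = digits)
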