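# Shared small helpers and element tables.

# Bondi van der Waals radii (Angstrom). Fixed internal table so surface areas
# are reproducible across machines; override via the `vdw` argument of
# read_pdb_structure().
.BONDI_VDW <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, BR = 1.85, I = 1.98, "NA" = 2.27, K = 2.75, MG = 1.73,
  ZN = 1.39, FE = 2.00, SE = 1.90, B = 1.92
)
.DEFAULT_VDW <- 1.70

# Atomic masses (amu) for mass-weighted centroids.
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998, P = 30.974,
  S = 32.06, CL = 35.45, BR = 79.904, I = 126.904, "NA" = 22.990, K = 39.098,
  MG = 24.305, ZN = 65.38, FE = 55.845, SE = 78.971, B = 10.81
)

.WATER_RESNAMES <- c("HOH", "WAT", "SPC", "T3P", "TIP3", "TIP4")

vdw_radius_for <- function(element) {
  el <- toupper(element)
  r <- .BONDI_VDW[el]
  r[is.na(r)] <- .DEFAULT_VDW
  unname(r)
}

mass_for <- function(element) {
  el <- toupper(element)
  m <- .ATOMIC_MASS[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

# Euclidean norms of rows of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Angle (degrees) at vertex b for points a-b-c; rows or single points.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

# Deterministic near-uniform points on the unit sphere (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# min distance from each row of `pts` to any row of `ref`
min_dist_to_set <- function(pts, ref) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  out <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(ref))) {
    d <- sqrt((pts[, 1] - ref[j, 1])^2 + (pts[, 2] - ref[j, 2])^2 +
                (pts[, 3] - ref[j, 3])^2)
    out <- pmin(out, d)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
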