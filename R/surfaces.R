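# Ligand surface decomposition: solvent-accessible (SASA), molecular /
# solvent-excluded (MolSA), their polar shares (SAPSA, PSA), and the derived
# buried areas (buried = MolSA - SASA, buried polar = PSA - SAPSA).
#
# SASA is Shrake-Rupley on a deterministic golden-spiral point set, so totals
# are reproducible bit-for-bit. MolSA is a numerical solvent-excluded surface:
# probe-scaled contact patches plus pairwise toroidal reentrant strips
# integrated along the accessible part of each probe-center circle. Concave
# triple-probe vertex patches are omitted (small for drug-sized molecules;
# see the methods vignette). Waters never occlude: the solvent defines the
# probe, not the environment.

#' Shrake-Rupley solvent-accessible surface area
#'
#' Accessible area at radius vdw + probe for each atom of `subset`, computed
#' in the context of all `environment` atoms. Deterministic for a fixed
#' `n_points`.
#'
#' @param frame a `restime_structure`.
#' @param subset atom indices whose area is wanted.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere test points per atom (>= 100, default 960).
#' @param environment atom indices that occlude (default: all non-water atoms).
#' @return list with `per_atom` (named by index) and `total` in Angstrom^2.
#' @export
compute_sasa <- function(frame, subset, probe = 1.4, n_points = 960,
                         environment = NULL) {
  if (!length(subset)) stop("empty atom subset")
  if (n_points < 100) stop("n_points must be >= 100")
  a <- frame$atoms
  if (is.null(environment))
    environment <- which(!(a$water_o | a$water_h))
  xyz <- coords(frame)
  r <- a$vdw
  res <- sasa_points(xyz, r, subset, environment, probe, n_points)
  list(per_atom = setNames(res, subset), total = sum(res))
}

sasa_points <- function(xyz, r, subset, environment, probe, n_points) {
  sp <- sphere_points(n_points)
  vapply(subset, function(i) {
    R <- r[i] + probe
    pts <- sweep(sp * R, 2, xyz[i, ], `+`)
    occl <- setdiff(environment, i)
    acc <- rep(TRUE, n_points)
    if (length(occl)) {
      # only neighbours that can possibly occlude
      dj <- sqrt(colSums((t(xyz[occl, , drop = FALSE]) - xyz[i, ])^2))
      occl <- occl[dj < R + r[occl] + probe]
      for (j in occl) {
        d <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & d >= (r[j] + probe)^2
        if (!any(acc)) break
      }
    }
    4 * pi * R^2 * mean(acc)
  }, numeric(1))
}

# Solvent-excluded (molecular) surface area of an atom set, decomposed into
# per-atom contributions. Contact patches are attributed to their atom;
# toroidal strips are split evenly between the two atoms of the pair.
molsa_area <- function(xyz, r, probe = 1.4, n_points = 960, n_arc = 360) {
  n <- nrow(xyz)
  sp <- sphere_points(n_points)
  per_atom <- numeric(n)
  R <- r + probe
  # contact patches: accessible fraction of the expanded sphere, scaled back
  # to the vdW sphere
  for (i in seq_len(n)) {
    pts <- sweep(sp * R[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in setdiff(seq_len(n), i)) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= R[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  # toroidal reentrant strips along accessible probe-center circles
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      dv <- xyz[j, ] - xyz[i, ]
      d <- sqrt(sum(dv * dv))
      if (d >= R[i] + R[j] || d <= abs(R[i] - R[j]) || d < 1e-9) next
      aa <- (d^2 + R[i]^2 - R[j]^2) / (2 * d)
      cc2 <- R[i]^2 - aa^2
      if (cc2 <= 0) next
      cc <- sqrt(cc2)
      # accessible fraction of the probe-center circle
      axis <- dv / d
      u <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- u - sum(u * axis) * axis; e1 <- e1 / sqrt(sum(e1 * e1))
      e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
              axis[3] * e1[1] - axis[1] * e1[3],
              axis[1] * e1[2] - axis[2] * e1[1])
      th <- seq(0, 2 * pi, length.out = n_arc + 1)[-(n_arc + 1)]
      circ <- sweep(outer(cos(th), e1) * cc + outer(sin(th), e2) * cc, 2,
                    xyz[i, ] + aa * axis, `+`)
      acc <- rep(TRUE, n_arc)
      for (k in setdiff(seq_len(n), c(i, j))) {
        d2 <- (circ[, 1] - xyz[k, 1])^2 + (circ[, 2] - xyz[k, 2])^2 +
          (circ[, 3] - xyz[k, 3])^2
        acc <- acc & d2 >= R[k]^2
      }
      f <- mean(acc)
      if (f <= 0) next
      strip <- toroidal_strip_area(aa, cc, d, R[i], R[j], probe)
      per_atom[i] <- per_atom[i] + f * strip / 2
      per_atom[j] <- per_atom[j] + f * strip / 2
    }
  }
  per_atom
}

# Area of the full (f = 1) toroidal reentrant patch for one atom pair, by
# meridian-plane integration of the probe arc as a surface of revolution.
# aa: axial coordinate of the probe-center circle (from atom i), cc: circle
# radius, d: interatomic distance. Spindle cusps (arc dipping below the axis)
# are clamped at rho = 0.
toroidal_strip_area <- function(aa, cc, d, Ri, Rj, probe, n_step = 400) {
  a_i <- atan2(-cc / Ri, -aa / Ri)
  a_j <- atan2(-cc / Rj, (d - aa) / Rj)
  if (a_j < a_i) a_j <- a_j + 2 * pi
  th <- seq(a_i, a_j, length.out = n_step)
  rho <- pmax(cc + probe * sin(th), 0)
  2 * pi * probe * sum((rho[-1] + rho[-n_step]) / 2) * (th[2] - th[1])
}

#' Per-frame ligand surface decomposition
#'
#' SASA and its polar share (SAPSA) are computed for the ligand in the
#' context of protein + ligand (no waters); MolSA and its polar share (PSA)
#' for the isolated ligand conformer at the same probe. Buried area is
#' MolSA - SASA and buried polar area is PSA - SAPSA, reported as computed
#' (they can be negative for an essentially isolated molecule).
#'
#' Polar area is the share contributed by N and O atoms and, by default,
#' hydrogens bonded to them.
#'
#' @param frame a `restime_structure`.
#' @param ligand_idx ligand atom indices (default: annotated ligand atoms).
#' @param probe probe radius (Angstrom).
#' @param n_points sphere points per atom.
#' @param include_polar_h count hydrogens on N/O as polar (default TRUE).
#' @return one-row data.frame(sasa, molsa, psa, sapsa, buried, buried_polar).
#' @export
compute_surface_decomposition <- function(frame,
                                          ligand_idx = atom_select(frame, ligand = TRUE),
                                          probe = 1.4, n_points = 960,
                                          include_polar_h = TRUE) {
  if (!length(ligand_idx)) stop("no ligand atoms")
  a <- frame$atoms
  polar <- a$element[ligand_idx] %in% c("N", "O")
  if (include_polar_h) {
    ho <- a$hydrogen_of[ligand_idx]
    polar <- polar | (a$element[ligand_idx] == "H" & !is.na(ho) &
                        a$element[pmax(ho, 1)] %in% c("N", "O"))
  }
  if (!any(a$element[ligand_idx] %in% c("N", "O", "H")) && any(polar))
    stop("polarity annotation missing")
  sas <- compute_sasa(frame, ligand_idx, probe, n_points)
  sasa <- sas$total
  sapsa <- sum(sas$per_atom[polar])
  lig_xyz <- coords(frame)[ligand_idx, , drop = FALSE]
  mol_atoms <- molsa_area(lig_xyz, a$vdw[ligand_idx], probe, n_points)
  molsa <- sum(mol_atoms)
  psa <- sum(mol_atoms[polar])
  data.frame(sasa = sasa, molsa = molsa, psa = psa, sapsa = sapsa,
             buried = molsa - sasa, buried_polar = psa - sapsa)
}

#' Surface decomposition along a trajectory
#'
#' @param traj a `restime_trajectory`.
#' @param ligand_idx ligand atom indices.
#' @param probe,n_points,include_polar_h see [compute_surface_decomposition()].
#' @return data.frame with one row per frame plus a `frame` column.
#' @export
surface_trajectory <- function(traj,
                               ligand_idx = atom_select(traj$structure, ligand = TRUE),
                               probe = 1.4, n_points = 960,
                               include_polar_h = TRUE) {
  rows <- lapply(seq_len(n_frames(traj)), function(f)
    cbind(frame = f,
          compute_surface_decomposition(frame_structure(traj, f), ligand_idx,
                                        probe, n_points, include_polar_h)))
  do.call(rbind, rows)
}
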