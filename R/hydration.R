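# Hydration sites and resolvation scoring.
#
# Sites are clustered from per-frame water-oxygen positions inside a shell
# around the ligand; each site carries a free energy relative to bulk water
# (supplied from an external table, or estimated from excess occupancy). A
# ligand displaces a site when the overlap factor exceeds 0.5 strictly, and
# the resolvation score sums the displaced energies with a sign convention
# that makes displacing unstable (positive delta-G) water favourable
# (negative score). State scores are combined with equilibrium-probability
# weights.

#' Cluster water observations into hydration sites
#'
#' Greedy density clustering: repeatedly take the observation with the most
#' neighbours within `radius`, found a site at their centroid, remove the
#' members, until no observation has at least `min_occupancy` neighbours
#' (itself included). Only observations within `shell` of any row of
#' `shell_center` enter the analysis (default shell 10 Angstrom).
#'
#' @param water_positions list of per-frame n x 3 matrices of water-oxygen
#'   positions, or a single pooled matrix.
#' @param radius clustering radius in Angstrom (default 1.0).
#' @param shell_center ligand heavy-atom coordinates (matrix) or NULL for no
#'   shell filter.
#' @param shell inclusion shell radius (default 10.0).
#' @param min_occupancy minimum members to found a site; default twice the
#'   bulk-water expectation for the clustering sphere (floor 5).
#' @param bulk_density bulk water number density (molecules per cubic
#'   Angstrom, default 0.0334).
#' @return data.frame(x, y, z, occupancy, n_frames) of class
#'   `restime_sites`; member observations kept in attribute `members`.
#' @export
cluster_hydration_sites <- function(water_positions, radius = 1.0,
                                    shell_center = NULL, shell = 10.0,
                                    min_occupancy = NULL,
                                    bulk_density = 0.0334) {
  if (is.list(water_positions)) {
    nf <- length(water_positions)
    pts <- do.call(rbind, water_positions)
  } else {
    nf <- 1L
    pts <- as.matrix(water_positions)
  }
  if (is.null(min_occupancy))
    min_occupancy <- max(5, ceiling(2 * bulk_density * (4 / 3) * pi *
                                      radius^3 * nf))
  if (!is.null(shell_center) && nrow(pts) > 0) {
    keep <- min_dist_to_set(pts, as.matrix(shell_center)) <= shell
    pts <- pts[keep, , drop = FALSE]
  }
  sites <- list(); members <- list()
  if (nrow(pts) > 0) {
    alive <- rep(TRUE, nrow(pts))
    repeat {
      idx <- which(alive)
      if (!length(idx)) break
      P <- pts[idx, , drop = FALSE]
      # neighbour counts within radius (self included)
      counts <- integer(length(idx))
      for (j in seq_along(idx)) {
        d2 <- (P[, 1] - P[j, 1])^2 + (P[, 2] - P[j, 2])^2 + (P[, 3] - P[j, 3])^2
        counts[j] <- sum(d2 <= radius^2)
      }
      best <- which.max(counts)
      if (counts[best] < min_occupancy) break
      d2 <- (P[, 1] - P[best, 1])^2 + (P[, 2] - P[best, 2])^2 +
        (P[, 3] - P[best, 3])^2
      mem <- idx[d2 <= radius^2]
      ctr <- colMeans(pts[mem, , drop = FALSE])
      sites[[length(sites) + 1]] <- c(ctr, length(mem))
      members[[length(members) + 1]] <- pts[mem, , drop = FALSE]
      alive[mem] <- FALSE
    }
  }
  if (!length(sites)) {
    out <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      occupancy = integer(), n_frames = integer())
  } else {
    m <- do.call(rbind, sites)
    out <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
                      occupancy = as.integer(m[, 4]), n_frames = nf)
  }
  attr(out, "members") <- members
  attr(out, "radius") <- radius
  class(out) <- c("restime_sites", "data.frame")
  out
}

#' Inverse-Boltzmann hydration-site energy estimate
#'
#' Crude excess-occupancy estimate delta-G = -kT log(rho_site / rho_bulk)
#' with kT = 0.616 kcal/mol (310 K). Explicitly an approximation: real
#' hydration-site free energies come from inhomogeneous solvation theory and
#' should be supplied as an external table when available.
#'
#' @param occupancy site observation count.
#' @param n_frames total frames.
#' @param radius site radius defining the sampling volume (default 1.0).
#' @param bulk_density bulk water density (default 0.0334 / A^3).
#' @param kT thermal energy in kcal/mol (default 0.616).
#' @return delta-G in kcal/mol (negative = more stable than bulk).
#' @export
estimate_site_energy <- function(occupancy, n_frames, radius = 1.0,
                                 bulk_density = 0.0334, kT = 0.616) {
  if (any(occupancy <= 0)) stop("site energy undefined for zero occupancy")
  vol <- (4 / 3) * pi * radius^3
  rho <- occupancy / (n_frames * vol)
  -kT * log(rho / bulk_density)
}

#' Overlap factor of a hydration site with a ligand
#'
#' Fraction of the site's member water-oxygen observations lying within
#' (vdW radius + `offset`) of any ligand heavy atom - positions a water
#' center could not occupy with the ligand present.
#'
#' @param member_positions n x 3 matrix of member observations.
#' @param ligand a `restime_structure` or a list(xyz, vdw).
#' @param offset added to the vdW radius (default 1.4, the water probe).
#' @return value in [0, 1].
#' @export
overlap_factor <- function(member_positions, ligand, offset = 1.4) {
  lg <- ligand_geometry(ligand)
  pts <- as.matrix(member_positions)
  inside <- rep(FALSE, nrow(pts))
  for (j in seq_len(nrow(lg$xyz))) {
    d <- sqrt((pts[, 1] - lg$xyz[j, 1])^2 + (pts[, 2] - lg$xyz[j, 2])^2 +
                (pts[, 3] - lg$xyz[j, 3])^2)
    inside <- inside | d <= lg$vdw[j] + offset
  }
  mean(inside)
}

ligand_geometry <- function(ligand) {
  if (inherits(ligand, "restime_structure")) {
    idx <- atom_select(ligand, ligand = TRUE)
    if (!length(idx)) idx <- seq_len(nrow(ligand$atoms))
    idx <- idx[ligand$atoms$element[idx] != "H"]
    list(xyz = coords(ligand)[idx, , drop = FALSE],
         vdw = ligand$atoms$vdw[idx])
  } else {
    list(xyz = as.matrix(ligand$xyz), vdw = ligand$vdw)
  }
}

#' Displaced-water resolvation score of a ligand
#'
#' A site is displaced when its overlap factor is strictly greater than
#' `threshold` (0.5). The ligand score is minus the sum of the displaced
#' sites' delta-G values, so displacing unstable high-energy water
#' contributes favourably (negatively).
#'
#' @param sites `restime_sites` with a `delta_g` column (or supplied via
#'   `delta_g`).
#' @param ligand see [overlap_factor()].
#' @param delta_g optional vector of site energies (kcal/mol).
#' @param threshold strict displacement threshold (default 0.5).
#' @param offset vdW offset for the overlap factor.
#' @return list with per-site table (`sites` plus overlap and displaced
#'   columns) and the ligand `score` in kcal/mol.
#' @export
ligand_displacement_score <- function(sites, ligand, delta_g = NULL,
                                      threshold = 0.5, offset = 1.4) {
  if (is.null(delta_g)) delta_g <- sites$delta_g
  if (is.null(delta_g) || any(is.na(delta_g)))
    stop("missing delta_g for site(s): ",
         paste(which(is.na(delta_g %||% rep(NA, nrow(sites)))), collapse = ", "))
  members <- attr(sites, "members")
  ov <- vapply(seq_len(nrow(sites)), function(i) {
    mp <- if (!is.null(members) && length(members) >= i) members[[i]] else
      matrix(as.numeric(sites[i, c("x", "y", "z")]), 1)
    overlap_factor(mp, ligand, offset)
  }, numeric(1))
  displaced <- ov > threshold
  tab <- cbind(as.data.frame(sites), delta_g = delta_g, overlap = ov,
               displaced = displaced)
  list(sites = tab, score = -sum(delta_g[displaced]))
}

#' Read a hydration-site table
#'
#' TSV with columns x, y, z, delta_g (and optionally occupancy), for example
#' exported from inhomogeneous-solvation-theory software.
#'
#' @param path TSV file.
#' @export
read_hydration_sites <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("x", "y", "z", "delta_g") %in% names(tab)))
  class(tab) <- c("restime_sites", "data.frame")
  tab
}

#' Equilibrium-probability-weighted state score
#'
#' Per-state scores (means over each state's representative structures if a
#' `state` grouping is given) combined as sum(pi_i * s_i) / sum(pi_i), with
#' the plain average reported alongside.
#'
#' @param scores numeric scores, one per state, or one per structure when
#'   `state` is given.
#' @param pi equilibrium probabilities (weights; non-negative, not all 0).
#' @param state optional integer state label per score.
#' @return list(state_scores, pi, plain_average, weighted_average).
#' @export
weighted_state_score <- function(scores, pi, state = NULL) {
  if (!is.null(state)) {
    scores <- vapply(split(scores, state), mean, numeric(1))
  }
  if (length(scores) != length(pi)) stop("scores and pi lengths differ")
  if (any(pi < 0) || all(pi == 0)) stop("weights must be >= 0 and not all 0")
  list(state_scores = unname(scores), pi = pi,
       plain_average = mean(scores),
       weighted_average = sum(pi * scores) / sum(pi))
}
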