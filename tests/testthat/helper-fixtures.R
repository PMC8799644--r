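# Fixture builders and independent oracles used across the test files.
# Everything is generated in code; no binary fixtures.

# ---- PDB text builders -------------------------------------------------

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM", element = NULL) {
  if (is.null(element)) element <- substr(gsub("^[0-9]+", "", name), 1, 1)
  namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, namef, resname, chain, resno, x, y, z, 1, 0, element)
}

# one glycine with backbone + HA hydrogens
glycine_pdb_text <- function() {
  c(pdb_line(1, "N",  "GLY", "A", 1, 0.000, 0.000, 0.000),
    pdb_line(2, "CA", "GLY", "A", 1, 1.458, 0.000, 0.000),
    pdb_line(3, "C",  "GLY", "A", 1, 2.000, 1.420, 0.000),
    pdb_line(4, "O",  "GLY", "A", 1, 1.300, 2.420, 0.000),
    pdb_line(5, "H",  "GLY", "A", 1, -0.500, -0.800, 0.000, element = "H"),
    "END")
}

waters_pdb_text <- function(centers) {
  lines <- character()
  for (i in seq_len(nrow(centers))) {
    lines <- c(lines, pdb_line(i, "O", "HOH", "W", i, centers[i, 1],
                               centers[i, 2], centers[i, 3],
                               record = "HETATM", element = "O"))
  }
  c(lines, "END")
}

write_tmp_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# a small poly-glycine helix-like chain with n residues (backbone only)
polyglycine_structure <- function(n_res, phi_jitter = 0) {
  atoms <- list()
  serial <- 0
  for (r in seq_len(n_res)) {
    base <- c(3.5 * r, 0.8 * (r %% 2), 0.3 * r)
    nm <- c("N", "CA", "C", "O")
    off <- rbind(c(0, 0, 0), c(1.2, 0.7, 0.2), c(2.4, 0.2, 0.5),
                 c(2.6, -1.0, 0.6))
    for (k in 1:4) {
      serial <- serial + 1
      atoms[[serial]] <- data.frame(
        serial = serial, name = nm[k], element = substr(nm[k], 1, 1),
        resname = "GLY", resno = r, chain = "A",
        x = base[1] + off[k, 1], y = base[2] + off[k, 2],
        z = base[3] + off[k, 3], vdw = vdw_radius_for(substr(nm[k], 1, 1)),
        backbone = TRUE, sidechain = FALSE, water_o = FALSE, water_h = FALSE,
        ligand = FALSE, donor = FALSE, hydrogen = FALSE, acceptor = TRUE,
        positive = FALSE, negative = FALSE, polar = TRUE,
        ring_id = NA_character_, hydrogen_of = NA_integer_)
    }
  }
  restime:::new_structure(do.call(rbind, atoms))
}

# a bare structure from coordinates + elements (all flagged as ligand)
ligand_structure <- function(xyz, elements = rep("C", nrow(xyz))) {
  a <- restime:::synthetic_atoms(nrow(xyz))
  a$element <- elements
  a$name <- paste0(elements, seq_len(nrow(xyz)))
  a$vdw <- vdw_radius_for(elements)
  a$ligand <- TRUE
  a[, c("x", "y", "z")] <- xyz
  restime:::new_structure(a)
}

rigid_transform <- function(xyz, angles = c(0.3, -0.5, 1.1),
                            shift = c(5, -3, 2)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  sweep(xyz %*% t(Rz %*% Ry %*% Rx), 2, shift, `+`)
}

transform_structure <- function(s, ...) {
  restime:::set_coords(s, rigid_transform(restime:::coords(s), ...))
}

# ---- independent oracles ----------------------------------------------

# brute-force superposition via quaternion grid + Nelder-Mead refinement
oracle_superpose_rmsd <- function(mobile_xyz, ref_xyz) {
  cm <- colMeans(mobile_xyz); cr <- colMeans(ref_xyz)
  A <- sweep(mobile_xyz, 2, cm); B <- sweep(ref_xyz, 2, cr)
  rot_from_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
          c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
          c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  }
  obj <- function(q) {
    if (sum(q^2) < 1e-12) return(1e9)
    sqrt(mean(rowSums((A %*% t(rot_from_q(q)) - B)^2)))
  }
  set.seed(99)
  best <- Inf; bestq <- c(1, 0, 0, 0)
  for (i in 1:400) {
    q <- rnorm(4)
    v <- obj(q)
    if (v < best) { best <- v; bestq <- q }
  }
  opt <- optim(bestq, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# Monte-Carlo SASA: random points on each expanded sphere
oracle_mc_sasa <- function(xyz, radii, probe = 1.4, n_samples = 1e6,
                           seed = 7) {
  set.seed(seed)
  R <- radii + probe
  w <- R^2 / sum(R^2)
  n_i <- round(n_samples * w)
  total <- 0
  for (i in seq_along(R)) {
    u <- matrix(rnorm(n_i[i] * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * R[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_i[i])
    for (j in seq_along(R)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= R[j]^2
    }
    total <- total + 4 * pi * R[i]^2 * mean(acc)
  }
  total
}

# Independent solvent-excluded surface area for TWO spheres on the x-axis:
# numerically trace the meridian profile of the closing (union dilated by the
# probe, then eroded) and integrate the surface of revolution. Membership
# uses only the definition of the closing, not the patch decomposition.
oracle_two_sphere_ses <- function(r1, r2, d, probe = 1.4, nz = 4000) {
  R1 <- r1 + probe; R2 <- r2 + probe
  # meridian half-plane: dilated region = two disks at (0,0) and (d,0)
  outside_dilated <- function(z, rho) {
    (z^2 + rho^2 >= R1^2) & ((z - d)^2 + rho^2 >= R2^2)
  }
  # distance from point to the complement of the dilated region (2D problem,
  # valid in 3D by rotational symmetry when the nearest complement point has
  # rho >= 0); evaluated by dense sampling of the complement boundary
  th <- seq(-pi, pi, length.out = 3000)
  b1 <- cbind(R1 * cos(th), R1 * sin(th))
  b2 <- cbind(d + R2 * cos(th), R2 * sin(th))
  bnd <- rbind(b1[outside_dilated(b1[, 1], b1[, 2] + 0) &
                    ((b1[, 1] - d)^2 + b1[, 2]^2 >= R2^2 - 1e-9), ],
               b2[outside_dilated(b2[, 1], b2[, 2]) &
                    (b2[, 1]^2 + b2[, 2]^2 >= R1^2 - 1e-9), ])
  in_closing <- function(z, rho) {
    if (!outside_dilated(z, rho)) {
      dmin <- sqrt(min((bnd[, 1] - z)^2 + (bnd[, 2] - rho)^2,
                       (bnd[, 1] - z)^2 + (bnd[, 2] + rho)^2))
      return(dmin > probe)   # no probe ball through the point fits outside
    }
    # outside the dilated region: inside closing only if inside a vdW ball
    (z^2 + rho^2 <= r1^2) | ((z - d)^2 + rho^2 <= r2^2)
  }
  zs <- seq(-r1 - 0.2, d + r2 + 0.2, length.out = nz)
  prof <- vapply(zs, function(z) {
    lo <- 0; hi <- max(R1, R2) + probe
    if (in_closing(z, hi)) return(hi)
    if (!in_closing(z, lo)) return(0)
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (in_closing(z, mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  dz <- zs[2] - zs[1]
  area <- 0
  for (i in seq_len(nz - 1)) {
    if (prof[i] <= 0 && prof[i + 1] <= 0) next
    drho <- prof[i + 1] - prof[i]
    area <- area + 2 * pi * (prof[i] + prof[i + 1]) / 2 *
      sqrt(dz^2 + drho^2)
  }
  area
}

# exhaustive best-first greedy clustering oracle for few points
oracle_greedy_cluster <- function(pts, radius, min_occ) {
  alive <- rep(TRUE, nrow(pts))
  sites <- list()
  repeat {
    idx <- which(alive)
    if (!length(idx)) break
    counts <- vapply(idx, function(j)
      sum(colSums((t(pts[idx, , drop = FALSE]) - pts[j, ])^2) <= radius^2),
      integer(1))
    if (max(counts) < min_occ) break
    best <- idx[which.max(counts)]
    mem <- idx[colSums((t(pts[idx, , drop = FALSE]) - pts[best, ])^2) <=
                 radius^2]
    sites[[length(sites) + 1]] <- colMeans(pts[mem, , drop = FALSE])
    alive[mem] <- FALSE
  }
  sites
}

# exhaustive optimal 2-partition k-means objective for <= 20 points
oracle_best_bipartition <- function(Y) {
  n <- nrow(Y)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(g) || all(g)) next
    ss <- function(M) if (nrow(M) == 0) 0 else
      sum(sweep(M, 2, colMeans(M))^2)
    v <- ss(Y[g, , drop = FALSE]) + ss(Y[!g, , drop = FALSE])
    if (v < best) best <- v
  }
  best
}
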