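# Synthetic-data generators with planted ground truth. Each generator is
# deterministic under a fixed seed and returns the truth alongside the data,
# so every downstream stage can be validated without trajectory downloads.

#' Planted metastable feature trajectory
#'
#' Samples a reversible Markov chain over metastable states (built from
#' symmetric exchange flows, so the stationary distribution is exactly
#' `pi`) and emits Gaussian features around per-state centers. The default
#' stationary split (0.43, 0.32, 0.25) mirrors a three-state kinase-inhibitor
#' partition; emission noise is chosen so basins overlap mildly (a few
#' percent misassignment), making state recovery nontrivial but reliable.
#'
#' @param n_frames number of frames.
#' @param pi planted stationary distribution.
#' @param exchange_flows symmetric inter-state probability flows per step,
#'   one per state pair in column-major upper-triangle order (1-2, 1-3, 2-3
#'   for three states). Must leave all self-transition masses positive.
#' @param centers n_states x d matrix of emission centers (default: an
#'   equilateral triangle of side 4 in 2 dimensions).
#' @param sigma emission standard deviation (default 1.0).
#' @param n_features embed the emission space in this many feature
#'   dimensions with a fixed mixing matrix (default: emission dimension).
#' @param seed RNG seed.
#' @return list(features, labels, pi_true, T_true, timescales_true, spec).
#' @export
gen_metastable_trajectory <- function(n_frames = 100000,
                                      pi = c(0.43, 0.32, 0.25),
                                      exchange_flows = c(0.006, 0.0025, 0.0015),
                                      centers = NULL, sigma = 0.85,
                                      n_features = NULL, seed = 1) {
  m <- length(pi)
  stopifnot(abs(sum(pi) - 1) < 1e-9, all(pi > 0))
  Fm <- matrix(0, m, m)
  Fm[upper.tri(Fm)] <- exchange_flows
  Fm <- Fm + t(Fm)
  diag(Fm) <- pi - rowSums(Fm)
  if (any(diag(Fm) <= 0)) stop("exchange flows too large for pi")
  T_true <- Fm / pi
  lam <- sort(eigen(T_true, only.values = TRUE)$values, decreasing = TRUE)
  timescales <- -1 / log(pmax(Re(lam[-1]), .Machine$double.eps))
  if (is.null(centers)) {
    centers <- rbind(c(0, 0), c(4, 0), c(2, 2 * sqrt(3)))[seq_len(m), , drop = FALSE]
  }
  d <- ncol(centers)
  set.seed(seed)
  states <- integer(n_frames)
  states[1] <- sample.int(m, 1, prob = pi)
  u <- runif(n_frames)
  cumT <- t(apply(T_true, 1, cumsum))
  for (t in 2:n_frames)
    states[t] <- findInterval(u[t], cumT[states[t - 1], ]) + 1L
  X <- centers[states, , drop = FALSE] +
    matrix(rnorm(n_frames * d, sd = sigma), n_frames, d)
  if (!is.null(n_features) && n_features > d) {
    # fixed orthogonal-ish mixing so the informative subspace is spread out
    mix <- qr.Q(qr(matrix(sin(seq_len(d * n_features)), n_features, d)))
    X <- X %*% t(mix) +
      matrix(rnorm(n_frames * n_features, sd = 0.5), n_frames, n_features)
  }
  list(features = X, labels = states, pi_true = pi, T_true = T_true,
       timescales_true = timescales,
       spec = list(n_frames = n_frames, sigma = sigma, seed = seed))
}

# build a minimal annotated atom table; flags default to FALSE/NA
synthetic_atoms <- function(n) {
  data.frame(serial = seq_len(n), name = paste0("X", seq_len(n)),
             element = "C", resname = "LIG", resno = 1L, chain = "A",
             x = 0, y = 0, z = 0, vdw = 1.70,
             backbone = FALSE, sidechain = FALSE, water_o = FALSE,
             water_h = FALSE, ligand = FALSE, donor = FALSE,
             hydrogen = FALSE, acceptor = FALSE, positive = FALSE,
             negative = FALSE, polar = FALSE, ring_id = NA_character_,
             hydrogen_of = NA_integer_, stringsAsFactors = FALSE)
}

hexagon_ring <- function(center, normal, radius = 1.39) {
  normal <- normal / sqrt(sum(normal^2))
  u <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * normal) * normal; e1 <- e1 / sqrt(sum(e1 * e1))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  sweep(outer(cos(th), e1) * radius + outer(sin(th), e2) * radius, 2,
        center, `+`)
}

#' Interaction geometry fixture
#'
#' Builds a minimal atom set realizing one interaction geometry exactly
#' (distances in Angstrom, angles in degrees), plus a trajectory variant
#' that holds the geometry in a prescribed fraction of frames and breaks it
#' (partner moved 20 Angstrom away) in the rest.
#'
#' @param kind one of "hbond", "pication", "pipi", "waterbridge", "saltbridge".
#' @param distance the kind's characteristic distance (H...A for hbond,
#'   center-centroid for pication, centroid-centroid for pipi, H...A for
#'   waterbridge, N-O for saltbridge).
#' @param donor_angle,acceptor_angle H-bond angles (degrees).
#' @param plane_angle interplanar angle for pipi (degrees).
#' @param n_frames,on_fraction,seed trajectory variant: number of frames and
#'   the exact fraction of frames with the geometry on.
#' @return list(structure, trajectory (or NULL), on_frames).
#' @export
gen_interaction_fixture <- function(kind, distance = NULL, donor_angle = 150,
                                    acceptor_angle = 120, plane_angle = 0,
                                    n_frames = NULL, on_fraction = 1,
                                    seed = 1) {
  build <- switch(kind,
    hbond = function(d) {
      d <- d %||% 2.4
      a <- synthetic_atoms(4)
      a$name <- c("N1", "H1", "O", "C")
      a$element <- c("N", "H", "O", "C")
      # acceptor O at origin with neighbour C; H placed at the requested
      # distance and acceptor angle; donor N at the requested donor angle
      th <- acceptor_angle * pi / 180
      a[4, c("x", "y", "z")] <- c(1.23, 0, 0)
      H <- d * c(cos(th), sin(th), 0)
      a[2, c("x", "y", "z")] <- H
      u <- -H / sqrt(sum(H^2))            # H -> acceptor direction
      v <- c(-u[2], u[1], 0)
      phi <- donor_angle * pi / 180
      a[1, c("x", "y", "z")] <- H + 1.0 * (cos(phi) * u + sin(phi) * v)
      a$resname[1:2] <- "LIG"; a$ligand[1:2] <- TRUE
      a$resname[3:4] <- "GLY"; a$resno[3:4] <- 2L
      a$backbone[3:4] <- TRUE
      a$donor[1] <- TRUE; a$hydrogen[2] <- TRUE; a$hydrogen_of[2] <- 1L
      a$acceptor[3] <- TRUE; a$polar[1:3] <- TRUE
      a$vdw <- vdw_radius_for(a$element)
      list(atoms = a, rings = list(), mobile = 1:2)
    },
    pication = function(d) {
      d <- d %||% 4.4
      a <- synthetic_atoms(7)
      ring <- hexagon_ring(c(0, 0, 0), c(0, 0, 1))
      a[1:6, c("x", "y", "z")] <- ring
      a$name[1:6] <- paste0("C", 1:6)
      a$resname[1:6] <- "LIG"; a$ligand[1:6] <- TRUE
      a$ring_id[1:6] <- "lig.r1"
      a[7, c("x", "y", "z")] <- c(0, 0, d)
      a$name[7] <- "NZ"; a$element[7] <- "N"; a$resname[7] <- "LYS"
      a$resno[7] <- 53L; a$sidechain[7] <- TRUE; a$positive[7] <- TRUE
      a$vdw <- vdw_radius_for(a$element)
      list(atoms = a, rings = list(lig.r1 = 1:6), mobile = 7)
    },
    pipi = function(d) {
      d <- d %||% 3.8
      a <- synthetic_atoms(12)
      r1 <- hexagon_ring(c(0, 0, 0), c(0, 0, 1))
      n2 <- c(0, sin(plane_angle * pi / 180), cos(plane_angle * pi / 180))
      r2 <- hexagon_ring(c(0, 0, d), n2)
      a[1:6, c("x", "y", "z")] <- r1
      a[7:12, c("x", "y", "z")] <- r2
      a$name <- paste0("C", 1:12)
      a$resname[1:6] <- "LIG"; a$ligand[1:6] <- TRUE
      a$ring_id[1:6] <- "lig.r1"
      a$resname[7:12] <- "PHE"; a$resno[7:12] <- 169L
      a$sidechain[7:12] <- TRUE; a$ring_id[7:12] <- "PHE169.1"
      list(atoms = a, rings = list(lig.r1 = 1:6, PHE169.1 = 7:12),
           mobile = 7:12)
    },
    waterbridge = function(d) {
      d <- d %||% 2.7
      a <- synthetic_atoms(7)
      a$name <- c("O1", "OW", "HW1", "HW2", "N", "H", "CA")
      a$element <- c("O", "O", "H", "H", "N", "H", "C")
      # ligand carbonyl O at origin; water donates HW1 to it; protein
      # backbone N-H donates to the water oxygen
      a[1, c("x", "y", "z")] <- c(0, 0, 0)
      hw1 <- c(0, 0, d)
      a[3, c("x", "y", "z")] <- hw1
      ow <- hw1 + c(0, 0.25, 0.92)      # ~165 deg donor angle at HW1
      ow <- hw1 + 0.96 * (ow - hw1) / sqrt(sum((ow - hw1)^2))
      a[2, c("x", "y", "z")] <- ow
      a[4, c("x", "y", "z")] <- ow + c(0.93, 0, 0.25)
      h <- ow + d * c(0, 0.94, 0.34) / sqrt(sum(c(0, 0.94, 0.34)^2))
      a[6, c("x", "y", "z")] <- h
      nn <- h + 1.0 * (h - ow) / sqrt(sum((h - ow)^2))
      a[5, c("x", "y", "z")] <- nn
      a[7, c("x", "y", "z")] <- nn + c(1.45, 0, 0)
      a$resname[1] <- "LIG"; a$ligand[1] <- TRUE
      a$resname[2:4] <- "HOH"; a$resno[2:4] <- 100L
      a$water_o[2] <- TRUE; a$water_h[3:4] <- TRUE
      a$hydrogen_of[3:4] <- 2L
      a$resname[5:7] <- "GLY"; a$resno[5:7] <- 2L; a$backbone[5:7] <- TRUE
      a$donor[5] <- TRUE; a$hydrogen[6] <- TRUE; a$hydrogen_of[6] <- 5L
      a$acceptor[c(1, 5)] <- TRUE; a$polar[c(1, 2, 3, 4, 5, 6)] <- TRUE
      a$vdw <- vdw_radius_for(a$element)
      list(atoms = a, rings = list(), mobile = 2:4)
    },
    saltbridge = function(d) {
      d <- d %||% 3.9
      a <- synthetic_atoms(2)
      a$name <- c("NZ", "OE1")
      a$element <- c("N", "O")
      a$resname <- c("LYS", "GLU"); a$resno <- c(53L, 71L)
      a$sidechain <- TRUE
      a[2, c("x", "y", "z")] <- c(d, 0, 0)
      a$positive[1] <- TRUE; a$negative[2] <- TRUE
      a$vdw <- vdw_radius_for(a$element)
      list(atoms = a, rings = list(), mobile = 2)
    },
    stop("unknown interaction kind: ", kind)
  )
  bb <- build(distance)
  s <- new_structure(bb$atoms, bb$rings, paste("synthetic", kind, "fixture"))
  traj <- NULL; on_frames <- NULL
  if (!is.null(n_frames)) {
    n_on <- round(on_fraction * n_frames)
    set.seed(seed)
    on_frames <- sort(sample.int(n_frames, n_on))
    xyz_on <- as.vector(t(coords(s)))
    xyz_off <- xyz_on
    for (i in bb$mobile) xyz_off[3 * i - 2] <- xyz_off[3 * i - 2] + 20
    xyz <- matrix(rep(xyz_off, each = n_frames), n_frames)
    xyz[on_frames, ] <- matrix(rep(xyz_on, each = length(on_frames)),
                               length(on_frames))
    traj <- new_trajectory(s, xyz)
  }
  list(structure = s, trajectory = traj, on_frames = on_frames)
}

#' Water ensemble with planted hydration sites
#'
#' Each planted site contributes `occupancy` observations drawn from an
#' isotropic Gaussian (sd 0.3 Angstrom) around its center, distributed over
#' frames; uniform bulk noise is added inside the shell. Site centers must
#' be at least 1 Angstrom apart.
#'
#' @param sites data.frame(x, y, z, occupancy, delta_g).
#' @param n_frames frames to emit.
#' @param bulk_per_frame uniform noise observations per frame.
#' @param shell_center,shell bulk-noise region (sphere).
#' @param sigma site scatter (default 0.3).
#' @param seed RNG seed.
#' @return list(positions = per-frame matrices, truth = sites).
#' @export
gen_water_ensemble <- function(sites, n_frames = 100, bulk_per_frame = 0,
                               shell_center = c(0, 0, 0), shell = 10,
                               sigma = 0.3, seed = 1) {
  ctrs <- as.matrix(sites[, c("x", "y", "z")])
  if (nrow(ctrs) > 1 && min(dist(ctrs)) < 1.0)
    stop("planted sites closer than 1 Angstrom")
  if (any(sites$occupancy > n_frames))
    stop("occupancy cannot exceed n_frames for a single-water site")
  set.seed(seed)
  frames <- replicate(n_frames, matrix(numeric(0), 0, 3), simplify = FALSE)
  for (i in seq_len(nrow(sites))) {
    occ <- sites$occupancy[i]
    fidx <- sample.int(n_frames, occ)
    obs <- matrix(rnorm(occ * 3, sd = sigma), occ, 3) +
      matrix(ctrs[i, ], occ, 3, byrow = TRUE)
    for (j in seq_len(occ))
      frames[[fidx[j]]] <- rbind(frames[[fidx[j]]], obs[j, ])
  }
  if (bulk_per_frame > 0) {
    for (f in seq_len(n_frames)) {
      # uniform in the shell sphere by radius-cubed inversion
      r <- shell * runif(bulk_per_frame)^(1 / 3)
      u <- matrix(rnorm(bulk_per_frame * 3), bulk_per_frame, 3)
      u <- u / row_norms(u)
      frames[[f]] <- rbind(frames[[f]],
                           sweep(u * r, 2, shell_center, `+`))
    }
  }
  list(positions = frames, truth = sites)
}

# double-well unbinding potential: minima at x = 3 (bound) and x = 15
# (dissociated), barrier of the given height at x = 9
toy_potential <- function(x, barrier) barrier * (((x - 9)^2 - 36)^2) / 1296
toy_force <- function(x, barrier) -barrier * (x - 9) * ((x - 9)^2 - 36) / 324

#' Toy well-tempered metadynamics traces
#'
#' Overdamped Langevin dynamics on a 1-D double-well unbinding potential
#' (bound well at 3 Angstrom, dissociated well at 15 Angstrom) with
#' well-tempered Gaussian deposition: each deposited height is
#' h0 * exp(-V_bias(x)/kTemp), so heights at revisited points never
#' increase. The bias is accumulated on a fine grid. One time step is 1 ps;
#' deposition happens every `interval_steps`. Purpose: validating trace
#' parsing, dissociation classification and the well-tempered update rule -
#' not physics.
#'
#' @param n_replicas independent replicas (default 20).
#' @param n_steps steps per replica (default 20000, i.e. 20 ns).
#' @param barrier barrier height in kcal/mol (default 6.5).
#' @param kT thermal energy (default 0.616 kcal/mol, 310 K).
#' @param height Gaussian height h0 (default 0.2 kcal/mol).
#' @param width Gaussian width (default 0.03 Angstrom).
#' @param interval_steps deposition interval in steps (default 1, i.e. 1 ps).
#' @param kTemp well-tempered damping parameter (default 3.4 kcal/mol).
#' @param wall reflecting wall position (default 35 Angstrom).
#' @param step_sd diffusive step standard deviation (default 0.3 Angstrom).
#' @param bias FALSE runs plain Langevin with zero bias.
#' @param seed RNG seed; replica r uses seed + r so biased/unbiased runs can
#'   be paired.
#' @return list(traces, max_cv, escaped (max_cv >= 15), depositions).
#' @export
gen_metad_traces <- function(n_replicas = 20, n_steps = 20000, barrier = 6.5,
                             kT = 0.616, height = 0.2, width = 0.03,
                             interval_steps = 1, kTemp = 3.4, wall = 35,
                             step_sd = 0.3, bias = TRUE, seed = 1) {
  if (wall <= 15) stop("wall must lie beyond the dissociated well")
  grid <- seq(0, wall, by = 0.01)
  mob <- step_sd^2 / (2 * kT)   # D * dt / kT with dt = 1
  traces <- vector("list", n_replicas)
  max_cv <- numeric(n_replicas)
  depos <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    set.seed(seed + r)
    noise <- rnorm(n_steps, sd = step_sd)
    vb <- numeric(length(grid))
    x <- 3
    xs <- numeric(n_steps)
    dep_x <- numeric(0); dep_h <- numeric(0)
    for (t in seq_len(n_steps)) {
      gi <- 1 + round(x / 0.01)
      gi <- min(max(gi, 2), length(grid) - 1)
      fbias <- if (bias) -(vb[gi + 1] - vb[gi - 1]) / 0.02 else 0
      f <- toy_force(x, barrier) + fbias
      x <- x + mob * f + noise[t]
      if (x < 0) x <- -x
      if (x > wall) x <- 2 * wall - x
      xs[t] <- x
      if (bias && t %% interval_steps == 0) {
        gi <- 1 + round(x / 0.01)
        gi <- min(max(gi, 1), length(grid))
        h <- height * exp(-vb[gi] / kTemp)
        lo <- max(1, gi - 60); hi <- min(length(grid), gi + 60)
        vb[lo:hi] <- vb[lo:hi] +
          h * exp(-(grid[lo:hi] - x)^2 / (2 * width^2))
        dep_x <- c(dep_x, x); dep_h <- c(dep_h, h)
      }
    }
    traces[[r]] <- data.frame(t_ns = seq_len(n_steps) / 1000, cv = xs)
    max_cv[r] <- max(xs)
    depos[[r]] <- data.frame(x = dep_x, height = dep_h)
  }
  list(traces = traces, max_cv = max_cv, escaped = max_cv >= 15,
       depositions = depos)
}
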