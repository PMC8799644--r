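# Hydration-site clustering, energies, overlap and resolvation scoring.

test_that("repeated observations at one point form a single full-occupancy site", {
  pts <- matrix(rep(c(1, 2, 3), each = 100), 100, 3, byrow = FALSE)
  pts <- matrix(c(rep(1, 100), rep(2, 100), rep(3, 100)), 100, 3)
  cl <- cluster_hydration_sites(pts, min_occupancy = 5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$occupancy, 100L)
  expect_equal(unlist(cl[1, c("x", "y", "z")]), c(x = 1, y = 2, z = 3))
})

test_that("groups separated beyond the radius give separate sites", {
  pts <- rbind(matrix(rep(c(0, 0, 0), 30), ncol = 3, byrow = TRUE),
               matrix(rep(c(5, 0, 0), 20), ncol = 3, byrow = TRUE))
  cl <- cluster_hydration_sites(pts, min_occupancy = 5)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$occupancy), c(20L, 30L))
})

test_that("greedy clustering matches the exhaustive best-first oracle", {
  set.seed(71)
  for (rep in 1:5) {
    pts <- matrix(runif(60, 0, 6), 20, 3)
    got <- cluster_hydration_sites(pts, radius = 1.5, min_occupancy = 2)
    want <- oracle_greedy_cluster(pts, 1.5, 2)
    expect_equal(nrow(got), length(want))
    if (length(want))
      expect_equal(unname(as.matrix(got[, c("x", "y", "z")])),
                   unname(do.call(rbind, want)), tolerance = 1e-12)
  }
})

test_that("clustering is invariant to frame order and conserves observations", {
  set.seed(72)
  f1 <- list(matrix(rnorm(30, 0, 0.2), 10, 3),
             matrix(rnorm(30, 4, 0.2), 10, 3))
  c1 <- cluster_hydration_sites(f1, min_occupancy = 3)
  c2 <- cluster_hydration_sites(rev(f1), min_occupancy = 3)
  expect_equal(sort(c1$occupancy), sort(c2$occupancy))
  expect_equal(sum(c1$occupancy), 20)
})

test_that("the shell filter excludes waters far from the ligand", {
  pts <- rbind(matrix(rep(c(0, 0, 0), 30), ncol = 3, byrow = TRUE),
               matrix(rep(c(30, 0, 0), 30), ncol = 3, byrow = TRUE))
  cl <- cluster_hydration_sites(pts, shell_center = matrix(0, 1, 3),
                                shell = 10, min_occupancy = 5)
  expect_equal(nrow(cl), 1)
  empty <- cluster_hydration_sites(matrix(numeric(0), 0, 3),
                                   shell_center = matrix(0, 1, 3))
  expect_equal(nrow(empty), 0)
})

test_that("inverse-Boltzmann site energies follow the defining formula", {
  vol <- (4 / 3) * pi
  bulk <- 0.0334
  occ_bulk <- bulk * vol * 100
  expect_equal(estimate_site_energy(occ_bulk, 100), 0, tolerance = 1e-12)
  expect_equal(estimate_site_energy(exp(1) * occ_bulk, 100), -0.616,
               tolerance = 1e-12)
  expect_error(estimate_site_energy(0, 100), "zero occupancy")
})

test_that("a planted double-density site is recovered within 0.1 kcal/mol", {
  sites <- data.frame(x = 0, y = 0, z = 0,
                      occupancy = round(2 * 0.0334 * (4 / 3) * pi * 500),
                      delta_g = NA)
  we <- gen_water_ensemble(sites, n_frames = 500, seed = 73)
  cl <- cluster_hydration_sites(we$positions, min_occupancy = 10)
  expect_equal(nrow(cl), 1)
  got <- estimate_site_energy(cl$occupancy, 500)
  expect_lt(abs(got - (-0.616 * log(2))), 0.1)
})

test_that("overlap factors span [0,1] with a strict displacement threshold", {
  lig <- ligand_structure(matrix(0, 1, 3))           # C, vdw 1.7
  inside <- matrix(0, 10, 3)
  expect_equal(overlap_factor(inside, lig), 1)
  far <- matrix(10, 10, 3)
  expect_equal(overlap_factor(far, lig), 0)
  # half in (distance < 3.1), half out
  half <- rbind(matrix(0, 5, 3), matrix(c(rep(5, 5), rep(0, 10)), 5, 3))
  expect_equal(overlap_factor(half, lig), 0.5)
  sites <- data.frame(x = 0, y = 0, z = 0, occupancy = 10L, n_frames = 10L)
  attr(sites, "members") <- list(half)
  class(sites) <- c("restime_sites", "data.frame")
  res <- ligand_displacement_score(sites, lig, delta_g = 3.0)
  expect_false(res$sites$displaced)   # exactly 0.5 is NOT displaced
  expect_equal(res$score, 0)
})

test_that("displacement scores sum displaced energies with a negative sign", {
  lig <- ligand_structure(matrix(0, 1, 3))
  mk_sites <- function(centers, dg) {
    s <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                    occupancy = 10L, n_frames = 10L, delta_g = dg)
    attr(s, "members") <- lapply(seq_len(nrow(centers)), function(i)
      matrix(centers[i, ], 10, 3, byrow = TRUE))
    class(s) <- c("restime_sites", "data.frame")
    s
  }
  two <- mk_sites(rbind(c(0, 0, 0), c(1, 0, 0)), c(3, 2))
  expect_equal(ligand_displacement_score(two, lig)$score, -5)
  none <- mk_sites(matrix(20, 1, 3), 5)
  expect_equal(ligand_displacement_score(none, lig)$score, 0)
  # adding a non-displaced site leaves the score unchanged (additivity)
  three <- mk_sites(rbind(c(0, 0, 0), c(1, 0, 0), c(20, 20, 20)), c(3, 2, 9))
  expect_equal(ligand_displacement_score(three, lig)$score, -5)
  expect_error(ligand_displacement_score(mk_sites(matrix(0, 1, 3), NA), lig),
               "delta_g")
})

test_that("hydration-site recall is 1.0 and scores match the generator truth", {
  planted <- data.frame(x = c(0, 3, -2, 0), y = c(0, 1, 2, -3),
                        z = c(0, 0, 2, 1),
                        occupancy = c(180, 160, 150, 170),
                        delta_g = c(2.5, 1.2, -0.8, 3.1))
  we <- gen_water_ensemble(planted, n_frames = 200, bulk_per_frame = 10,
                           shell_center = c(0, 0, 0), shell = 10, seed = 74)
  lig <- ligand_structure(rbind(c(0, 0, 0), c(3, 1, 0)))
  cl <- cluster_hydration_sites(we$positions, shell_center = rbind(c(0, 0, 0)),
                                shell = 10)
  # recall: every planted site matched by a recovered center within 0.5 A
  d <- vapply(seq_len(nrow(planted)), function(i)
    min(sqrt((cl$x - planted$x[i])^2 + (cl$y - planted$y[i])^2 +
               (cl$z - planted$z[i])^2)), numeric(1))
  expect_true(all(d < 0.5))
  # transfer the planted energies to the matched sites and score
  match_idx <- vapply(seq_len(nrow(cl)), function(i)
    which.min((planted$x - cl$x[i])^2 + (planted$y - cl$y[i])^2 +
                (planted$z - cl$z[i])^2), integer(1))
  cl$delta_g <- planted$delta_g[match_idx]
  res <- ligand_displacement_score(cl, lig)
  truth_displaced <- vapply(seq_len(nrow(cl)), function(i)
    overlap_factor(attr(cl, "members")[[i]], lig) > 0.5, logical(1))
  expect_equal(res$score, -sum(cl$delta_g[truth_displaced]))
})

test_that("zero bulk noise never produces spurious sites", {
  planted <- data.frame(x = c(0, 4), y = 0, z = 0, occupancy = c(90, 80),
                        delta_g = c(1, 2))
  we <- gen_water_ensemble(planted, n_frames = 100, bulk_per_frame = 0,
                           seed = 75)
  cl <- cluster_hydration_sites(we$positions, min_occupancy = 10)
  expect_equal(nrow(cl), 2)
})

test_that("equilibrium-probability weighting reproduces hand arithmetic", {
  ws <- weighted_state_score(c(-50, -45.2, -60), c(0.08, 0.07, 0.85))
  expect_equal(ws$weighted_average, -58.164, tolerance = 1e-9)
  expect_equal(ws$plain_average, mean(c(-50, -45.2, -60)))
  eq <- weighted_state_score(c(-1, -2, -3), rep(1 / 3, 3))
  expect_equal(eq$weighted_average, eq$plain_average)
  one <- weighted_state_score(c(-1, -2, -3), c(0, 1, 0))
  expect_equal(one$weighted_average, -2)
  # per-structure scores are averaged within state first
  per <- weighted_state_score(c(-10, -20, -40, -60), c(0.5, 0.5),
                              state = c(1, 1, 2, 2))
  expect_equal(per$state_scores, c(-15, -50))
  expect_equal(per$weighted_average, -32.5)
  expect_error(weighted_state_score(c(1, 2), c(1, 2, 3)), "lengths")
  expect_error(weighted_state_score(c(1, 2), c(0, 0)), "not all 0")
})

test_that("hydration-site tables round trip through TSV", {
  tab <- data.frame(x = 1, y = 2, z = 3, occupancy = 50L, delta_g = 1.5)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_hydration_sites(path)
  expect_equal(got$delta_g, 1.5)
})
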