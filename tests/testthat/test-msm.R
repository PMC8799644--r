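# Featurization, VAMP-2, TICA, microstate clustering, transition-matrix
# estimation, implied timescales, Chapman-Kolmogorov and PCCA++.

sample_chain <- function(T, n, seed = 1, start = 1) {
  set.seed(seed)
  m <- nrow(T)
  cumT <- t(apply(T, 1, cumsum))
  s <- integer(n)
  s[1] <- start
  u <- runif(n)
  for (t in 2:n) s[t] <- findInterval(u[t], cumT[s[t - 1], ]) + 1L
  s
}

test_that("a 5-residue chain yields 4 phi + 4 psi torsions as cos/sin pairs", {
  s <- polyglycine_structure(5)
  traj <- restime:::new_trajectory(s, rbind(as.vector(t(restime:::coords(s)))))
  ft <- featurize_backbone_torsions(traj)
  expect_equal(ncol(ft$X), 16)
  cs <- ft$X[1, seq(1, 15, by = 2)]^2 + ft$X[1, seq(2, 16, by = 2)]^2
  expect_equal(unname(cs), rep(1, 8), tolerance = 1e-9)
  # excluded residues drop their torsions
  ft2 <- featurize_backbone_torsions(traj, residue_exclusions = 3)
  expect_equal(ncol(ft2$X), 12)
})

test_that("the cos/sin encoding respects angular periodicity", {
  enc <- function(a) c(cos(a * pi / 180), sin(a * pi / 180))
  d_wrap <- sqrt(sum((enc(179) - enc(-179))^2))
  d_near <- sqrt(sum((enc(179) - enc(170))^2))
  expect_lt(d_wrap, d_near)
})

test_that("VAMP-2 scores iid noise near 1 and Markov indicators at 1+lambda^2", {
  set.seed(51)
  noise <- matrix(rnorm(20000), ncol = 2)
  expect_equal(vamp2_score(noise, lag = 5, n_components = 3), 1,
               tolerance = 0.01)
  T <- rbind(c(0.9, 0.1), c(0.1, 0.9))     # lambda_2 = 0.8
  s <- sample_chain(T, 200000, seed = 52)
  X <- cbind(as.numeric(s == 1))
  expect_equal(vamp2_score(X, lag = 1, n_components = 2), 1 + 0.8^2,
               tolerance = 0.02)
  expect_equal(vamp2_score(X, lag = 1, n_components = 1), 1)
})

test_that("TICA finds the slow coordinate and ignores fast noise", {
  set.seed(53)
  n <- 20000
  ar1 <- function(n, rho) {
    x <- numeric(n)
    for (t in 2:n) x[t] <- rho * x[t - 1] + rnorm(1, sd = sqrt(1 - rho^2))
    x
  }
  slow <- ar1(n, exp(-1 / 100))
  fast <- ar1(n, exp(-1 / 2))
  X <- cbind(slow, fast)
  t1 <- fit_tica(X, lag = 10, n_dims = 2)
  ic1 <- t1$loadings[, 1] / sqrt(sum(t1$loadings[, 1]^2))
  expect_gt(abs(ic1[1]), 0.99 * sqrt(sum(ic1^2)))
  # affine feature rescaling leaves the projection unchanged up to sign
  X2 <- sweep(X %*% diag(c(3, 0.2)), 2, c(10, -4), `+`)
  t2 <- fit_tica(X2, lag = 10, n_dims = 2)
  cor12 <- abs(cor(t1$Y[, 1], t2$Y[, 1]))
  expect_gt(cor12, 0.9999)
})

test_that("TICA eigenvalues of white noise sit at zero within sampling error", {
  set.seed(54)
  reps <- vapply(1:5, function(r) {
    X <- matrix(rnorm(10000 * 3), ncol = 3)
    max(abs(fit_tica(X, lag = 5, n_dims = 1)$eigenvalues))
  }, numeric(1))
  expect_lt(max(reps), 0.08)
})

test_that("microstate count defaults to round(sqrt(n)) and degenerates safely", {
  set.seed(55)
  Y <- matrix(rnorm(800), ncol = 2)
  cl <- cluster_microstates(Y)
  expect_equal(cl$k, round(sqrt(400)))
  same <- matrix(1, 50, 2)
  cl1 <- cluster_microstates(same, k = 5)
  expect_equal(cl1$k, 1)
  expect_error(cluster_microstates(Y, k = 1000), "exceed")
})

test_that("k-means with restarts reaches the exhaustive bipartition optimum", {
  set.seed(56)
  Y <- rbind(matrix(rnorm(20, sd = 0.6), 10, 2),
             matrix(rnorm(20, 3, sd = 0.6), 10, 2))
  best_obj <- min(vapply(1:10, function(s) {
    cl <- cluster_microstates(Y, k = 2, seed = s)
    sum(vapply(seq_len(nrow(Y)), function(i)
      sum((Y[i, ] - cl$centers[cl$assignments[i], ])^2), numeric(1)))
  }, numeric(1)))
  expect_lte(best_obj, oracle_best_bipartition(Y) * 1.05)
})

test_that("symmetric counts give the symmetric transition matrix exactly", {
  fit <- restime:::reversible_mle(rbind(c(9, 1), c(1, 9)))
  expect_equal(fit$T, rbind(c(0.9, 0.1), c(0.1, 0.9)), tolerance = 1e-9)
  expect_equal(fit$mu, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("nonreversible estimation returns the stationary left eigenvector", {
  C <- rbind(c(90, 10), c(30, 70))
  T <- C / rowSums(C)
  expect_equal(restime:::stationary_distribution(T), c(0.75, 0.25),
               tolerance = 1e-12)
})

test_that("the reversible estimator satisfies detailed balance", {
  T3 <- rbind(c(0.90, 0.07, 0.03), c(0.05, 0.90, 0.05), c(0.02, 0.08, 0.90))
  s <- sample_chain(T3, 30000, seed = 57)
  m <- estimate_msm(s, lag = 1)
  expect_equal(rowSums(m$T), rep(1, 3), tolerance = 1e-10)
  expect_equal(as.numeric(m$mu %*% m$T), m$mu, tolerance = 1e-10)
  db <- m$mu * m$T - t(m$mu * m$T)
  expect_lt(max(abs(db)), 1e-8)
})

test_that("disconnected microstates are trimmed to the largest strong set", {
  # states 1-2 communicate; state 3 only appears once at the end
  s <- c(rep(c(1, 2), 50), 3)
  expect_message(m <- estimate_msm(s, lag = 1), "largest connected set")
  expect_equal(m$active_set, c(1, 2))
})

test_that("implied timescales follow -tau/log(lambda) and flag edge cases", {
  expect_equal(restime:::implied_timescale_values(0.9, 40), -40 / log(0.9))
  expect_equal(round(restime:::implied_timescale_values(0.9, 40), 2), 379.65)
  expect_true(is.na(restime:::implied_timescale_values(1, 40)))
  expect_true(is.na(restime:::implied_timescale_values(-0.2, 40)))
})

test_that("an exactly Markov chain has flat implied timescales across lags", {
  T <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  s <- sample_chain(T, 100000, seed = 58)
  its <- implied_timescales(s, lags = c(1, 2, 5, 10), n_timescales = 1)
  ts <- its$timescale_ns
  expect_lt((max(ts) - min(ts)) / mean(ts), 0.15)
  expect_true(any(its$converged))
})

test_that("Chapman-Kolmogorov is exact at factor 1 and passes for Markov data", {
  T3 <- rbind(c(0.97, 0.02, 0.01), c(0.02, 0.96, 0.02), c(0.01, 0.03, 0.96))
  trajs <- lapply(1:5, function(r) sample_chain(T3, 8000, seed = 60 + r))
  ck <- ck_test(trajs, lag = 5, n_metastable = 3, factors = 1:4)
  f1 <- ck[ck$factor == 1, ]
  expect_equal(f1$predicted, f1$estimated, tolerance = 1e-12)
  expect_true(ck_passes(ck))
})

test_that("a hidden-state (non-Markov) process fails the CK test", {
  # three hidden states lumped into two observed ones: the sticky hidden
  # substate makes the observed 2-state process strongly non-Markov
  Th <- rbind(c(0.998, 0.002, 0), c(0.002, 0.948, 0.05), c(0, 0.05, 0.95))
  hidden <- sample_chain(Th, 60000, seed = 65)
  observed <- ifelse(hidden <= 2, 1L, 2L)
  ck <- ck_test(observed, lag = 1, n_metastable = 2,
                factors = c(1, 5, 10, 20, 40), n_boot = 50)
  expect_false(ck_passes(ck))
})

test_that("PCCA++ of a 2-state chain is the identity partition with pi = mu", {
  s <- sample_chain(rbind(c(0.9, 0.1), c(0.2, 0.8)), 20000, seed = 66)
  m <- estimate_msm(s, lag = 1)
  p <- pcca_coarse_grain(m, 2)
  expect_equal(sort(unique(p$assignment)), 1:2)
  expect_equal(sort(p$pi), sort(m$mu), tolerance = 1e-12)
})

test_that("PCCA++ recovers planted blocks of a 6-microstate chain", {
  # 3 blocks of 2 microstates: ~90 percent intra-block mass, ~10 percent
  # spread unevenly across the other blocks (uneven so the slow eigenvalues
  # are distinct); symmetric, hence reversible with uniform stationary mass
  T <- matrix(0, 6, 6)
  blocks <- list(1:2, 3:4, 5:6)
  T[1:2, 3:4] <- 0.035; T[1:2, 5:6] <- 0.015
  T[3:4, 1:2] <- 0.035; T[3:4, 5:6] <- 0.025
  T[5:6, 1:2] <- 0.015; T[5:6, 3:4] <- 0.025
  T[1:2, 1:2] <- 0.45; T[3:4, 3:4] <- 0.44; T[5:6, 5:6] <- 0.46
  stopifnot(all(abs(rowSums(T) - 1) < 1e-12), all(abs(T - t(T)) < 1e-12))
  m <- structure(list(T = T, mu = rep(1 / 6, 6), mode = "mle_reversible"),
                 class = "restime_msm")
  p <- pcca_coarse_grain(m, 3)
  grouping <- p$assignment
  for (b in blocks) expect_equal(length(unique(grouping[b])), 1)
  expect_equal(length(unique(grouping[c(1, 3, 5)])), 3)
  expect_equal(sum(p$pi), 1, tolerance = 1e-10)
})

test_that("representative frames are deterministic and respect state size", {
  Y <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5), c(5, 5.1), c(0, 0.1))
  cl <- list(centers = rbind(c(0.05, 0.03), c(5.03, 5.03)),
             assignments = c(1, 1, 2, 2, 2, 1))
  part <- structure(list(assignment = c(1, 2), n_states = 2,
                         mu = c(0.5, 0.5), pi = c(0.5, 0.5)),
                    class = "restime_pcca")
  w <- capture_warnings(rep1 <- select_representatives(part, Y, cl,
                                                       n_per_state = 3))
  expect_match(w, "only", all = TRUE)
  expect_equal(lengths(rep1), c(1, 1))
  # reordering frames leaves the selected coordinates unchanged
  ord <- c(3, 1, 6, 2, 5, 4)
  cl2 <- list(centers = cl$centers, assignments = cl$assignments[ord])
  rep2 <- select_representatives(part, Y[ord, ], cl2, n_per_state = 1)
  expect_equal(Y[ord, ][rep2[[1]], ], Y[rep1[[1]], ])
})

test_that("the full stack is reproducible bit-for-bit under a fixed seed", {
  g <- gen_metastable_trajectory(n_frames = 4000, seed = 9)
  f1 <- fit_msm(g$features, lag_ns = 40, k = 20, seed = 123)
  f2 <- fit_msm(g$features, lag_ns = 40, k = 20, seed = 123)
  expect_identical(f1$pcca$pi, f2$pcca$pi)
  expect_identical(f1$clustering$assignments, f2$clustering$assignments)
})

test_that("bayesian mode adds stationary-vector spread around the MLE", {
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  s <- sample_chain(T, 5000, seed = 67)
  m <- estimate_msm(s, lag = 1, mode = "bayesian", n_samples = 25)
  expect_equal(dim(m$mu_samples), c(25, 2))
  expect_lt(abs(mean(m$mu_samples[, 1]) - m$mu[1]), 0.05)
  expect_gt(sd(m$mu_samples[, 1]), 0)
})
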