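# Markov state models: k-means microstates, reversible transition-matrix
# estimation, implied timescales, Chapman-Kolmogorov validation, PCCA++
# coarse-graining and representative-frame selection.

#' k-means microstate clustering
#'
#' k defaults to round(sqrt(n_frames)). Centers are seeded with k-means++
#' under a fixed seed, refined with Lloyd iterations (stats::kmeans), and
#' empty or duplicate clusters are pruned, so the discretization is
#' reproducible bit-for-bit.
#'
#' @param projected n x d matrix (for instance TICA output).
#' @param k number of microstates (default round(sqrt(n))).
#' @param seed RNG seed for the k-means++ initialization (default 2022).
#' @param iter_max Lloyd iteration cap.
#' @return list(centers, assignments, k, seed).
#' @export
cluster_microstates <- function(projected, k = NULL, seed = 2022,
                                iter_max = 100) {
  Y <- as.matrix(projected)
  n <- nrow(Y)
  if (is.null(k)) k <- max(1L, round(sqrt(n)))
  if (k > n) stop("k must not exceed the number of frames")
  uniq <- unique(Y)
  k_eff <- min(k, nrow(uniq))
  centers <- kmeanspp_centers(uniq, k_eff, seed)
  if (k_eff == 1L) {
    fit <- list(centers = centers, cluster = rep(1L, n))
  } else {
    fit <- suppressWarnings(stats::kmeans(Y, centers = centers,
                                          iter.max = iter_max,
                                          algorithm = "Lloyd"))
  }
  centers <- fit$centers[sort(unique(fit$cluster)), , drop = FALSE]
  assign <- match(fit$cluster, sort(unique(fit$cluster)))
  list(centers = centers, assignments = assign, k = nrow(centers), seed = seed)
}

kmeanspp_centers <- function(Y, k, seed) {
  set.seed(seed)
  n <- nrow(Y)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(Y, 2, Y[idx[1], ])^2)
  if (k > 1) for (j in 2:k) {
    p <- d2 / sum(d2)
    idx[j] <- if (all(d2 == 0)) sample.int(n, 1) else sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(Y, 2, Y[idx[j], ])^2))
  }
  Y[idx, , drop = FALSE]
}

# sliding-window transition counts at the given lag
count_transitions <- function(dtrajs, lag) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  k <- max(unlist(dtrajs))
  C <- matrix(0, k, k)
  for (dt in dtrajs) {
    n <- length(dt)
    if (n <= lag) next
    from <- dt[1:(n - lag)]
    to <- dt[(1 + lag):n]
    tab <- table(factor(from, levels = 1:k), factor(to, levels = 1:k))
    C <- C + unname(as.matrix(tab))
  }
  C
}

largest_connected_set <- function(C) {
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  members <- which(comp$membership == which.max(tabulate(comp$membership)))
  sort(unname(members))
}

# reversible maximum-likelihood transition matrix by the standard fixed-point
# iteration on the symmetric flow variables x_ij
reversible_mle <- function(C, tol = 1e-12, max_iter = 10000) {
  k <- nrow(C)
  Csym <- C + t(C)
  ci <- rowSums(C)
  x <- Csym / sum(Csym)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    q <- ci / xi
    denom <- outer(q, q, `+`)
    xnew <- Csym / denom
    xnew <- xnew / sum(xnew)
    delta <- max(abs(xnew - x))
    x <- xnew
    if (delta < tol) break
  }
  xi <- rowSums(x)
  T <- x / xi
  list(T = T, mu = xi / sum(xi), iterations = it)
}

stationary_distribution <- function(T) {
  ev <- eigen(t(T))
  i <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}

#' Estimate a Markov state model from discrete trajectories
#'
#' Counts transitions at the given lag with a sliding window, restricts to
#' the largest strongly connected set of microstates, and estimates the
#' transition matrix. The reversible maximum-likelihood estimator (default)
#' satisfies detailed balance; `nonreversible` row-normalizes the counts;
#' `bayesian` adds posterior samples about the MLE (by multinomial count
#' resampling and re-estimation) to give error bars on the stationary vector,
#' while the point estimates stay at the MLE.
#'
#' @param dtrajs integer vector or list of integer vectors (microstate
#'   assignments, 1-based).
#' @param lag lag in frames (>= 1).
#' @param mode one of "mle_reversible", "nonreversible", "bayesian".
#' @param n_samples posterior samples in bayesian mode.
#' @param stride_ns ns per frame, for reporting the lag in ns.
#' @param seed RNG seed used in bayesian mode.
#' @return object of class `restime_msm` with counts, transition matrix `T`,
#'   stationary vector `mu`, the active set, and the lag.
#' @export
estimate_msm <- function(dtrajs, lag, mode = c("mle_reversible",
                                               "nonreversible", "bayesian"),
                         n_samples = 100, stride_ns = 1, seed = 2022) {
  mode <- match.arg(mode)
  if (lag < 1) stop("lag must be >= 1 frame")
  Cfull <- count_transitions(dtrajs, lag)
  active <- largest_connected_set(Cfull)
  if (!length(active)) stop("no connected microstates at this lag")
  if (length(active) < nrow(Cfull))
    message("restricting to largest connected set: ", length(active), " of ",
            nrow(Cfull), " microstates")
  C <- Cfull[active, active, drop = FALSE]
  if (mode == "nonreversible") {
    T <- C / pmax(rowSums(C), 1)
    mu <- stationary_distribution(T)
    samples <- NULL
  } else {
    fit <- reversible_mle(C)
    T <- fit$T
    mu <- fit$mu
    samples <- NULL
    if (mode == "bayesian") {
      set.seed(seed)
      rs <- rowSums(C)
      samples <- matrix(NA_real_, n_samples, nrow(C))
      for (s in seq_len(n_samples)) {
        Cs <- t(vapply(seq_len(nrow(C)), function(i)
          as.numeric(rmultinom(1, rs[i], T[i, ])), numeric(nrow(C))))
        samples[s, ] <- reversible_mle(Cs, tol = 1e-10, max_iter = 2000)$mu
      }
    }
  }
  structure(list(counts = C, T = T, mu = mu, active_set = active,
                 lag_frames = lag, lag_ns = lag * stride_ns, mode = mode,
                 mu_samples = samples),
            class = "restime_msm")
}

#' @export
print.restime_msm <- function(x, ...) {
  cat("Markov state model (", x$mode, "): ", nrow(x$T), " microstates, lag ",
      x$lag_ns, " ns\n", sep = "")
  invisible(x)
}

#' @export
summary.restime_msm <- function(object, n_timescales = 3, ...) {
  lam <- msm_eigenvalues(object, n_timescales + 1)
  ts <- implied_timescale_values(lam[-1], object$lag_frames) * object$lag_ns /
    object$lag_frames
  cat("Markov state model (", object$mode, ")\n", sep = "")
  cat("  microstates:", nrow(object$T), " lag:", object$lag_ns, "ns\n")
  cat("  slowest implied timescales (ns):",
      paste(round(ts, 1), collapse = ", "), "\n")
  invisible(list(eigenvalues = lam, timescales_ns = ts))
}

# leading eigenvalues of a reversible T via the symmetrized similar matrix
msm_eigenvalues <- function(msm, n = 5) {
  T <- msm$T; mu <- msm$mu
  S <- diag(sqrt(mu)) %*% T %*% diag(1 / sqrt(mu))
  lam <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  head(sort(lam, decreasing = TRUE), n)
}

# right eigenvectors of reversible T (real), columns sorted by eigenvalue
msm_eigenvectors <- function(msm, n) {
  T <- msm$T; mu <- msm$mu
  S <- diag(sqrt(mu)) %*% T %*% diag(1 / sqrt(mu))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ord <- order(ev$values, decreasing = TRUE)
  list(values = ev$values[ord][seq_len(n)],
       vectors = diag(1 / sqrt(mu)) %*% ev$vectors[, ord[seq_len(n)], drop = FALSE])
}

implied_timescale_values <- function(lambda, lag) {
  ts <- rep(NA_real_, length(lambda))
  ok <- lambda > 0 & lambda < 1
  ts[ok] <- -lag / log(lambda[ok])
  ts
}

#' Implied timescales over a set of lags
#'
#' t_i(tau) = -tau / log lambda_i(tau) for the leading non-unit eigenvalues.
#' A timescale is flagged converged when its relative change between
#' successive lags drops below `tol`; eigenvalues <= 0 give an absent (NA)
#' timescale, and lambda = 1 is flagged non-decaying.
#'
#' @param dtrajs discrete trajectories.
#' @param lags vector of >= 2 lags (frames).
#' @param n_timescales how many timescales to report.
#' @param mode estimator mode passed to [estimate_msm()].
#' @param stride_ns ns per frame.
#' @return data.frame(lag_frames, lag_ns, index, timescale_ns, converged).
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 3,
                               mode = "mle_reversible", stride_ns = 1) {
  if (length(lags) < 2) stop("need >= 2 lags")
  lags <- sort(lags)
  rows <- list()
  for (lg in lags) {
    m <- estimate_msm(dtrajs, lg, mode = mode, stride_ns = stride_ns)
    lam <- msm_eigenvalues(m, n_timescales + 1)[-1]
    lam <- c(lam, rep(NA_real_, max(0, n_timescales - length(lam))))[1:n_timescales]
    ts <- implied_timescale_values(lam, lg) * stride_ns
    rows[[length(rows) + 1]] <- data.frame(lag_frames = lg,
                                           lag_ns = lg * stride_ns,
                                           index = seq_len(n_timescales),
                                           eigenvalue = lam,
                                           timescale_ns = ts,
                                           nondecaying = !is.na(lam) & lam >= 1)
  }
  out <- do.call(rbind, rows)
  out$converged <- FALSE
  for (i in unique(out$index)) {
    sel <- which(out$index == i)
    ts <- out$timescale_ns[sel]
    rel <- c(NA, abs(diff(ts)) / abs(ts[-length(ts)]))
    out$converged[sel] <- !is.na(rel) & rel < 0.10
  }
  out
}

#' Chapman-Kolmogorov test
#'
#' Compares metastable-set occupation probabilities predicted by propagating
#' the lag-tau model, T(tau)^k, against models re-estimated at k * tau, for
#' each factor k. Uncertainty bands come from bootstrap resampling of the
#' trajectories (single trajectories are split into contiguous blocks first).
#'
#' @param dtrajs discrete trajectories.
#' @param lag base lag (frames).
#' @param n_metastable number of PCCA++ sets to project on.
#' @param factors multiples of the lag to test (>= 1; k = 1 is exact by
#'   construction).
#' @param n_boot bootstrap replicates for the band (default 50).
#' @param conf band coverage (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame(factor, set_from, set_to, predicted, estimated,
#'   lower, upper) plus attribute `max_deviation`.
#' @export
ck_test <- function(dtrajs, lag, n_metastable = 3, factors = 1:5,
                    n_boot = 50, conf = 0.95, seed = 2022) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (length(dtrajs) == 1 && length(dtrajs[[1]]) >= 8 * lag * max(factors)) {
    # split one long trajectory into blocks so the bootstrap has units
    x <- dtrajs[[1]]
    nb <- 10
    bl <- split(x, cut(seq_along(x), nb, labels = FALSE))
    dtrajs <- unname(bl)
  }
  base <- estimate_msm(dtrajs, lag)
  part <- pcca_coarse_grain(base, n_metastable)
  project_dtraj <- function(dt) {
    pos <- match(dt, base$active_set)
    st <- part$assignment[pos]
    st[is.na(st)] <- 1L
    st
  }
  proj <- lapply(dtrajs, project_dtraj)
  est_at <- function(trajs, k) {
    C <- count_transitions(trajs, k * lag)
    if (nrow(C) < n_metastable) {
      C2 <- matrix(0, n_metastable, n_metastable)
      C2[seq_len(nrow(C)), seq_len(ncol(C))] <- C
      C <- C2
    }
    C / pmax(rowSums(C), 1)
  }
  rows <- list()
  max_dev <- 0
  set.seed(seed)
  bidx <- lapply(seq_len(n_boot), function(b)
    sample.int(length(proj), length(proj), replace = TRUE))
  Pbase <- est_at(proj, 1)
  for (k in factors) {
    if (all(vapply(dtrajs, length, 1L) <= k * lag)) {
      warning("insufficient data at factor ", k, "; truncated")
      break
    }
    Ppred <- Pbase
    if (k > 1) for (j in seq_len(k - 1)) Ppred <- Ppred %*% Pbase
    Pest <- est_at(proj, k)
    bootP <- array(NA_real_, c(n_boot, n_metastable, n_metastable))
    for (b in seq_len(n_boot)) bootP[b, , ] <- est_at(proj[bidx[[b]]], k)
    lo <- apply(bootP, c(2, 3), quantile, probs = (1 - conf) / 2, na.rm = TRUE)
    hi <- apply(bootP, c(2, 3), quantile, probs = 1 - (1 - conf) / 2, na.rm = TRUE)
    for (a in seq_len(n_metastable)) for (b2 in seq_len(n_metastable)) {
      rows[[length(rows) + 1]] <- data.frame(
        factor = k, set_from = a, set_to = b2,
        predicted = Ppred[a, b2], estimated = Pest[a, b2],
        lower = lo[a, b2], upper = hi[a, b2])
      max_dev <- max(max_dev, abs(Ppred[a, b2] - Pest[a, b2]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "max_deviation") <- max_dev
  out
}

#' Does the model pass the Chapman-Kolmogorov test?
#'
#' TRUE when every predicted set-occupation probability lies inside the
#' bootstrap band of the re-estimated one (with a small absolute slack for
#' degenerate bands).
#'
#' @param ck output of [ck_test()].
#' @param slack absolute tolerance added to the band (default 0.02).
#' @export
ck_passes <- function(ck, slack = 0.02) {
  all(ck$predicted >= ck$lower - slack & ck$predicted <= ck$upper + slack)
}

#' PCCA++ coarse-graining into metastable states
#'
#' Spectral clustering of a reversible transition matrix: the top
#' `n_states` right eigenvectors span a simplex whose vertices are located
#' with the inner simplex algorithm; memberships are the barycentric
#' coordinates (clipped to [0, 1] and renormalized), crisp assignments take
#' the argmax, and the equilibrium probability of each metastable state is
#' the summed stationary mass of its crisp members.
#'
#' @param msm a `restime_msm` (reversible).
#' @param n_states number of metastable states (default 3).
#' @return object of class `restime_pcca`: membership matrix `chi`
#'   (microstate x state), `assignment`, and equilibrium probabilities `pi`.
#' @export
pcca_coarse_grain <- function(msm, n_states = 3) {
  if (msm$mode == "nonreversible")
    stop("PCCA++ needs a reversible transition matrix")
  k <- nrow(msm$T)
  if (n_states > k) stop("n_states exceeds number of microstates")
  eg <- msm_eigenvectors(msm, n_states)
  if (n_states >= 2 &&
      any(abs(diff(eg$values)) < 1e-10))
    warning("nearly degenerate eigenvalues; memberships may be ambiguous")
  X <- eg$vectors
  X[, 1] <- 1
  chi <- pcca_isa(X)
  chi <- pmin(pmax(chi, 0), 1)
  chi <- chi / rowSums(chi)
  assignment <- max.col(chi, ties.method = "first")
  pi_states <- vapply(seq_len(n_states), function(s)
    sum(msm$mu[assignment == s]), numeric(1))
  structure(list(chi = chi, assignment = assignment, pi = pi_states,
                 n_states = n_states, mu = msm$mu),
            class = "restime_pcca")
}

# inner simplex algorithm: find n rows of X forming the most spread simplex,
# then express all rows in barycentric coordinates of those vertices
pcca_isa <- function(X) {
  m <- ncol(X)
  ind <- integer(m)
  Xw <- X
  ind[1] <- which.max(rowSums(Xw^2))
  Xw <- sweep(Xw, 2, Xw[ind[1], ])
  if (m > 1) for (j in 2:m) {
    norms <- sqrt(rowSums(Xw^2))
    ind[j] <- which.max(norms)
    v <- Xw[ind[j], ]
    nv <- sum(v * v)
    if (nv > 1e-14) Xw <- Xw - (Xw %*% v) %*% t(v) / nv
  }
  A <- solve(X[ind, , drop = FALSE])
  X %*% A
}

#' @export
print.restime_pcca <- function(x, ...) {
  cat("PCCA++ partition:", x$n_states, "metastable states, pi =",
      paste(round(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Representative frames for each metastable state
#'
#' For each metastable state, the `n_per_state` most populated member
#' microstates are taken (by stationary mass) and for each of them the frame
#' nearest its center in projected space is chosen. Fully deterministic;
#' states with fewer member microstates than requested return all of them
#' with a warning.
#'
#' @param partition a `restime_pcca`.
#' @param projected n x d projected coordinates.
#' @param clustering output of [cluster_microstates()].
#' @param n_per_state frames per state (default 3).
#' @return list of integer frame-id vectors, one per state.
#' @export
select_representatives <- function(partition, projected, clustering,
                                   n_per_state = 3) {
  if (n_per_state < 1) stop("n_per_state must be >= 1")
  Y <- as.matrix(projected)
  out <- vector("list", partition$n_states)
  for (s in seq_len(partition$n_states)) {
    micro <- which(partition$assignment == s)
    if (length(micro) < n_per_state)
      warning("state ", s, " has only ", length(micro), " microstates")
    micro <- micro[order(partition$mu[micro], decreasing = TRUE)]
    micro <- head(micro, n_per_state)
    out[[s]] <- vapply(micro, function(mc) {
      frames <- which(clustering$assignments == mc)
      d2 <- rowSums(sweep(Y[frames, , drop = FALSE], 2,
                          clustering$centers[mc, ])^2)
      frames[which.min(d2)]
    }, integer(1))
  }
  out
}

#' Fit the full Markov-state-model stack
#'
#' Convenience front end running TICA, k-means microstate clustering,
#' reversible transition-matrix estimation and PCCA++ coarse-graining in one
#' call, with the defaults used throughout the package (lag 40 frames at a
#' 1 ns stride, 2 independent components, sqrt(n) microstates, 3 metastable
#' states). Reproducible bit-for-bit for a fixed seed.
#'
#' @param features feature matrix or `restime_features`.
#' @param lag_ns model lag in ns.
#' @param stride_ns ns per frame.
#' @param n_tica retained independent components.
#' @param k microstate count (default round(sqrt(n))).
#' @param n_states metastable states.
#' @param mode estimator mode.
#' @param seed seed for clustering (and bayesian sampling).
#' @return object of class `restime_msm_fit` bundling the TICA model,
#'   clustering, `restime_msm` and `restime_pcca`.
#' @export
fit_msm <- function(features, lag_ns = 40, stride_ns = 1, n_tica = 2,
                    k = NULL, n_states = 3, mode = "mle_reversible",
                    seed = 2022) {
  lag <- max(1L, round(lag_ns / stride_ns))
  tica <- fit_tica(features, lag = lag, n_dims = n_tica)
  cl <- cluster_microstates(tica$Y, k = k, seed = seed)
  msm <- estimate_msm(cl$assignments, lag = lag, mode = mode,
                      stride_ns = stride_ns, seed = seed)
  pcca <- pcca_coarse_grain(msm, n_states)
  # per-frame metastable labels (frames outside the active set get NA)
  pos <- match(cl$assignments, msm$active_set)
  frame_states <- ifelse(is.na(pos), NA_integer_, pcca$assignment[pos])
  structure(list(tica = tica, clustering = cl, msm = msm, pcca = pcca,
                 frame_states = frame_states, lag_ns = lag_ns,
                 stride_ns = stride_ns, seed = seed),
            class = "restime_msm_fit")
}

#' @export
print.restime_msm_fit <- function(x, ...) {
  cat("MSM fit: lag", x$lag_ns, "ns,", x$clustering$k, "microstates,",
      x$pcca$n_states, "metastable states\n")
  cat("  equilibrium probabilities:",
      paste(round(x$pcca$pi, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.restime_msm_fit <- function(object, ...) {
  print(object)
  summary(object$msm)
}
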