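# Featurization and kinetic scoring: backbone torsions, VAMP-2, TICA.

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone-torsion feature matrix
#'
#' Computes phi/psi backbone dihedrals for every residue that has complete
#' flanking atoms and encodes each angle as a (cos, sin) pair so the
#' periodicity at +/-180 degrees is respected. Residues in
#' `residue_exclusions` are omitted; torsions spanning a chain break
#' (C-N distance > 2.5 Angstrom) are dropped with a warning.
#'
#' @param traj a `restime_trajectory` of a protein with >= 3 residues.
#' @param residue_exclusions residue numbers to leave out.
#' @return object of class `restime_features`: list with `X`
#'   (n_frames x n_features), `labels`, and `stride_ns`.
#' @export
featurize_backbone_torsions <- function(traj, residue_exclusions = NULL) {
  s <- traj$structure
  a <- s$atoms
  resk <- unique(a[a$backbone, c("chain", "resno")])
  resk <- resk[order(resk$chain, resk$resno), ]
  if (nrow(resk) < 3) stop("need a protein chain with >= 3 residues")
  idx_of <- function(ch, rn, nm) {
    i <- which(a$chain == ch & a$resno == rn & a$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  quads <- list(); labels <- character()
  for (r in seq_len(nrow(resk))) {
    ch <- resk$chain[r]; rn <- resk$resno[r]
    if (rn %in% residue_exclusions) next
    iN <- idx_of(ch, rn, "N"); iCA <- idx_of(ch, rn, "CA"); iC <- idx_of(ch, rn, "C")
    iCp <- idx_of(ch, rn - 1, "C"); iNn <- idx_of(ch, rn + 1, "N")
    if (!any(is.na(c(iCp, iN, iCA, iC)))) {
      quads[[length(quads) + 1]] <- c(iCp, iN, iCA, iC)
      labels <- c(labels, paste0("phi_", ch, rn))
    }
    if (!any(is.na(c(iN, iCA, iC, iNn)))) {
      quads[[length(quads) + 1]] <- c(iN, iCA, iC, iNn)
      labels <- c(labels, paste0("psi_", ch, rn))
    }
  }
  if (!length(quads)) stop("no complete backbone torsions found")
  # drop torsions across chain breaks, judged on the first frame
  xyz0 <- frame_coords(traj, 1)
  keep <- vapply(quads, function(q) {
    ok <- TRUE
    for (k in 1:3) ok <- ok && sqrt(sum((xyz0[q[k], ] - xyz0[q[k + 1], ])^2)) <= 2.5
    ok
  }, logical(1))
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " torsion(s) spanning a chain break")
    quads <- quads[keep]; labels <- labels[keep]
  }
  nf <- n_frames(traj)
  X <- matrix(NA_real_, nf, 2 * length(quads))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    ang <- vapply(quads, function(q)
      dihedral_deg(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ]),
      numeric(1)) * pi / 180
    X[f, ] <- as.vector(rbind(cos(ang), sin(ang)))
  }
  colnames(X) <- as.vector(rbind(paste0("cos_", labels), paste0("sin_", labels)))
  structure(list(X = X, labels = labels, stride_ns = traj$stride_ns),
            class = "restime_features")
}

feature_matrix <- function(features) {
  if (inherits(features, "restime_features")) features$X else as.matrix(features)
}

# instantaneous and time-lagged covariances on mean-centered data, using the
# symmetrized (reversible) estimate
lagged_covariances <- function(X, lag, symmetrize = TRUE) {
  n <- nrow(X)
  if (n <= lag) stop("n_frames must exceed the lag")
  X0 <- X[1:(n - lag), , drop = FALSE]
  Xt <- X[(1 + lag):n, , drop = FALSE]
  if (symmetrize) {
    mu <- colMeans(rbind(X0, Xt))
    X0 <- sweep(X0, 2, mu); Xt <- sweep(Xt, 2, mu)
    C0 <- (crossprod(X0) + crossprod(Xt)) / (2 * (n - lag))
    Ct <- (crossprod(X0, Xt) + crossprod(Xt, X0)) / (2 * (n - lag))
  } else {
    mu <- colMeans(X0)
    X0 <- sweep(X0, 2, mu); Xt <- sweep(Xt, 2, colMeans(X[(1 + lag):n, , drop = FALSE]))
    C0 <- crossprod(X0) / (n - lag)
    Ct <- crossprod(X0, Xt) / (n - lag)
  }
  list(C0 = C0, Ct = Ct, mean = mu)
}

# inverse square root of a symmetric PSD matrix, dropping tiny directions;
# applies a ridge when the matrix is numerically singular
inv_sqrt_psd <- function(C, epsilon = 1e-10, ridge = 1e-12) {
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- ev$values
  if (all(lam < epsilon)) stop("covariance matrix is numerically zero")
  if (min(lam) < epsilon) lam <- lam + ridge
  keep <- lam > epsilon * max(lam)
  list(W = ev$vectors[, keep, drop = FALSE] %*%
         diag(1 / sqrt(lam[keep]), sum(keep)),
       rank = sum(keep))
}

#' VAMP-2 score of a featurization
#'
#' Sum of squared singular values of the half-weighted time-lagged covariance
#' operator C00^{-1/2} C0t Ctt^{-1/2}, truncated at `n_components`, with the
#' constant singular function included, so the score is always >= 1 and iid
#' noise scores close to 1.
#'
#' @param features feature matrix or `restime_features`.
#' @param lag lag time in frames.
#' @param n_components number of singular components kept (including the
#'   constant).
#' @return numeric score.
#' @export
vamp2_score <- function(features, lag, n_components = 10) {
  X <- feature_matrix(features)
  n <- nrow(X)
  if (n <= lag) stop("n_frames must exceed the lag")
  X0 <- sweep(X[1:(n - lag), , drop = FALSE], 2,
              colMeans(X[1:(n - lag), , drop = FALSE]))
  Xt <- sweep(X[(1 + lag):n, , drop = FALSE], 2,
              colMeans(X[(1 + lag):n, , drop = FALSE]))
  C00 <- crossprod(X0) / (n - lag)
  Ctt <- crossprod(Xt) / (n - lag)
  C0t <- crossprod(X0, Xt) / (n - lag)
  W0 <- inv_sqrt_psd(C00)$W
  Wt <- inv_sqrt_psd(Ctt)$W
  s <- svd(t(W0) %*% C0t %*% Wt)$d
  s <- pmin(s, 1)
  k <- min(n_components - 1, length(s))
  if (k < 1) return(1)
  1 + sum(s[seq_len(k)]^2)
}

#' Time-lagged independent component analysis
#'
#' Solves the symmetrized generalized eigenproblem of the time-lagged versus
#' instantaneous covariance and projects the data on the `n_dims` slowest
#' components. Rank-deficient covariances are ridge-regularized.
#'
#' @param features feature matrix or `restime_features`.
#' @param lag lag in frames (default 40, one frame per ns).
#' @param n_dims retained independent components (default 2).
#' @return object of class `restime_tica`: eigenvalues, loadings, means, and
#'   the projected coordinates `Y` (n_frames x n_dims).
#' @export
fit_tica <- function(features, lag = 40, n_dims = 2) {
  X <- feature_matrix(features)
  if (n_dims < 1) stop("n_dims must be >= 1")
  cv <- lagged_covariances(X, lag, symmetrize = TRUE)
  iw <- inv_sqrt_psd(cv$C0)
  W <- iw$W
  M <- t(W) %*% cv$Ct %*% W
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(ev$values, decreasing = TRUE)
  lam <- pmin(ev$values[ord], 1)
  vecs <- W %*% ev$vectors[, ord, drop = FALSE]
  nd <- min(n_dims, iw$rank)
  if (nd < n_dims) warning("rank ", iw$rank, " < requested n_dims; truncated")
  Y <- sweep(X, 2, cv$mean) %*% vecs[, seq_len(nd), drop = FALSE]
  structure(list(lag = lag, eigenvalues = lam, loadings = vecs,
                 means = cv$mean, n_dims = nd, Y = Y),
            class = "restime_tica")
}

#' Project new data on a fitted TICA model
#' @param object a `restime_tica`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
predict.restime_tica <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  sweep(X, 2, object$means) %*%
    object$loadings[, seq_len(object$n_dims), drop = FALSE]
}

#' @export
print.restime_tica <- function(x, ...) {
  cat("TICA: lag", x$lag, "frames,", x$n_dims, "dims retained; eigenvalues",
      paste(round(head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}
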