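# Metadynamics dissociation analysis: the unbinding collective variable, the
# 15-Angstrom dissociation rule (inclusive - dissociated when the distance is
# reached), and the per-state count table.

.CV_SITE_RESIDUES <- c(38, 51, 75, 84, 106, 109)

#' Ligand-binding-site distance collective variable
#'
#' Euclidean distance between the mass-weighted centroid of the ligand atoms
#' and that of all atoms of the binding-site residues (defaults: Val38,
#' Ala51, Leu75, Ile84, Thr106, Met109).
#'
#' @param frame a `restime_structure`.
#' @param ligand_idx ligand atom indices (default: annotated ligand).
#' @param site_residues residue numbers of the binding site.
#' @return distance in Angstrom.
#' @export
compute_cv <- function(frame, ligand_idx = atom_select(frame, ligand = TRUE),
                       site_residues = .CV_SITE_RESIDUES) {
  a <- frame$atoms
  xyz <- coords(frame)
  missing <- setdiff(site_residues, a$resno)
  if (length(missing)) stop("missing binding-site residue(s): ",
                            paste(missing, collapse = ", "))
  site_idx <- which(a$resno %in% site_residues & !a$ligand & !a$water_o &
                      !a$water_h)
  com <- function(idx) {
    w <- mass_for(a$element[idx])
    colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
  }
  sqrt(sum((com(ligand_idx) - com(site_idx))^2))
}

#' Read a metadynamics CV trace
#'
#' Two-column whitespace- or comma-separated (time_ns, cv_angstrom) files
#' with `#` comments; one non-numeric header line is tolerated.
#'
#' @param path trace file.
#' @return data.frame(t_ns, cv) of class `restime_cvtrace`.
#' @export
read_cv_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parse1 <- function(ln) suppressWarnings(as.numeric(
    strsplit(trimws(ln), "[,[:space:]]+")[[1]]))
  vals <- lapply(lines, parse1)
  bad <- vapply(vals, function(v) any(is.na(v[1:2])), logical(1))
  if (any(bad[-1])) stop("unparseable trace line: ", which(bad[-1])[1] + 1)
  if (bad[1]) vals <- vals[-1]
  m <- t(vapply(vals, function(v) v[1:2], numeric(2)))
  out <- data.frame(t_ns = m[, 1], cv = m[, 2])
  if (any(diff(out$t_ns) <= 0)) stop("trace times must be strictly increasing")
  if (any(out$cv < 0)) stop("negative CV value in trace")
  class(out) <- c("restime_cvtrace", "data.frame")
  out
}

#' Classify a CV trace as dissociated or bound
#'
#' Dissociated if and only if the maximum CV reaches the threshold
#' (inclusive, default 15 Angstrom).
#'
#' @param trace data.frame with a `cv` column, or a numeric CV vector.
#' @param threshold dissociation distance (default 15.0).
#' @return "dissociated" or "bound".
#' @export
classify_dissociation <- function(trace, threshold = 15.0) {
  cv <- if (is.data.frame(trace)) trace$cv else as.numeric(trace)
  if (!length(cv)) stop("empty CV trace")
  if (max(cv) >= threshold) "dissociated" else "bound"
}

#' Dissociation count table
#'
#' Per start-state dissociated/bound counts with compound totals, in the
#' layout of a published metadynamics unbinding table.
#'
#' @param traces data.frame with columns `compound`, `state`, and either
#'   `max_cv` or a list-column `cv` of traces.
#' @param threshold dissociation distance (default 15.0).
#' @param expected_replicas warn when a state group deviates from this count
#'   (default NULL = no check; published protocol used 60 per state).
#' @return data.frame(compound, state, n_dissociated, n_bound) plus a totals
#'   row per compound, class `restime_dissociation`.
#' @export
build_dissociation_table <- function(traces, threshold = 15.0,
                                     expected_replicas = NULL) {
  stopifnot(all(c("compound", "state") %in% names(traces)))
  if (!"max_cv" %in% names(traces)) {
    traces$max_cv <- vapply(traces$cv, function(tr)
      max(if (is.data.frame(tr)) tr$cv else tr), numeric(1))
  }
  traces$dissociated <- traces$max_cv >= threshold
  sp <- split(traces, list(traces$compound, traces$state), drop = TRUE)
  rows <- do.call(rbind, lapply(sp, function(d) {
    if (!nrow(d)) stop("empty trace group")
    data.frame(compound = d$compound[1], state = d$state[1],
               n_dissociated = sum(d$dissociated),
               n_bound = sum(!d$dissociated))
  }))
  rows <- rows[order(rows$compound, rows$state), ]
  if (!is.null(expected_replicas)) {
    n <- rows$n_dissociated + rows$n_bound
    if (any(n != expected_replicas))
      warning("replica count differs from expected ", expected_replicas,
              " in state(s): ",
              paste(rows$state[n != expected_replicas], collapse = ", "))
  }
  totals <- do.call(rbind, lapply(split(rows, rows$compound), function(d)
    data.frame(compound = d$compound[1], state = "total",
               n_dissociated = sum(d$n_dissociated),
               n_bound = sum(d$n_bound))))
  out <- rbind(rows, totals)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("restime_dissociation", "data.frame")
  out
}
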