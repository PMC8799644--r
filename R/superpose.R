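# Rigid-body superposition and cross-structure distance measurements.

# Default reference frame for cross-structure measurements: backbone atoms of
# residues common to both structures, excluding the activation loop (170-185)
# and the glycine-rich loop (30-38), so loop displacement is measured against
# the stable kinase core.
.DEFAULT_EXCLUDE_LOOPS <- c(30:38, 170:185)

match_selection <- function(mobile, reference, sel_mobile, sel_reference) {
  key <- function(s, idx) with(s$atoms[idx, ], paste(chain, resno, name))
  km <- key(mobile, sel_mobile)
  kr <- key(reference, sel_reference)
  common <- intersect(km, kr)
  if (!length(common)) stop("empty or mismatched superposition selection")
  list(mobile = sel_mobile[match(common, km)],
       reference = sel_reference[match(common, kr)])
}

#' Superpose one structure onto another
#'
#' Least-squares rigid-body fit over a selection matched 1:1 by
#' (chain, residue number, atom name); all atoms of `mobile` are transformed.
#'
#' @param mobile,reference `restime_structure`s.
#' @param sel_mobile,sel_reference atom indices defining the fit selection
#'   (defaults: all backbone atoms).
#' @return list with the transformed `structure` and the fit `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference,
                      sel_mobile = atom_select(mobile, backbone = TRUE),
                      sel_reference = atom_select(reference, backbone = TRUE)) {
  mm <- match_selection(mobile, reference, sel_mobile, sel_reference)
  fixed <- as.vector(t(coords(reference)))
  mob <- as.vector(t(coords(mobile)))
  xyz_inds <- function(idx) as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  fitted <- bio3d::fit.xyz(fixed, mob,
                           fixed.inds = xyz_inds(mm$reference),
                           mobile.inds = xyz_inds(mm$mobile))
  out <- set_coords(mobile, matrix(fitted, ncol = 3, byrow = TRUE))
  d <- coords(out)[mm$mobile, , drop = FALSE] -
    coords(reference)[mm$reference, , drop = FALSE]
  list(structure = out, rmsd = sqrt(mean(rowSums(d * d))))
}

default_core_selection <- function(s, exclude_resno = .DEFAULT_EXCLUDE_LOOPS) {
  atom_select(s, backbone = TRUE, exclude_resno = exclude_resno)
}

#' Distance between the CA atoms of a residue in two structures
#'
#' Superposes `b` onto `a` over the given selection (default: shared backbone
#' excluding the A-loop, residues 170-185, and G-loop, residues 30-38) and
#' returns the Euclidean CA-CA distance for the residue. `measure_ca_distance_sets`
#' averages the measurement over all cross pairs of two structure sets.
#'
#' @param a,b `restime_structure`s.
#' @param resno residue number (PDB numbering).
#' @param sel_a,sel_b superposition selections.
#' @return distance in Angstrom.
#' @export
measure_ca_distance <- function(a, b, resno,
                                sel_a = default_core_selection(a),
                                sel_b = default_core_selection(b)) {
  ca <- function(s) {
    i <- atom_select(s, resno = resno, name = "CA")
    if (!length(i)) stop("residue ", resno, " has no CA atom")
    coords(s)[i[1], ]
  }
  fit <- superpose(b, a, sel_b, sel_a)
  sqrt(sum((ca(a) - ca(fit$structure))^2))
}

#' @rdname measure_ca_distance
#' @param set_a,set_b lists of structures; every cross pair is measured.
#' @param exclude_resno residues excluded from the superposition core.
#' @export
measure_ca_distance_sets <- function(set_a, set_b, resno,
                                     exclude_resno = .DEFAULT_EXCLUDE_LOOPS) {
  core <- function(s) default_core_selection(s, exclude_resno)
  vals <- unlist(lapply(set_a, function(sa)
    vapply(set_b, function(sb)
      measure_ca_distance(sa, sb, resno, core(sa), core(sb)), numeric(1))))
  mean(vals)
}
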