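# Per-residue sidechain solvent-exposure traces.
#
# A residue is exposed in a frame when at least one water molecule lies
# within the cutoff (default 3 Angstrom) of its sidechain. Waters are counted
# by molecule from their oxygen position; the sidechain is its non-backbone
# heavy atoms. Both conventions are arguments because published monitoring
# scripts differ.

#' Count water molecules near a residue sidechain
#'
#' @param frame a `restime_structure`.
#' @param resno residue number.
#' @param chain chain id (default first chain carrying the residue).
#' @param cutoff distance cutoff in Angstrom, inclusive (default 3.0).
#' @param heavy_only use only sidechain heavy atoms (default TRUE).
#' @return number of distinct water molecules whose oxygen lies within
#'   `cutoff` of any sidechain atom.
#' @export
count_waters_near_sidechain <- function(frame, resno, chain = NULL,
                                        cutoff = 3.0, heavy_only = TRUE) {
  a <- frame$atoms
  sel <- atom_select(frame, resno = resno, chain = chain, sidechain = TRUE)
  if (heavy_only) sel <- sel[a$element[sel] != "H"]
  if (!length(sel)) stop("residue ", resno, " has no sidechain atoms")
  wo <- which(a$water_o)
  if (!length(wo)) return(0L)
  xyz <- coords(frame)
  d <- min_dist_to_set(xyz[wo, , drop = FALSE], xyz[sel, , drop = FALSE])
  sum(d <= cutoff)
}

#' Solvent-exposure trace for residues along a trajectory
#'
#' @param traj a `restime_trajectory`.
#' @param residues residue numbers to monitor.
#' @param cutoff,heavy_only see [count_waters_near_sidechain()].
#' @return data.frame(resno, frame, water_count, exposed) with one row per
#'   residue and frame; `exposed` is `water_count >= 1`.
#' @export
exposure_trace <- function(traj, residues, cutoff = 3.0, heavy_only = TRUE) {
  rows <- list()
  for (res in residues) {
    wc <- vapply(seq_len(n_frames(traj)), function(f)
      count_waters_near_sidechain(frame_structure(traj, f), res,
                                  cutoff = cutoff, heavy_only = heavy_only),
      integer(1))
    rows[[length(rows) + 1]] <- data.frame(resno = res,
                                           frame = seq_along(wc),
                                           water_count = wc,
                                           exposed = wc >= 1L)
  }
  do.call(rbind, rows)
}

#' Summarise an exposure trace
#'
#' @param trace output of [exposure_trace()].
#' @return data.frame(resno, fraction_exposed, median_count).
#' @export
summarise_exposure <- function(trace) {
  sp <- split(trace, trace$resno)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(resno = d$resno[1],
               fraction_exposed = mean(d$exposed),
               median_count = median(d$water_count))))
  rownames(out) <- NULL
  out
}
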