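# Frame-wise geometric interaction detection and frequency tabulation.
#
# All cutoffs are inclusive at equality. Criteria defaults follow the
# simulation-interaction-diagram convention: the 2.5 A hydrogen-bond distance
# is hydrogen-to-acceptor (a 2.5 A heavy-heavy distance would be physically
# impossible).

#' Interaction criteria
#'
#' Geometric thresholds for the five interaction detectors. Defaults:
#' H-bonds 2.5 A (hydrogen to acceptor) with donor angle >= 120 deg and
#' acceptor angle >= 90 deg; pi-cation 4.5 A charged-center to ring centroid;
#' pi-pi face-to-face centroid <= 4.4 A at interplanar angle <= 30 deg and
#' edge-to-face centroid <= 5.5 A at 60-120 deg; water bridges use relaxed
#' H-bond criteria 2.8 A / >= 110 deg / >= 90 deg; salt bridges 4.0 A between
#' charged-group nitrogen/oxygen heavy atoms.
#'
#' @param hbond_distance,hbond_donor_angle_min,hbond_acceptor_angle_min H-bond thresholds.
#' @param pication_distance pi-cation distance cutoff (Angstrom).
#' @param pipi_f2f_centroid_max,pipi_f2f_angle_max face-to-face thresholds.
#' @param pipi_e2f_centroid_max,pipi_e2f_angle_window edge-to-face thresholds.
#' @param waterbridge_distance,waterbridge_donor_angle_min,waterbridge_acceptor_angle_min water-bridge thresholds.
#' @param saltbridge_distance salt-bridge N/O pair cutoff (Angstrom).
#' @export
interaction_criteria <- function(hbond_distance = 2.5,
                                 hbond_donor_angle_min = 120,
                                 hbond_acceptor_angle_min = 90,
                                 pication_distance = 4.5,
                                 pipi_f2f_centroid_max = 4.4,
                                 pipi_f2f_angle_max = 30,
                                 pipi_e2f_centroid_max = 5.5,
                                 pipi_e2f_angle_window = c(60, 120),
                                 waterbridge_distance = 2.8,
                                 waterbridge_donor_angle_min = 110,
                                 waterbridge_acceptor_angle_min = 90,
                                 saltbridge_distance = 4.0) {
  cr <- list(hbond_distance = hbond_distance,
             hbond_donor_angle_min = hbond_donor_angle_min,
             hbond_acceptor_angle_min = hbond_acceptor_angle_min,
             pication_distance = pication_distance,
             pipi_f2f_centroid_max = pipi_f2f_centroid_max,
             pipi_f2f_angle_max = pipi_f2f_angle_max,
             pipi_e2f_centroid_max = pipi_e2f_centroid_max,
             pipi_e2f_angle_window = pipi_e2f_angle_window,
             waterbridge_distance = waterbridge_distance,
             waterbridge_donor_angle_min = waterbridge_donor_angle_min,
             waterbridge_acceptor_angle_min = waterbridge_acceptor_angle_min,
             saltbridge_distance = saltbridge_distance)
  dpos <- unlist(cr[grepl("distance|centroid", names(cr))])
  if (any(dpos <= 0)) stop("all distance cutoffs must be > 0")
  angs <- c(hbond_donor_angle_min, hbond_acceptor_angle_min,
            pipi_f2f_angle_max, pipi_e2f_angle_window,
            waterbridge_donor_angle_min, waterbridge_acceptor_angle_min)
  if (any(angs < 0 | angs > 180)) stop("angle bounds must be in [0, 180]")
  structure(cr, class = "restime_criteria")
}

atom_label <- function(s, i) {
  a <- s$atoms
  paste0(a$resname[i], a$resno[i], ":", a$name[i])
}

group_label <- function(s, i) {
  a <- s$atoms
  paste0(a$resname[i], a$resno[i])
}

empty_events <- function() {
  data.frame(kind = character(), partner_a = character(),
             partner_b = character(), bridging_water = character(),
             stringsAsFactors = FALSE)
}

event_df <- function(kind, pa, pb, water = NA_character_) {
  if (!length(pa)) return(empty_events())
  data.frame(kind = kind, partner_a = pa, partner_b = pb,
             bridging_water = water, stringsAsFactors = FALSE)
}

# heavy covalent neighbors of acceptor i (same residue, <= 1.8 A)
acceptor_neighbors <- function(s, i, xyz) {
  a <- s$atoms
  cand <- which(a$chain == a$chain[i] & a$resno == a$resno[i] &
                  a$resname == a$resname[i] & a$element != "H")
  cand <- setdiff(cand, i)
  if (!length(cand)) return(integer())
  dd <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
  cand[dd <= 1.8]
}

hbond_geometry_ok <- function(s, xyz, h, acc, dmax, ang_donor, ang_acc) {
  don <- s$atoms$hydrogen_of[h]
  if (is.na(don)) return(FALSE)
  dha <- sqrt(sum((xyz[h, ] - xyz[acc, ])^2))
  if (dha > dmax + 1e-9) return(FALSE)
  if (angle_deg(xyz[don, ], xyz[h, ], xyz[acc, ]) < ang_donor - 1e-9)
    return(FALSE)
  nb <- acceptor_neighbors(s, acc, xyz)
  if (!length(nb)) return(TRUE)
  any(vapply(nb, function(x)
    angle_deg(xyz[h, ], xyz[acc, ], xyz[x, ]) >= ang_acc - 1e-9, logical(1)))
}

#' Detect hydrogen bonds in a frame
#'
#' An event is recorded for each (donor hydrogen, acceptor) pair with
#' hydrogen-acceptor distance <= `hbond_distance`, donor angle D-H...A >=
#' `hbond_donor_angle_min`, and angle H...A-X >= `hbond_acceptor_angle_min`
#' for at least one heavy covalent neighbor X of the acceptor. Events are
#' labelled by the donor heavy atom and the acceptor.
#'
#' @param frame a `restime_structure`.
#' @param criteria an [interaction_criteria()] object.
#' @param donors,acceptors optional atom-index restrictions.
#' @return data.frame of events.
#' @export
detect_hbonds <- function(frame, criteria = interaction_criteria(),
                          donors = NULL, acceptors = NULL) {
  a <- frame$atoms
  xyz <- coords(frame)
  dset <- if (is.null(donors)) which(a$donor) else intersect(donors, which(a$donor))
  aset <- if (is.null(acceptors)) which(a$acceptor) else intersect(acceptors, which(a$acceptor))
  lonely <- if (is.null(donors)) integer() else setdiff(donors, which(a$donor))
  lonely <- lonely[a$element[lonely] %in% c("N", "O")]
  if (length(lonely))
    warning("donor atom(s) without attached hydrogen skipped: ",
            paste(atom_label(frame, lonely), collapse = ", "))
  hyd <- which(a$hydrogen & a$hydrogen_of %in% dset)
  out <- list()
  for (h in hyd) {
    for (acc in aset) {
      if (acc == a$hydrogen_of[h]) next
      if (hbond_geometry_ok(frame, xyz, h, acc, criteria$hbond_distance,
                            criteria$hbond_donor_angle_min,
                            criteria$hbond_acceptor_angle_min))
        out[[length(out) + 1]] <- event_df("hbond",
                                           atom_label(frame, a$hydrogen_of[h]),
                                           atom_label(frame, acc))
    }
  }
  if (!length(out)) empty_events() else do.call(rbind, out)
}

ring_centroid_normal <- function(frame, idx) {
  xyz <- coords(frame)[idx, , drop = FALSE]
  c0 <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, c0))
  list(centroid = c0, normal = sv$v[, 3])
}

#' Detect pi-cation interactions in a frame
#'
#' Event when the distance between a positively charged center atom and an
#' aromatic ring centroid is <= `pication_distance`.
#'
#' @inheritParams detect_hbonds
#' @export
detect_pication <- function(frame, criteria = interaction_criteria()) {
  pos <- which(frame$atoms$positive)
  if (!length(pos) || !length(frame$rings)) return(empty_events())
  out <- list()
  for (rid in names(frame$rings)) {
    cn <- ring_centroid_normal(frame, frame$rings[[rid]])
    for (p in pos) {
      d <- sqrt(sum((coords(frame)[p, ] - cn$centroid)^2))
      if (d <= criteria$pication_distance + 1e-9)
        out[[length(out) + 1]] <- event_df("pication",
                                           atom_label(frame, p), rid)
    }
  }
  if (!length(out)) empty_events() else do.call(rbind, out)
}

#' Detect pi-pi stacking in a frame
#'
#' Face-to-face when the centroid distance is <= `pipi_f2f_centroid_max` with
#' interplanar angle <= `pipi_f2f_angle_max`; edge-to-face when the centroid
#' distance is <= `pipi_e2f_centroid_max` with the angle inside
#' `pipi_e2f_angle_window`. The interplanar angle is folded into [0, 90].
#'
#' @inheritParams detect_hbonds
#' @export
detect_pipi <- function(frame, criteria = interaction_criteria()) {
  rids <- names(frame$rings)
  if (length(rids) < 2) return(empty_events())
  out <- list()
  for (i in seq_len(length(rids) - 1)) for (j in seq(i + 1, length(rids))) {
    ci <- ring_centroid_normal(frame, frame$rings[[rids[i]]])
    cj <- ring_centroid_normal(frame, frame$rings[[rids[j]]])
    d <- sqrt(sum((ci$centroid - cj$centroid)^2))
    ang <- acos(min(1, abs(sum(ci$normal * cj$normal)))) * 180 / pi
    win <- criteria$pipi_e2f_angle_window
    ang_in_window <- ang >= min(win) ||
      (180 - ang) >= min(win) && (180 - ang) <= max(win)
    if (d <= criteria$pipi_f2f_centroid_max + 1e-9 &&
        ang <= criteria$pipi_f2f_angle_max + 1e-9) {
      out[[length(out) + 1]] <- cbind(event_df("pipi", rids[i], rids[j]),
                                      geometry = "face_to_face")
    } else if (d <= criteria$pipi_e2f_centroid_max + 1e-9 && ang_in_window) {
      out[[length(out) + 1]] <- cbind(event_df("pipi", rids[i], rids[j]),
                                      geometry = "edge_to_face")
    }
  }
  if (!length(out)) empty_events() else do.call(rbind, out)
}

# water-mediated H-bond test between a water molecule and a solute atom,
# in either direction, using the relaxed water-bridge criteria
water_solute_hbond <- function(frame, xyz, wo, solute_idx, criteria) {
  a <- frame$atoms
  hits <- integer()
  wh <- which(a$water_h & a$hydrogen_of == wo)
  for (i in solute_idx) {
    ok <- FALSE
    if (a$acceptor[i] || (a$element[i] %in% c("N", "O"))) {
      for (h in wh) {
        if (water_hb_ok(frame, xyz, h, wo, i, criteria)) { ok <- TRUE; break }
      }
    }
    if (!ok && a$donor[i]) {
      hs <- which(a$hydrogen & a$hydrogen_of == i)
      for (h in hs) {
        if (water_hb_ok(frame, xyz, h, i, wo, criteria)) { ok <- TRUE; break }
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# relaxed-geometry H-bond: hydrogen h on donor heavy `don` to acceptor `acc`
water_hb_ok <- function(frame, xyz, h, don, acc, criteria) {
  dha <- sqrt(sum((xyz[h, ] - xyz[acc, ])^2))
  if (dha > criteria$waterbridge_distance + 1e-9) return(FALSE)
  if (angle_deg(xyz[don, ], xyz[h, ], xyz[acc, ]) <
      criteria$waterbridge_donor_angle_min - 1e-9) return(FALSE)
  nb <- acceptor_neighbors(frame, acc, xyz)
  if (frame$atoms$water_o[acc]) {
    nb <- which(frame$atoms$water_h & frame$atoms$hydrogen_of == acc)
  }
  if (!length(nb)) return(TRUE)
  any(vapply(nb, function(x)
    angle_deg(xyz[h, ], xyz[acc, ], xyz[x, ]) >=
      criteria$waterbridge_acceptor_angle_min - 1e-9, logical(1)))
}

#' Detect water bridges in a frame
#'
#' Event when one water molecule simultaneously satisfies the relaxed
#' hydrogen-bond criteria with at least one ligand atom and at least one
#' protein atom. Partners are the bridged ligand and protein atoms; the
#' bridging water is recorded.
#'
#' @inheritParams detect_hbonds
#' @export
detect_waterbridge <- function(frame, criteria = interaction_criteria()) {
  a <- frame$atoms
  xyz <- coords(frame)
  waters <- which(a$water_o)
  lig <- which(a$ligand & a$element != "H")
  prot <- which((a$backbone | a$sidechain) & a$element != "H")
  lig <- lig[a$polar[lig]]
  prot <- prot[a$polar[prot]]
  out <- list()
  for (wo in waters) {
    # prefilter by distance to keep the pair scan small
    near <- function(idx) idx[min_dist_to_set(xyz[idx, , drop = FALSE],
                                              xyz[wo, , drop = FALSE]) <= 4.0]
    lh <- water_solute_hbond(frame, xyz, wo, near(lig), criteria)
    if (!length(lh)) next
    ph <- water_solute_hbond(frame, xyz, wo, near(prot), criteria)
    for (l in lh) for (p in ph)
      out[[length(out) + 1]] <- event_df("waterbridge",
                                         atom_label(frame, l),
                                         atom_label(frame, p),
                                         group_label(frame, wo))
  }
  if (!length(out)) empty_events() else do.call(rbind, out)
}

#' Detect salt bridges in a frame
#'
#' Event when any nitrogen/oxygen heavy-atom pair of a positively and a
#' negatively charged group lies within `saltbridge_distance`. Events are
#' reported once per residue pair.
#'
#' @inheritParams detect_hbonds
#' @export
detect_saltbridge <- function(frame, criteria = interaction_criteria()) {
  a <- frame$atoms
  xyz <- coords(frame)
  pos <- which(a$positive)
  neg <- which(a$negative)
  if (!length(pos) || !length(neg)) return(empty_events())
  out <- list()
  for (p in pos) for (q in neg) {
    d <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
    if (d <= criteria$saltbridge_distance + 1e-9)
      out[[length(out) + 1]] <- event_df("saltbridge",
                                         group_label(frame, p),
                                         group_label(frame, q))
  }
  if (!length(out)) return(empty_events())
  ev <- do.call(rbind, out)
  ev[!duplicated(ev[, c("partner_a", "partner_b")]), , drop = FALSE]
}

#' Detect interactions over a trajectory
#'
#' Runs the requested detectors on every frame and returns one event table
#' with a `frame` column.
#'
#' @param traj a `restime_trajectory`.
#' @param criteria an [interaction_criteria()].
#' @param kinds subset of c("hbond","pication","pipi","waterbridge","saltbridge").
#' @export
detect_interactions <- function(traj, criteria = interaction_criteria(),
                                kinds = c("hbond", "pication", "pipi",
                                          "waterbridge", "saltbridge")) {
  out <- list()
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_structure(traj, f)
    ev <- list()
    if ("hbond" %in% kinds) ev$h <- detect_hbonds(fr, criteria)
    if ("pication" %in% kinds) ev$pc <- detect_pication(fr, criteria)
    if ("pipi" %in% kinds) ev$pp <- detect_pipi(fr, criteria)[, 1:4]
    if ("waterbridge" %in% kinds) ev$wb <- detect_waterbridge(fr, criteria)
    if ("saltbridge" %in% kinds) ev$sb <- detect_saltbridge(fr, criteria)
    ev <- do.call(rbind, unname(ev))
    if (nrow(ev)) out[[length(out) + 1]] <- cbind(frame = f, ev)
  }
  if (!length(out)) cbind(frame = integer(), empty_events()) else
    do.call(rbind, out)
}

#' Tabulate interaction frequencies
#'
#' Collapses events to one observation per (kind, partner pair, frame) - a
#' pair interacts in a frame if at least one event of that kind exists - and
#' reports occurrence fractions. Rows are kept only when frequency is
#' strictly greater than `min_frequency` (the published fingerprints show
#' interactions with > 15 percent frequency).
#'
#' @param events event data.frame with a `frame` column.
#' @param n_frames total number of analysed frames.
#' @param min_frequency strict lower filter, or NULL to keep all rows.
#' @return data.frame(kind, partner_a, partner_b, n_obs, n_total, frequency).
#' @export
tabulate_frequencies <- function(events, n_frames, min_frequency = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!nrow(events)) {
    tab <- data.frame(kind = character(), partner_a = character(),
                      partner_b = character(), n_obs = integer(),
                      n_total = integer(), frequency = numeric())
    return(tab)
  }
  key <- paste(events$kind, events$partner_a, events$partner_b, sep = "\t")
  per_frame <- unique(data.frame(key = key, frame = events$frame))
  counts <- table(per_frame$key)
  parts <- strsplit(names(counts), "\t", fixed = TRUE)
  tab <- data.frame(kind = vapply(parts, `[`, "", 1),
                    partner_a = vapply(parts, `[`, "", 2),
                    partner_b = vapply(parts, `[`, "", 3),
                    n_obs = as.integer(counts),
                    n_total = n_frames,
                    stringsAsFactors = FALSE)
  tab$frequency <- tab$n_obs / tab$n_total
  if (!is.null(min_frequency)) tab <- tab[tab$frequency > min_frequency, , drop = FALSE]
  tab <- tab[order(-tab$frequency, tab$kind, tab$partner_a), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a frequency table as TSV
#' @param tab frequency table from [tabulate_frequencies()].
#' @param path output file.
#' @export
write_frequency_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
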