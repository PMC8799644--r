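# Annotated structures: atoms, roles, rings, charged centers.
#
# A `restime_structure` is a list with
#   atoms : data.frame(serial, name, element, resname, resno, chain, x, y, z,
#                      vdw, backbone, sidechain, water_o, water_h, ligand,
#                      donor, hydrogen, acceptor, positive, negative, polar,
#                      ring_id, hydrogen_of)
#   rings : named list of integer atom-index vectors (>= 5 coplanar members)
#   title : character
# Residue numbering is kept verbatim from the input PDB so residues such as
# Met109 or Thr175 keep their crystallographic numbers.

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA",
                     "HA2", "HA3", "HN")

.RING_TEMPLATES <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

.POSITIVE_CENTERS <- list(LYS = "NZ", ARG = c("NH1", "NH2"))
.NEGATIVE_CENTERS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.AMINO3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
             "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

new_structure <- function(atoms, rings = list(), title = "") {
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serial number(s): ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
  structure(list(atoms = atoms, rings = rings, title = title),
            class = "restime_structure")
}

#' @export
print.restime_structure <- function(x, ...) {
  a <- x$atoms
  cat("restime structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      sum(a$water_o), "waters,", sum(a$ligand), "ligand atoms,",
      length(x$rings), "aromatic rings\n")
  invisible(x)
}

coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

set_coords <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Read and annotate a PDB structure
#'
#' Parses ATOM/HETATM records (via bio3d) and annotates each atom with the
#' roles the downstream detectors need: backbone/sidechain, water oxygen and
#' hydrogen (recognised by residue name HOH/WAT/SPC/T3P), hydrogen-bond donor
#' heavy atoms and their hydrogens (inferred from covalent H distances
#' <= 1.25 Angstrom), acceptors (N/O), charged centers (Lys NZ, Arg NH1/NH2;
#' Asp OD1/OD2, Glu OE1/OE2), aromatic rings from sidechain templates, and
#' polarity (N, O and hydrogens bonded to them). Ligand atoms (non-water
#' HETATM, or a residue name given in the sidecar) get their roles from an
#' optional sidecar file; without one a warning is issued and ligand roles
#' stay minimal.
#'
#' @param path PDB file.
#' @param ligand_sidecar optional path to a YAML role sidecar, see
#'   [read_ligand_sidecar()].
#' @param vdw optional named numeric vector of van der Waals radii by element
#'   symbol, overriding the internal Bondi table.
#' @return a `restime_structure`.
#' @export
read_pdb_structure <- function(path, ligand_sidecar = NULL, vdw = NULL) {
  validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  blank <- is.na(element) | element == ""
  if (any(blank)) element[blank] <- guess_element(at$elety[blank])
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = element,
    resname = trimws(at$resid), resno = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  atoms$vdw <- vdw_radius_for(atoms$element)
  if (!is.null(vdw)) {
    hit <- toupper(atoms$element) %in% names(vdw)
    atoms$vdw[hit] <- unname(vdw[toupper(atoms$element[hit])])
  }
  sidecar <- if (!is.null(ligand_sidecar)) read_ligand_sidecar(ligand_sidecar)
  annotate_structure(atoms, sidecar, title = basename(path))
}

# Light validation so malformed coordinate records fail with a line number
# before bio3d silently coerces them.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(flds)))))
      stop("malformed PDB record at line ", i, ": bad coordinate field")
  }
  serials <- suppressWarnings(as.integer(substr(lines[idx], 7, 11)))
  if (anyDuplicated(serials))
    stop("duplicate atom serial at line ",
         idx[which(duplicated(serials))[1]])
  invisible(TRUE)
}

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE"),
               two, substr(gsub("^[0-9]+", "", nm), 1, 1))
  el
}

annotate_structure <- function(atoms, sidecar = NULL, title = "") {
  n <- nrow(atoms)
  is_h <- atoms$element == "H"
  is_water <- atoms$resname %in% .WATER_RESNAMES
  std_aa <- atoms$resname %in% .AMINO3
  lig_res <- if (!is.null(sidecar)) sidecar$resname else NULL
  is_lig <- if (!is.null(lig_res)) atoms$resname %in% lig_res else
    (!std_aa & !is_water)

  atoms$backbone  <- std_aa & atoms$name %in% .BACKBONE_NAMES
  atoms$sidechain <- std_aa & !atoms$backbone
  atoms$water_o <- is_water & atoms$element == "O"
  atoms$water_h <- is_water & is_h
  atoms$ligand  <- is_lig & !is_water

  # covalent H attachment by distance (<= 1.25 A, same residue)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  atoms$hydrogen_of <- NA_integer_
  reskey <- paste(atoms$chain, atoms$resno, atoms$resname)
  for (i in which(is_h)) {
    cand <- which(reskey == reskey[i] & !is_h)
    if (!length(cand)) next
    d <- min_dist_to_set(xyz[i, , drop = FALSE], xyz[cand, , drop = FALSE])
    # recompute per-candidate to pick the nearest heavy atom
    dd <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
    j <- cand[which.min(dd)]
    if (min(dd) <= 1.25) atoms$hydrogen_of[i] <- j
  }

  heavy_no <- atoms$element %in% c("N", "O")
  has_h <- rep(FALSE, n)
  att <- atoms$hydrogen_of[!is.na(atoms$hydrogen_of)]
  has_h[unique(att)] <- TRUE
  atoms$donor <- heavy_no & has_h & !atoms$water_o
  atoms$hydrogen <- is_h & !is.na(atoms$hydrogen_of) &
    heavy_no[pmax(atoms$hydrogen_of, 1)] %in% TRUE
  atoms$hydrogen[is.na(atoms$hydrogen)] <- FALSE
  atoms$acceptor <- heavy_no & !atoms$water_o & !atoms$water_h
  atoms$polar <- heavy_no |
    (is_h & !is.na(atoms$hydrogen_of) & heavy_no[pmax(atoms$hydrogen_of, 1)])

  atoms$positive <- FALSE
  atoms$negative <- FALSE
  for (rn in names(.POSITIVE_CENTERS))
    atoms$positive[atoms$resname == rn &
                     atoms$name %in% .POSITIVE_CENTERS[[rn]]] <- TRUE
  for (rn in names(.NEGATIVE_CENTERS))
    atoms$negative[atoms$resname == rn &
                     atoms$name %in% .NEGATIVE_CENTERS[[rn]]] <- TRUE

  atoms$ring_id <- NA_character_
  rings <- list()
  # protein sidechain rings from templates
  for (rn in names(.RING_TEMPLATES)) {
    for (resi in unique(atoms$resno[atoms$resname == rn])) {
      for (k in seq_along(.RING_TEMPLATES[[rn]])) {
        nm <- .RING_TEMPLATES[[rn]][[k]]
        sel <- which(atoms$resname == rn & atoms$resno == resi &
                       atoms$name %in% nm)
        if (length(sel) == length(nm)) {
          rid <- paste0(rn, resi, ".", k)
          check_ring_planarity(xyz[sel, , drop = FALSE], rid)
          rings[[rid]] <- sel
          atoms$ring_id[sel] <- rid
        }
      }
    }
  }

  # ligand roles from sidecar
  if (!is.null(sidecar)) {
    lig_idx <- which(atoms$ligand)
    lname <- atoms$name[lig_idx]
    pick <- function(nms) lig_idx[match(nms, lname)]
    if (length(sidecar$donors)) {
      dh <- pick(names(sidecar$donors)); hh <- pick(unlist(sidecar$donors))
      ok <- !is.na(dh) & !is.na(hh)
      atoms$donor[dh[ok]] <- TRUE
      atoms$hydrogen[hh[ok]] <- TRUE
      atoms$hydrogen_of[hh[ok]] <- dh[ok]
      atoms$polar[c(dh[ok], hh[ok])] <- TRUE
    }
    if (length(sidecar$acceptors)) {
      aa <- pick(sidecar$acceptors); aa <- aa[!is.na(aa)]
      atoms$acceptor[aa] <- TRUE; atoms$polar[aa] <- TRUE
    }
    if (length(sidecar$positive)) {
      pp <- pick(sidecar$positive); atoms$positive[pp[!is.na(pp)]] <- TRUE
    }
    if (length(sidecar$negative)) {
      nn <- pick(sidecar$negative); atoms$negative[nn[!is.na(nn)]] <- TRUE
    }
    for (rid in names(sidecar$rings)) {
      sel <- pick(sidecar$rings[[rid]]); sel <- sel[!is.na(sel)]
      if (length(sel) >= 5) {
        check_ring_planarity(xyz[sel, , drop = FALSE], rid)
        rings[[rid]] <- sel
        atoms$ring_id[sel] <- rid
      }
    }
  } else if (any(atoms$ligand)) {
    warning("ligand residue(s) without a role sidecar: roles left minimal")
  }

  new_structure(atoms, rings, title)
}

# rings must be >= 5 members and coplanar (plane-fit RMS <= 0.15 A)
check_ring_planarity <- function(xyz, rid, tol = 0.15) {
  if (nrow(xyz) < 5) stop("ring ", rid, " has fewer than 5 members")
  c0 <- colMeans(xyz)
  m <- sweep(xyz, 2, c0)
  sv <- svd(m)
  rms <- sqrt(mean((m %*% sv$v[, 3])^2))
  if (rms > tol)
    stop("ring ", rid, " is not planar (RMS ", round(rms, 3), " A)")
  invisible(rms)
}

#' Read a ligand role sidecar
#'
#' Small YAML file that maps ligand atom names to interaction roles, used
#' because ligand topology perception is out of scope. Expected keys:
#' `resname`, `donors` (map heavy-atom name to its hydrogen name),
#' `acceptors`, `positive`, `negative` (name lists) and `rings` (map of ring
#' id to a list of >= 5 atom names).
#'
#' @param path YAML file.
#' @export
read_ligand_sidecar <- function(path) {
  sc <- yaml::read_yaml(path)
  list(resname = sc$resname %||% "LIG",
       donors = sc$donors %||% list(),
       acceptors = unlist(sc$acceptors) %||% character(),
       positive = unlist(sc$positive) %||% character(),
       negative = unlist(sc$negative) %||% character(),
       rings = sc$rings %||% list())
}

#' Write a structure to PDB
#'
#' @param s a `restime_structure`.
#' @param path output file.
#' @export
write_pdb_structure <- function(s, path) {
  a <- s$atoms
  het <- a$ligand | a$water_o | a$water_h | !(a$resname %in% .AMINO3)
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords(s))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' Select atom indices
#'
#' @param s a `restime_structure`.
#' @param chain,resno,name optional filters.
#' @param backbone,sidechain,ligand,water logical filters (NULL = no filter).
#' @param exclude_resno residue numbers to drop after filtering.
#' @return integer atom indices.
#' @export
atom_select <- function(s, chain = NULL, resno = NULL, name = NULL,
                        backbone = NULL, sidechain = NULL, ligand = NULL,
                        water = NULL, exclude_resno = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(backbone)) keep <- keep & a$backbone == backbone
  if (!is.null(sidechain)) keep <- keep & a$sidechain == sidechain
  if (!is.null(ligand)) keep <- keep & a$ligand == ligand
  if (!is.null(water)) keep <- keep & (a$water_o | a$water_h) == water
  if (!is.null(exclude_resno)) keep <- keep & !(a$resno %in% exclude_resno)
  which(keep)
}
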