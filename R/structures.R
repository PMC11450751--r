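#' @importFrom stats dist prcomp rnorm runif setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

WATER_RESIDS <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "H2O", "DOD")

ATOM_COLS <- c("type", "eleno", "elety", "resid", "chain", "resno", "insert",
               "x", "y", "z", "o", "b", "elesy", "charge", "fill")

empty_atoms <- function() {
  data.frame(type = character(), eleno = integer(), elety = character(),
             resid = character(), chain = character(), resno = integer(),
             insert = character(), x = numeric(), y = numeric(), z = numeric(),
             o = numeric(), b = numeric(), elesy = character(),
             charge = numeric(), fill = logical(), stringsAsFactors = FALSE)
}

#' Construct a Structure from an atom table
#'
#' A `Structure` holds one conformation of a (possibly multi-chain) molecular
#' system as a flat atom table plus a model id.  Atoms belong to residues
#' identified by `(chain, resno, insert)` in author (file) numbering, which is
#' the single residue coordinate system used throughout the package.
#'
#' @param atoms data.frame with columns `type` ("ATOM"/"HETATM"), `eleno`,
#'   `elety` (atom name), `resid` (3-letter residue name), `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, and optionally `o`, `b`, `elesy` (element
#'   symbol), `charge` (partial charge) and `fill` (fill-hydrogen flag).
#' @param model_id integer model number (for multi-model files).
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, model_id = 1L) {
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  for (col in c("elety", "resid", "chain", "resno", "x", "y", "z")) {
    if (is.null(atoms[[col]])) stop("atom table lacks column '", col, "'")
  }
  if (is.null(atoms$type))   atoms$type   <- "ATOM"
  if (is.null(atoms$eleno))  atoms$eleno  <- seq_len(nrow(atoms))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o))      atoms$o      <- 1
  if (is.null(atoms$b))      atoms$b      <- 0
  if (is.null(atoms$elesy))  atoms$elesy  <- guess_element(atoms$elety)
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$fill))   atoms$fill   <- FALSE
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$elesy))) stop("empty element symbol")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms[, ATOM_COLS], model_id = as.integer(model_id)),
            class = "Structure")
}

guess_element <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(nm, 1, 2))
  ele <- toupper(substr(nm, 1, 1))
  ele[two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE")] <-
    two[two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE")]
  # names like 1HG2, HG21 are hydrogens
  ele[grepl("^[0-9]*H", elety)] <- "H"
  ele
}

#' @export
print.Structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("Structure (model ", x$model_id, "): ",
      nrow(x$atoms), " atoms, ", nrow(rt), " residues, ",
      length(unique(rt$chain)), " chain(s) [",
      paste(unique(rt$chain), collapse = ", "), "]\n", sep = "")
  nw <- sum(is_water_resid(rt$resid))
  if (nw > 0) cat("  including", nw, "water residue(s)\n")
  invisible(x)
}

#' Is a residue name a solvent (water) residue?
#'
#' @param resid character vector of residue names.
#' @return Logical vector.
#' @export
is_water_resid <- function(resid) toupper(resid) %in% WATER_RESIDS

#' Residue key strings
#'
#' Residues are addressed by compact keys `"chain:resno"` (or
#' `"chain:resno:insert"` when an insertion code is present).
#'
#' @param chain,resno,insert residue identity components.
#' @return character vector of keys.
#' @export
res_key <- function(chain, resno, insert = "") {
  n <- max(length(chain), length(resno), length(insert))
  chain <- rep_len(chain, n)
  resno <- rep_len(resno, n)
  insert <- rep_len(insert, n)
  insert[is.na(insert)] <- ""
  ifelse(nzchar(insert),
         paste(chain, resno, insert, sep = ":"),
         paste(chain, resno, sep = ":"))
}

parse_res_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1),
             resno = as.integer(vapply(parts, `[`, "", 2)),
             insert = vapply(parts, function(p) if (length(p) > 2) p[3] else "", ""),
             stringsAsFactors = FALSE)
}

atom_res_keys <- function(atoms) res_key(atoms$chain, atoms$resno, atoms$insert)

#' Table of residues in a Structure
#'
#' @param structure a `Structure`.
#' @return data.frame with one row per residue, in file order, with columns
#'   `chain`, `resno`, `insert`, `resid`, `key`, `water`.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- atom_res_keys(a)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             key = key[first], water = is_water_resid(a$resid[first]),
             stringsAsFactors = FALSE)
}

#' Atoms of one residue
#'
#' @param structure a `Structure`.
#' @param key residue key (see [res_key()]).
#' @return The residue's rows of the atom table.
#' @export
residue_atoms <- function(structure, key) {
  structure$atoms[atom_res_keys(structure$atoms) == key, , drop = FALSE]
}

#' Coordinate matrix of an atom table
#'
#' @param atoms an atom data.frame (e.g. `structure$atoms`).
#' @return Numeric n-by-3 matrix.
#' @export
coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Replace the coordinates of a Structure
#'
#' @param structure a `Structure`.
#' @param xyz numeric n-by-3 matrix.
#' @return The updated `Structure`.
#' @export
set_coords <- function(structure, xyz) {
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM/MODEL records, preserving author residue numbering,
#' insertion codes and chain identifiers verbatim.  For alternate locations
#' only the highest-occupancy conformer of each atom is kept.
#'
#' @param path path to a PDB file.
#' @param keep_waters logical; keep solvent (HOH/WAT/...) residues.
#' @return A list of `Structure` objects, one per MODEL (length one for
#'   single-model files).
#' @export
read_pdb <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty structure: no ATOM/HETATM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest-occupancy conformer per atom
  aid <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  if (anyDuplicated(aid)) {
    keep <- unlist(lapply(split(seq_len(nrow(at)), factor(aid, unique(aid))),
                          function(i) i[which.max(at$o[i])]), use.names = FALSE)
    keep <- sort(keep)
  } else keep <- seq_len(nrow(at))
  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  out <- vector("list", nmodels)
  for (m in seq_len(nmodels)) {
    xm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(type = at$type, eleno = at$eleno, elety = at$elety,
                        resid = at$resid, chain = at$chain, resno = at$resno,
                        insert = at$insert,
                        x = xm[, 1], y = xm[, 2], z = xm[, 3],
                        o = at$o, b = ifelse(is.na(at$b), 0, at$b),
                        elesy = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                                       guess_element(at$elety), at$elesy),
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
    if (!keep_waters) atoms <- atoms[!is_water_resid(atoms$resid), , drop = FALSE]
    if (nrow(atoms) == 0L) stop("empty structure after water removal: ", path)
    out[[m]] <- new_structure(atoms, model_id = m)
  }
  out
}

check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": record too short")
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(flds)))))
      stop("malformed ATOM/HETATM record at line ", i,
           ": non-numeric coordinate field")
  }
  invisible(TRUE)
}

#' Write a Structure (or Trajectory) to a PDB file
#'
#' Coordinates are rendered with three decimals; chain ids, residue numbers
#' and insertion codes are written as stored.  Water residues are emitted as
#' HETATM records.  A `Trajectory` is written as a multi-MODEL file.
#'
#' @param structure a `Structure` or `Trajectory`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  if (inherits(structure, "Trajectory")) {
    frames <- structure$frames
    xyz <- do.call(rbind, lapply(frames, function(s) as.vector(t(coords(s$atoms)))))
    s1 <- frames[[1]]
  } else {
    s1 <- structure
    xyz <- matrix(as.vector(t(coords(s1$atoms))), nrow = 1)
  }
  a <- s1$atoms
  type <- ifelse(is_water_resid(a$resid) | a$type == "HETATM", "HETATM", "ATOM")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  bio3d::write.pdb(file = path, xyz = xyz, type = type, resno = a$resno,
                   resid = a$resid, eleno = a$eleno, elety = a$elety,
                   chain = ifelse(a$chain == " ", "", a$chain),
                   insert = a$insert, o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Select residues by chain and sequence-number ranges
#'
#' @param structure a `Structure`.
#' @param chains character vector of chain ids to keep.
#' @param ranges `NULL` (all residues of the chains), a list of inclusive
#'   `c(start, end)` intervals applied to every selected chain, or a named
#'   list of such lists keyed by chain id.
#' @return The sub-`Structure` containing exactly the matching residues, in
#'   the original order.
#' @export
select_residues <- function(structure, chains, ranges = NULL) {
  a <- structure$atoms
  keep <- a$chain %in% chains
  if (!is.null(ranges)) {
    norm <- function(r) if (is.list(r)) r else list(r)
    in_ranges <- function(resno, rlist) {
      ok <- rep(FALSE, length(resno))
      for (r in norm(rlist)) ok <- ok | (resno >= r[1] & resno <= r[2])
      ok
    }
    if (!is.null(names(ranges)) && all(nzchar(names(ranges)))) {
      ok <- rep(FALSE, nrow(a))
      for (ch in names(ranges))
        ok <- ok | (a$chain == ch & in_ranges(a$resno, ranges[[ch]]))
      keep <- keep & ok
    } else {
      keep <- keep & in_ranges(a$resno, ranges)
    }
  }
  if (!any(keep)) stop("empty selection")
  new_structure(a[keep, , drop = FALSE], model_id = structure$model_id)
}

#' Minimum inter-residue atom distance
#'
#' @param structure a `Structure`.
#' @param key_a,key_b residue keys (see [res_key()]).
#' @param heavy_only logical; restrict to non-hydrogen atoms.
#' @return Minimum distance in Angstrom over all atom pairs.
#' @export
min_residue_distance <- function(structure, key_a, key_b, heavy_only = TRUE) {
  aa <- residue_atoms(structure, key_a)
  ab <- residue_atoms(structure, key_b)
  if (nrow(aa) == 0L) stop("residue not found: ", key_a)
  if (nrow(ab) == 0L) stop("residue not found: ", key_b)
  if (heavy_only) {
    # fall back to all atoms for residues that carry only hydrogens
    ha <- aa[aa$elesy != "H", , drop = FALSE]
    hb <- ab[ab$elesy != "H", , drop = FALSE]
    if (nrow(ha) > 0L) aa <- ha
    if (nrow(hb) > 0L) ab <- hb
  }
  min(cross_dist(coords(aa), coords(ab)))
}

# all pairwise distances between two coordinate matrices (rows = atoms)
cross_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

#' Bundle Structures sharing one topology into a Trajectory
#'
#' @param frames list of `Structure` objects with identical atom count and
#'   ordering.
#' @param times optional numeric frame times (ns).
#' @return An object of class `Trajectory`.
#' @export
as_trajectory <- function(frames, times = NULL) {
  if (inherits(frames, "Structure")) frames <- list(frames)
  if (length(frames) == 0L) stop("empty trajectory")
  ref <- frames[[1]]$atoms
  for (f in frames) {
    if (nrow(f$atoms) != nrow(ref) ||
        any(f$atoms$elety != ref$elety) || any(f$atoms$resno != ref$resno) ||
        any(f$atoms$chain != ref$chain))
      stop("trajectory frames must share an identical topology")
  }
  if (!is.null(times) && length(times) != length(frames))
    stop("times must match the number of frames")
  structure(list(frames = frames, times = times), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory: ", length(x$frames), " frames, ",
      nrow(x$frames[[1]]$atoms), " atoms/frame\n", sep = "")
  invisible(x)
}

#' @export
length.Trajectory <- function(x) length(x$frames)
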