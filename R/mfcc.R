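COULOMB_K <- 332.0636  # kcal*Angstrom/(mol*e^2)
FILL_H_LENGTH <- 1.09  # Angstrom, standard C-H bond length

#' Enumerate interface residue pairs within a distance cutoff
#'
#' All cross-group residue pairs whose minimum heavy-atom distance is at most
#' `cutoff` (default 8.0 A), in deterministic (chain, resno) order.  Waters
#' are never part of the enumeration.
#'
#' @param structure a `Structure`.
#' @param group_a,group_b character vectors of chain ids (must not overlap).
#' @param cutoff distance threshold in Angstrom.
#' @return data.frame with columns `key_i`, `chain_i`, `resno_i`, `resid_i`,
#'   `key_j`, `chain_j`, `resno_j`, `resid_j`, `dist`.
#' @export
enumerate_pairs <- function(structure, group_a, group_b, cutoff = 8.0) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  gr <- split_groups(structure, group_a, group_b)
  a1 <- gr$a1[gr$a1$elesy != "H", , drop = FALSE]
  a2 <- gr$a2[gr$a2$elesy != "H", , drop = FALSE]
  out <- data.frame(key_i = character(), chain_i = character(),
                    resno_i = integer(), resid_i = character(),
                    key_j = character(), chain_j = character(),
                    resno_j = integer(), resid_j = character(),
                    dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(a1) == 0L || nrow(a2) == 0L) return(out)
  dd <- cross_dist(coords(a1), coords(a2))
  k1 <- atom_res_keys(a1); k2 <- atom_res_keys(a2)
  for (key1 in unique(k1)) for (key2 in unique(k2)) {
    d <- min(dd[k1 == key1, k2 == key2, drop = FALSE])
    if (d > cutoff || cutoff == 0) next
    i1 <- which(k1 == key1)[1]; i2 <- which(k2 == key2)[1]
    out <- rbind(out, data.frame(
      key_i = key1, chain_i = a1$chain[i1], resno_i = a1$resno[i1],
      resid_i = a1$resid[i1],
      key_j = key2, chain_j = a2$chain[i2], resno_j = a2$resno[i2],
      resid_j = a2$resid[i2], dist = d, stringsAsFactors = FALSE))
  }
  out[order(out$chain_i, out$resno_i, out$chain_j, out$resno_j), , drop = FALSE]
}

# residues of one chain in file order (waters excluded); used to find the
# covalent sequence neighbours that become the conjugated caps
chain_residues <- function(structure, chain) {
  rt <- residue_table(structure)
  rt[rt$chain == chain & !rt$water, , drop = FALSE]
}

fill_hydrogen <- function(keep_atom, removed_atom) {
  v <- as.numeric(removed_atom[, c("x", "y", "z")]) -
       as.numeric(keep_atom[, c("x", "y", "z")])
  pos <- as.numeric(keep_atom[, c("x", "y", "z")]) + FILL_H_LENGTH * v / sqrt(sum(v^2))
  data.frame(type = "ATOM", eleno = 0L, elety = "HF",
             resid = keep_atom$resid, chain = keep_atom$chain,
             resno = keep_atom$resno, insert = keep_atom$insert,
             x = pos[1], y = pos[2], z = pos[3], o = 1, b = 0,
             elesy = "H", charge = 0, fill = TRUE, stringsAsFactors = FALSE)
}

get_atom <- function(structure, key, elety) {
  a <- residue_atoms(structure, key)
  a[a$elety == elety, , drop = FALSE]
}

# Capped fragment: core residue (optionally omitted) plus its sequence
# neighbours, with fill hydrogens on every cut backbone bond.
capped_fragment <- function(structure, key, include_core = TRUE) {
  ref <- parse_res_key(key)
  cr <- chain_residues(structure, ref$chain)
  pos <- which(cr$key == key)
  if (length(pos) != 1L) stop("residue not found in chain: ", key)
  keys <- cr$key[pos + (-1:1)[pos + (-1:1) >= 1 & pos + (-1:1) <= nrow(cr)]]
  cap_keys <- setdiff(keys, key)
  kept <- if (include_core) keys else cap_keys
  fills <- list()
  add_fill <- function(keep_key, keep_name, rem_key, rem_name) {
    ka <- get_atom(structure, keep_key, keep_name)
    ra <- get_atom(structure, rem_key, rem_name)
    if (nrow(ka) == 1L && nrow(ra) == 1L)
      fills[[length(fills) + 1L]] <<- fill_hydrogen(ka, ra)
  }
  # outer cuts: cap loses its own outward neighbour
  if (pos - 2 >= 1 && (pos - 1) >= 1)
    add_fill(cr$key[pos - 1], "N", cr$key[pos - 2], "C")
  if (pos + 2 <= nrow(cr) && (pos + 1) <= nrow(cr))
    add_fill(cr$key[pos + 1], "C", cr$key[pos + 2], "N")
  if (!include_core) {
    # inner cuts at the removed core
    if (pos - 1 >= 1) add_fill(cr$key[pos - 1], "C", key, "N")
    if (pos + 1 <= nrow(cr)) add_fill(cr$key[pos + 1], "N", key, "C")
  }
  a <- structure$atoms
  atoms <- a[atom_res_keys(a) %in% kept, , drop = FALSE]
  n_fill <- length(fills)
  if (n_fill) {
    fills <- do.call(rbind, fills)
    fills$elety <- paste0("HF", seq_len(nrow(fills)))  # unique per fragment
    atoms <- rbind(atoms, fills)
  }
  list(atoms = atoms, core = key, caps = cap_keys, n_fill = n_fill)
}

water_keys_near <- function(structure, key, shell) {
  rt <- residue_table(structure)
  wk <- rt$key[rt$water]
  if (length(wk) == 0L) return(list(keys = character(), dist = numeric()))
  xc <- coords(residue_atoms(structure, key))
  d <- vapply(wk, function(w)
    min(cross_dist(coords(residue_atoms(structure, w)), xc)), 0)
  sel <- d <= shell
  list(keys = wk[sel], dist = unname(d[sel]))
}

#' Build the four capped MFCC subsystems for one residue pair
#'
#' Each fragmented residue keeps its covalent sequence neighbours as
#' conjugated caps; every cut backbone bond receives one fill hydrogen placed
#' 1.09 A along the former bond vector.  The four subsystems are
#' S1 = cap_i+Ri + cap_j+Rj, S2 = cap_i+Ri + cap_j, S3 = cap_i + cap_j+Rj and
#' S4 = cap_i + cap_j.  When `water_shell` is set, solvent molecules with any
#' atom within the shell of a core residue are attached to that core (a water
#' qualifying for both cores goes to the nearer one, ties to Ri) and appear
#' in every subsystem that contains the core.
#'
#' @param structure a `Structure` (with waters present if `water_shell` is
#'   used).
#' @param key_i,key_j residue keys of the pair; must lie in distinct chains.
#' @param water_shell shell radius in Angstrom, or `NULL` for no waters.
#' @return An object of class `subsystem_quartet` with elements `S1`..`S4`
#'   (Structures), `pair`, `caps_i`, `caps_j`, `waters_i`, `waters_j`,
#'   `n_fill`.
#' @export
build_quartet <- function(structure, key_i, key_j, water_shell = NULL) {
  ri <- parse_res_key(key_i); rj <- parse_res_key(key_j)
  if (ri$chain == rj$chain)
    stop("pair residues must lie in distinct chains: ", key_i, " / ", key_j)
  fi  <- capped_fragment(structure, key_i, include_core = TRUE)
  fic <- capped_fragment(structure, key_i, include_core = FALSE)
  fj  <- capped_fragment(structure, key_j, include_core = TRUE)
  fjc <- capped_fragment(structure, key_j, include_core = FALSE)
  wi <- character(); wj <- character()
  if (!is.null(water_shell)) {
    qi <- water_keys_near(structure, key_i, water_shell)
    qj <- water_keys_near(structure, key_j, water_shell)
    both <- intersect(qi$keys, qj$keys)
    for (w in both) {
      # nearest-fragment attribution, ties to Ri
      if (qj$dist[match(w, qj$keys)] < qi$dist[match(w, qi$keys)])
        qi$keys <- setdiff(qi$keys, w)
      else qj$keys <- setdiff(qj$keys, w)
    }
    wi <- qi$keys; wj <- qj$keys
  }
  wat_atoms <- function(keys) {
    if (length(keys) == 0L) return(NULL)
    a <- structure$atoms
    a[atom_res_keys(a) %in% keys, , drop = FALSE]
  }
  assemble <- function(fa, wa, fb, wb) {
    atoms <- rbind(fa$atoms, wat_atoms(wa), fb$atoms, wat_atoms(wb))
    # caps-only subsystems of single-residue chains are legitimately empty
    if (nrow(atoms) == 0L)
      return(structure(list(atoms = empty_atoms(), model_id = 1L),
                       class = "Structure"))
    atoms$eleno <- seq_len(nrow(atoms))
    new_structure(atoms)
  }
  structure(list(
    pair = c(i = key_i, j = key_j),
    S1 = assemble(fi,  wi, fj,  wj),
    S2 = assemble(fi,  wi, fjc, NULL),
    S3 = assemble(fic, NULL, fj, wj),
    S4 = assemble(fic, NULL, fjc, NULL),
    caps_i = fi$caps, caps_j = fj$caps,
    waters_i = wi, waters_j = wj,
    n_fill = c(S1 = fi$n_fill + fj$n_fill, S2 = fi$n_fill + fjc$n_fill,
               S3 = fic$n_fill + fj$n_fill, S4 = fic$n_fill + fjc$n_fill)),
    class = "subsystem_quartet")
}

#' @export
print.subsystem_quartet <- function(x, ...) {
  cat("MFCC subsystem quartet for pair ", x$pair["i"], " :: ", x$pair["j"], "\n",
      sep = "")
  for (s in c("S1", "S2", "S3", "S4"))
    cat("  ", s, ": ", nrow(x[[s]]$atoms), " atoms (",
        x$n_fill[s], " fill H)\n", sep = "")
  if (length(x$waters_i) + length(x$waters_j) > 0)
    cat("  waters: ", length(x$waters_i), " on i, ",
        length(x$waters_j), " on j\n", sep = "")
  invisible(x)
}

#' Combine the four MFCC subsystem energies
#'
#' The pair interaction energy is `e1 - e2 - e3 + e4`: the capped-pair energy
#' minus the two single-core terms plus the caps-only term, so that cap and
#' solvent self-energies cancel.
#'
#' @param e1,e2,e3,e4 subsystem energies (kcal/mol).
#' @return Interaction energy in kcal/mol.
#' @export
mfcc_combine <- function(e1, e2, e3, e4) {
  if (any(!is.finite(c(e1, e2, e3, e4))))
    stop("non-finite subsystem energy")
  e1 - e2 - e3 + e4
}

#' Configure an MFCC energy backend
#'
#' * `classical`: built-in pairwise Coulomb term with a distance-independent
#'   dielectric plus a 12-6 Lennard-Jones term with a small shipped parameter
#'   table; partial charges come from an explicit per-atom `charge` column
#'   when present, else from a fixed per-residue table.  A desk-scale,
#'   strictly pairwise-additive stand-in that preserves every structural
#'   aspect of the fragmentation scheme.
#' * `table`: subsystem energies read from an external table (e.g. a quantum
#'   engine's output) with columns `pair_id`, `subsystem`, `energy_kcal_mol`,
#'   where `pair_id` is `"<key_i>|<key_j>"`.
#' * `export`: no energies; subsystem geometries are written to `dir` for an
#'   external engine.
#'
#' @param kind one of `"classical"`, `"table"`, `"export"`.
#' @param dielectric relative dielectric constant (default 40).
#' @param table data.frame or CSV path (table backend).
#' @param dir output directory (export backend).
#' @param format `"pdb"` or `"xyz"` (export backend).
#' @return An object of class `backend_config`.
#' @export
backend_config <- function(kind = c("classical", "table", "export"),
                           dielectric = 40, table = NULL, dir = NULL,
                           format = c("pdb", "xyz")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!is.finite(dielectric) || dielectric <= 0)
    stop("dielectric must be positive")
  if (kind == "table") {
    if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
    if (is.null(table) ||
        !all(c("pair_id", "subsystem", "energy_kcal_mol") %in% names(table)))
      stop("table backend needs columns pair_id, subsystem, energy_kcal_mol")
  }
  if (kind == "export" && is.null(dir))
    stop("export backend needs an output directory")
  id <- switch(kind,
               classical = sprintf("classical(eps=%g)", dielectric),
               table = "table", export = "export")
  structure(list(kind = kind, dielectric = dielectric, table = table,
                 dir = dir, format = format, id = id),
            class = "backend_config")
}

# total nonbonded energy of a structure under the classical backend: sum over
# all atom pairs in different residues of Coulomb + 12-6 LJ.  Same-residue
# pairs are excluded (a constant self-term that cancels in the MFCC
# combination).  Fill hydrogens carry zero parameters.
classical_total_energy <- function(structure, dielectric = 40) {
  a <- structure$atoms
  n <- nrow(a)
  if (n < 2L) return(0)
  x <- coords(a)
  q <- lookup_charges(a)
  lj <- lookup_lj(a)
  dd <- cross_dist(x, x)
  same_res <- outer(atom_res_keys(a), atom_res_keys(a), `==`)
  sel <- upper.tri(dd) & !same_res
  if (!any(sel)) return(0)
  r <- dd[sel]
  qq <- tcrossprod(q)[sel]
  eps <- tcrossprod(sqrt(lj[, "eps"]))[sel]
  rmin <- outer(lj[, "rmin2"], lj[, "rmin2"], `+`)[sel]
  r <- pmax(r, 1e-6)
  s6 <- (rmin / r)^6
  sum(COULOMB_K * qq / (dielectric * r) + eps * (s6^2 - 2 * s6))
}

# cross-group nonbonded energy between two atom sets (same pair potential as
# classical_total_energy); the brute-force oracle side of the MFCC identity
nb_cross_energy <- function(atoms_a, atoms_b, dielectric = 40) {
  if (nrow(atoms_a) == 0L || nrow(atoms_b) == 0L) return(0)
  qa <- lookup_charges(atoms_a); qb <- lookup_charges(atoms_b)
  la <- lookup_lj(atoms_a); lb <- lookup_lj(atoms_b)
  r <- pmax(cross_dist(coords(atoms_a), coords(atoms_b)), 1e-6)
  qq <- outer(qa, qb)
  eps <- outer(sqrt(la[, "eps"]), sqrt(lb[, "eps"]))
  rmin <- outer(la[, "rmin2"], lb[, "rmin2"], `+`)
  s6 <- (rmin / r)^6
  sum(COULOMB_K * qq / (dielectric * r) + eps * (s6^2 - 2 * s6))
}

#' Direct residue-residue interaction energy (brute-force reference)
#'
#' Sums the classical pair potential over all cross atom pairs between the
#' two residues (plus any attached waters).  For a strictly pairwise-additive
#' backend this is what the four-term MFCC combination must reproduce; it is
#' the independent reference route, not the MFCC path.
#'
#' @param structure a `Structure`.
#' @param key_i,key_j residue keys.
#' @param dielectric relative dielectric constant.
#' @param waters_i,waters_j optional water residue keys attached to each side.
#' @return Energy in kcal/mol.
#' @export
direct_pair_energy <- function(structure, key_i, key_j, dielectric = 40,
                               waters_i = character(), waters_j = character()) {
  a <- structure$atoms
  keys <- atom_res_keys(a)
  ai <- a[keys %in% c(key_i, waters_i), , drop = FALSE]
  aj <- a[keys %in% c(key_j, waters_j), , drop = FALSE]
  nb_cross_energy(ai, aj, dielectric)
}

#' Interaction energy of one residue pair through the MFCC route
#'
#' Builds the subsystem quartet, evaluates the four subsystem energies with
#' the configured backend, and combines them.
#'
#' @inheritParams build_quartet
#' @param backend a [backend_config()].
#' @return One-row data.frame (an interaction record): pair identity,
#'   `energy` (kcal/mol), `backend_id`, `pair_distance` (minimum heavy-atom
#'   distance, Angstrom), `included_waters`.
#' @export
pair_energy <- function(structure, key_i, key_j,
                        backend = backend_config("classical"),
                        water_shell = NULL) {
  qt <- build_quartet(structure, key_i, key_j, water_shell)
  energy <- NA_real_
  if (backend$kind == "classical") {
    es <- vapply(c("S1", "S2", "S3", "S4"),
                 function(s) classical_total_energy(qt[[s]], backend$dielectric), 0)
    energy <- mfcc_combine(es[1], es[2], es[3], es[4])
  } else if (backend$kind == "table") {
    pid <- paste(key_i, key_j, sep = "|")
    tab <- backend$table[backend$table$pair_id == pid, , drop = FALSE]
    es <- vapply(c("S1", "S2", "S3", "S4"), function(s) {
      e <- tab$energy_kcal_mol[tab$subsystem == s]
      if (length(e) != 1L)
        stop("table backend: missing energy for pair ", pid, " subsystem ", s)
      e
    }, 0)
    energy <- mfcc_combine(es[1], es[2], es[3], es[4])
  } else {
    export_subsystems(qt, backend$dir, backend$format)
  }
  ri <- parse_res_key(key_i); rj <- parse_res_key(key_j)
  data.frame(key_i = key_i, chain_i = ri$chain, resno_i = ri$resno,
             resid_i = residue_atoms(structure, key_i)$resid[1],
             key_j = key_j, chain_j = rj$chain, resno_j = rj$resno,
             resid_j = residue_atoms(structure, key_j)$resid[1],
             energy = energy, backend_id = backend$id,
             pair_distance = min_residue_distance(structure, key_i, key_j,
                                                  heavy_only = TRUE),
             included_waters = length(qt$waters_i) + length(qt$waters_j),
             stringsAsFactors = FALSE)
}

#' Decompose a whole interface into residue-pair interaction energies
#'
#' Enumerates all cross-group residue pairs within `cutoff` and evaluates
#' each through the MFCC route.
#'
#' @inheritParams enumerate_pairs
#' @inheritParams pair_energy
#' @return data.frame of interaction records (class `interaction_records`),
#'   with the grand total in `attr(, "total")`.
#' @export
interface_energies <- function(structure, group_a, group_b,
                               backend = backend_config("classical"),
                               cutoff = 8.0, water_shell = NULL) {
  pairs <- enumerate_pairs(structure, group_a, group_b, cutoff)
  recs <- lapply(seq_len(nrow(pairs)), function(k)
    pair_energy(structure, pairs$key_i[k], pairs$key_j[k], backend, water_shell))
  out <- if (length(recs)) do.call(rbind, recs) else
    pair_energy_template()
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$energy)
  class(out) <- c("interaction_records", class(out))
  out
}

pair_energy_template <- function() {
  data.frame(key_i = character(), chain_i = character(), resno_i = integer(),
             resid_i = character(), key_j = character(), chain_j = character(),
             resno_j = integer(), resid_j = character(), energy = numeric(),
             backend_id = character(), pair_distance = numeric(),
             included_waters = integer(), stringsAsFactors = FALSE)
}

#' Export the four MFCC subsystems to coordinate files
#'
#' Files are named `pair_<i>_<j>_S1` .. `_S4` with the chosen extension.
#'
#' @param quartet a `subsystem_quartet`.
#' @param dir output directory (created if needed).
#' @param format `"pdb"` or `"xyz"`.
#' @return Character vector of the four file paths.
#' @export
export_subsystems <- function(quartet, dir, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- gsub(":", "", quartet$pair)
  paths <- character(4)
  for (k in 1:4) {
    s <- paste0("S", k)
    paths[k] <- file.path(dir, sprintf("pair_%s_%s_%s.%s",
                                       tag["i"], tag["j"], s, format))
    if (format == "pdb") write_pdb(quartet[[s]], paths[k])
    else write_xyz(quartet[[s]], paths[k])
  }
  paths
}

#' Minimal XYZ coordinate output
#'
#' @param structure a `Structure`.
#' @param path output path.
#' @export
write_xyz <- function(structure, path) {
  a <- structure$atoms
  lines <- c(as.character(nrow(a)), "generated by epitopedecomp",
             sprintf("%-2s %12.6f %12.6f %12.6f", a$elesy, a$x, a$y, a$z))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz` returns a data.frame with `elesy`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1])
  flds <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  data.frame(elesy = vapply(flds, `[`, "", 1),
             x = as.numeric(vapply(flds, `[`, "", 2)),
             y = as.numeric(vapply(flds, `[`, "", 3)),
             z = as.numeric(vapply(flds, `[`, "", 4)),
             stringsAsFactors = FALSE)
}
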