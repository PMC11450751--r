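# Synthetic desk-scale fixtures with known ground truth: ideal-geometry
# peptide chains, two-chain complexes with planted interface contacts, and
# clustered conformer ensembles.  Geometry is idealized (fixed bond lengths
# and angles, extended backbone, approximate rotamer templates), not
# physically relaxed.

unit3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# NeRF: place atom D given three reference atoms A-B-C, the C-D bond length,
# the B-C-D angle and the A-B-C-D torsion (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# approximate side-chain templates: atom, three reference atoms, bond length,
# angle, torsion.  References may be backbone (N, CA, C) or earlier template
# atoms.
SIDECHAIN_TOPO <- list(
  GLY = list(),
  ALA = list(),
  SER = list(c("OG", "N", "CA", "CB", "1.42", "110.5", "180")),
  CYS = list(c("SG", "N", "CA", "CB", "1.81", "114", "180")),
  THR = list(c("OG1", "N", "CA", "CB", "1.43", "109.5", "180"),
             c("CG2", "N", "CA", "CB", "1.52", "110.5", "-60")),
  VAL = list(c("CG1", "N", "CA", "CB", "1.52", "110.5", "180"),
             c("CG2", "N", "CA", "CB", "1.52", "110.5", "-60")),
  LEU = list(c("CG", "N", "CA", "CB", "1.53", "116", "180"),
             c("CD1", "CA", "CB", "CG", "1.52", "110.5", "180"),
             c("CD2", "CA", "CB", "CG", "1.52", "110.5", "-60")),
  ILE = list(c("CG1", "N", "CA", "CB", "1.53", "110.5", "180"),
             c("CG2", "N", "CA", "CB", "1.52", "110.5", "-60"),
             c("CD1", "CA", "CB", "CG1", "1.52", "114", "180")),
  MET = list(c("CG", "N", "CA", "CB", "1.52", "114", "180"),
             c("SD", "CA", "CB", "CG", "1.80", "112.7", "180"),
             c("CE", "CB", "CG", "SD", "1.79", "100.9", "180")),
  PRO = list(c("CG", "N", "CA", "CB", "1.49", "104", "30"),
             c("CD", "CA", "CB", "CG", "1.50", "105", "-35")),
  ASP = list(c("CG", "N", "CA", "CB", "1.52", "112.6", "180"),
             c("OD1", "CA", "CB", "CG", "1.25", "118.4", "90"),
             c("OD2", "CA", "CB", "CG", "1.25", "118.4", "-90")),
  ASN = list(c("CG", "N", "CA", "CB", "1.52", "112.6", "180"),
             c("OD1", "CA", "CB", "CG", "1.23", "120.8", "90"),
             c("ND2", "CA", "CB", "CG", "1.33", "116.4", "-90")),
  GLU = list(c("CG", "N", "CA", "CB", "1.52", "114", "180"),
             c("CD", "CA", "CB", "CG", "1.52", "112.6", "180"),
             c("OE1", "CB", "CG", "CD", "1.25", "118.4", "90"),
             c("OE2", "CB", "CG", "CD", "1.25", "118.4", "-90")),
  GLN = list(c("CG", "N", "CA", "CB", "1.52", "114", "180"),
             c("CD", "CA", "CB", "CG", "1.52", "112.6", "180"),
             c("OE1", "CB", "CG", "CD", "1.23", "120.8", "90"),
             c("NE2", "CB", "CG", "CD", "1.33", "116.4", "-90")),
  LYS = list(c("CG", "N", "CA", "CB", "1.52", "114", "180"),
             c("CD", "CA", "CB", "CG", "1.52", "111.3", "180"),
             c("CE", "CB", "CG", "CD", "1.52", "111.3", "180"),
             c("NZ", "CG", "CD", "CE", "1.49", "112", "180")),
  ARG = list(c("CG", "N", "CA", "CB", "1.52", "114", "180"),
             c("CD", "CA", "CB", "CG", "1.52", "111.3", "180"),
             c("NE", "CB", "CG", "CD", "1.46", "112", "180"),
             c("CZ", "CG", "CD", "NE", "1.33", "124.2", "180"),
             c("NH1", "CD", "NE", "CZ", "1.33", "120", "0"),
             c("NH2", "CD", "NE", "CZ", "1.33", "120", "180")),
  HIS = list(c("CG", "N", "CA", "CB", "1.49", "114", "180"),
             c("ND1", "CA", "CB", "CG", "1.38", "122.7", "90"),
             c("CD2", "CA", "CB", "CG", "1.35", "131", "-90"),
             c("CE1", "CB", "CG", "ND1", "1.32", "109", "180"),
             c("NE2", "CB", "CG", "CD2", "1.35", "107", "180")),
  PHE = list(c("CG", "N", "CA", "CB", "1.50", "114", "180"),
             c("CD1", "CA", "CB", "CG", "1.39", "120", "90"),
             c("CD2", "CA", "CB", "CG", "1.39", "120", "-90"),
             c("CE1", "CB", "CG", "CD1", "1.39", "120", "180"),
             c("CE2", "CB", "CG", "CD2", "1.39", "120", "180"),
             c("CZ", "CG", "CD1", "CE1", "1.39", "120", "0")),
  TYR = list(c("CG", "N", "CA", "CB", "1.50", "114", "180"),
             c("CD1", "CA", "CB", "CG", "1.39", "120", "90"),
             c("CD2", "CA", "CB", "CG", "1.39", "120", "-90"),
             c("CE1", "CB", "CG", "CD1", "1.39", "120", "180"),
             c("CE2", "CB", "CG", "CD2", "1.39", "120", "180"),
             c("CZ", "CG", "CD1", "CE1", "1.39", "120", "0"),
             c("OH", "CD1", "CE1", "CZ", "1.38", "120", "180")),
  TRP = list(c("CG", "N", "CA", "CB", "1.50", "114", "180"),
             c("CD1", "CA", "CB", "CG", "1.37", "127", "90"),
             c("CD2", "CA", "CB", "CG", "1.43", "126", "-90"),
             c("NE1", "CB", "CG", "CD1", "1.38", "110", "180"),
             c("CE2", "CB", "CG", "CD2", "1.41", "107", "180"),
             c("CE3", "CB", "CG", "CD2", "1.40", "134", "0"),
             c("CZ2", "CG", "CD2", "CE2", "1.40", "122", "180"),
             c("CZ3", "CG", "CD2", "CE3", "1.39", "118", "180"),
             c("CH2", "CD2", "CE3", "CZ3", "1.37", "121", "0")))

# backbone internal coordinates (extended conformation)
BB_N_CA <- 1.458; BB_CA_C <- 1.525; BB_C_N <- 1.329; BB_C_O <- 1.231
ANG_N_CA_C <- 111.0; ANG_CA_C_N <- 116.6; ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.5

#' Build an ideal-geometry peptide chain
#'
#' Extended backbone (phi = psi = omega = 180 degrees) grown by internal
#' coordinates, with approximate idealized side-chain rotamer templates and,
#' optionally, backbone amide hydrogens.  Intended for synthetic fixtures,
#' not for physical modelling.
#'
#' @param sequence one-letter amino-acid string.
#' @param chain chain id.
#' @param start_resno first residue number.
#' @param with_hydrogens logical; add backbone amide hydrogens.
#' @return A `Structure`.
#' @export
build_peptide <- function(sequence, chain = "A", start_resno = 1L,
                          with_hydrogens = FALSE) {
  res3 <- aa_one_to_three(sequence)
  n <- length(res3)
  rows <- list()
  add <- function(elety, resid, resno, pos, elesy = substr(elety, 1, 1)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "ATOM", eleno = 0L, elety = elety, resid = resid, chain = chain,
      resno = resno, insert = "", x = pos[1], y = pos[2], z = pos[3],
      o = 1, b = 0, elesy = elesy, charge = NA_real_, fill = FALSE,
      stringsAsFactors = FALSE)
  }
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n)) {
    resno <- start_resno + i - 1L
    if (i == 1L) {
      Ni <- c(0, 0, 0)
      CAi <- c(BB_N_CA, 0, 0)
      ang <- ANG_N_CA_C * pi / 180
      Ci <- CAi + BB_CA_C * c(-cos(ang), sin(ang), 0)
    } else {
      Ni <- place_atom(prevN, prevCA, prevC, BB_C_N, ANG_CA_C_N, 180)
      CAi <- place_atom(prevCA, prevC, Ni, BB_N_CA, ANG_C_N_CA, 180)
      Ci <- place_atom(prevC, Ni, CAi, BB_CA_C, ANG_N_CA_C, 180)
    }
    Oi <- place_atom(Ni, CAi, Ci, BB_C_O, ANG_CA_C_O, 0)
    add("N", res3[i], resno, Ni)
    if (with_hydrogens && res3[i] != "PRO") {
      Hi <- if (i == 1L) Ni + c(0, 0, 1) else
        Ni + unit3(unit3(Ni - prevC) + unit3(Ni - CAi))
      add("H", res3[i], resno, Hi, elesy = "H")
    }
    add("CA", res3[i], resno, CAi)
    pos_tab <- list(N = Ni, CA = CAi, C = Ci)
    if (res3[i] != "GLY") {
      CBi <- place_atom(Ci, Ni, CAi, 1.53, 110.5, 122.5)
      add("CB", res3[i], resno, CBi)
      pos_tab$CB <- CBi
      for (tmpl in SIDECHAIN_TOPO[[res3[i]]]) {
        p <- place_atom(pos_tab[[tmpl[2]]], pos_tab[[tmpl[3]]],
                        pos_tab[[tmpl[4]]], as.numeric(tmpl[5]),
                        as.numeric(tmpl[6]), as.numeric(tmpl[7]))
        add(tmpl[1], res3[i], resno, p)
        pos_tab[[tmpl[1]]] <- p
      }
    }
    add("C", res3[i], resno, Ci)
    add("O", res3[i], resno, Oi)
    prevN <- Ni; prevCA <- CAi; prevC <- Ci
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure(atoms)
}

#' Specify a synthetic two-chain complex with planted contacts
#'
#' @param n_res residues per chain (default 6; poly-alanine unless planted
#'   contacts require specific residue types, or sequences are supplied).
#' @param contacts list of planted contacts, each a list with `type`
#'   (`"hbond"`, `"hydrophobic"`, `"salt_bridge"`), `res_a`, `res_b` (residue
#'   numbers in chains A and B) and `dist` (target anchor distance, A).
#'   Targets must lie inside the corresponding detection window.
#' @param charges `"zero"` or `"random"` (uniform in \[-0.3, 0.3\] e per
#'   atom, seeded).
#' @param seq_a,seq_b optional one-letter sequences overriding the defaults.
#' @param separation chain A to chain B baseline offset (A).
#' @param with_hydrogens logical; include backbone amide hydrogens.
#' @param seed integer seed.
#' @return An object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_res = 6L, contacts = list(),
                             charges = c("zero", "random"),
                             seq_a = NULL, seq_b = NULL, separation = 10,
                             with_hydrogens = TRUE, seed = 1L) {
  charges <- match.arg(charges)
  crit <- contact_criteria()
  win <- list(hbond = c(0, crit$hbond_da_max),
              hydrophobic = c(crit$hydrophobic_min, crit$hydrophobic_max),
              salt_bridge = c(0, crit$salt_bridge_max))
  for (ct in contacts) {
    if (!ct$type %in% names(win)) stop("unknown contact type: ", ct$type)
    if (ct$dist < win[[ct$type]][1] || ct$dist > win[[ct$type]][2])
      stop("target distance ", ct$dist, " outside the ", ct$type,
           " detection window")
    if (ct$res_a < 1 || ct$res_a > n_res || ct$res_b < 1 || ct$res_b > n_res)
      stop("planted contact residue outside 1..n_res")
  }
  structure(list(n_res = as.integer(n_res), contacts = contacts,
                 charges = charges, seq_a = seq_a, seq_b = seq_b,
                 separation = separation, with_hydrogens = with_hydrogens,
                 seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# anchor atom names per planted-contact type (chain A side, chain B side).
# Anchors sit on side-chain tips (or the backbone amide for the donor) so a
# planted geometry does not drag neighbouring atoms into the detection
# windows.
contact_anchors <- function(type) {
  switch(type,
         hbond = c("OG", "N"),           # Ser acceptor on A, amide donor on B
         hydrophobic = c("CD1", "CD1"),  # Leu apolar tips
         salt_bridge = c("OE1", "NZ"),   # Glu carboxylate vs Lys amine
         stop("unknown contact type: ", type))
}

# rigid placement of chain B so its anchor atoms hit the target points:
# translation only for one anchor; for two anchors the roll about the
# anchor axis is fixed by an "up" pseudo-point; three or more use Kabsch
rigid_place <- function(xyz, anchors, targets) {
  n <- nrow(anchors)
  if (n == 1L) return(sweep(xyz, 2, targets[1, ] - anchors[1, ], `+`))
  if (n == 2L) {
    up <- c(0, 1, 0)
    anchors <- rbind(anchors, colMeans(anchors) + up)
    targets <- rbind(targets, colMeans(targets) + up)
  }
  k <- kabsch(anchors, targets)
  sweep(sweep(xyz, 2, k$cm) %*% t(k$R), 2, k$cq, `+`)
}

#' Generate a synthetic two-chain complex with known ground truth
#'
#' Chain A runs along x; chain B is built with the same ideal geometry,
#' rotated to cross over chain A, and rigidly placed so each planted
#' contact's anchor-atom pair meets its target distance (within 0.05 A, else
#' a generation error).  Residue types at planted positions are set to Ala
#' (hydrophobic, via CB) and Glu/Lys (salt bridge) as needed.  The returned
#' ground truth contains the planted contact table and the exact
#' residue-pair interaction energies under the classical backend (the direct
#' cross-residue sums).
#'
#' @param spec a [toy_complex_spec()].
#' @param dielectric dielectric constant for the ground-truth energies.
#' @return List with `structure` (a `Structure`), `truth_contacts`
#'   (data.frame `type`, `res_a`, `res_b`, `dist`), and `truth_energies`
#'   (data.frame `key_i`, `key_j`, `dist`, `energy` for all cross pairs
#'   within 8 A).
#' @export
make_toy_complex <- function(spec, dielectric = 40) {
  set.seed(spec$seed)
  seq_a <- if (is.null(spec$seq_a)) strrep("A", spec$n_res) else spec$seq_a
  seq_b <- if (is.null(spec$seq_b)) strrep("A", spec$n_res) else spec$seq_b
  sa <- strsplit(seq_a, "")[[1]]; sb <- strsplit(seq_b, "")[[1]]
  for (ct in spec$contacts) {
    if (ct$type == "salt_bridge") { sa[ct$res_a] <- "E"; sb[ct$res_b] <- "K" }
    if (ct$type == "hbond") {
      sa[ct$res_a] <- "S"
      # glycines around the amide donor keep stray side-chain carbons out of
      # the hydrophobic window
      sb[max(1, ct$res_b - 1):min(spec$n_res, ct$res_b + 1)] <- "G"
    }
    if (ct$type == "hydrophobic") { sa[ct$res_a] <- "L"; sb[ct$res_b] <- "L" }
  }
  A <- build_peptide(paste(sa, collapse = ""), chain = "A",
                     with_hydrogens = spec$with_hydrogens)
  B <- build_peptide(paste(sb, collapse = ""), chain = "B",
                     with_hydrogens = spec$with_hydrogens)
  # Chains are built with the backbone plane in xy and side chains along
  # +-z.  Lay chain A's backbone plane horizontal (rotate 90 degrees about
  # its x axis) with the planted anchor's side-chain mast pointing up toward
  # the interface.
  if (length(spec$contacts)) {
    ct1 <- spec$contacts[[1]]
    anA <- contact_anchors(ct1$type)[1]
    xyzA <- coords(A$atoms)
    bbA <- A$atoms$elety %in% c("N", "CA", "C", "O")
    za <- get_atom(A, res_key("A", ct1$res_a), anA)$z
    s <- if (length(za) == 1L && za < mean(xyzA[bbA, 3])) -1 else 1
    # rotate about x by -+90 degrees: z offsets become +-y
    A <- set_coords(A, cbind(xyzA[, 1], s * xyzA[, 3], -s * xyzA[, 2]))
  }
  # rotate B to run along z with a horizontal backbone plane (cyclic axis
  # permutation, a proper rotation), crossing over A; flip it half a turn
  # about its own axis so the anchor faces the interface: side-chain mast
  # anchors point down toward A, while for the backbone amide donor the
  # anchor residue's CB points up (keeping polar backbone atoms highest)
  xyzB <- coords(B$atoms) %*%
    t(matrix(c(0, 0, 1,  1, 0, 0,  0, 1, 0), 3, 3))  # x->z, y->x, z->y
  if (length(spec$contacts)) {
    ct1 <- spec$contacts[[1]]
    if (ct1$type == "hbond") { orient <- "CB"; want_up <- TRUE }
    else { orient <- contact_anchors(ct1$type)[2]; want_up <- FALSE }
    B1 <- set_coords(B, xyzB)
    bbB <- B$atoms$elety %in% c("N", "CA", "C", "O")
    oy <- get_atom(B1, res_key("B", ct1$res_b), orient)$y
    if (length(oy) == 1L && (oy > mean(xyzB[bbB, 2])) != want_up)
      xyzB[, c(1, 2)] <- -xyzB[, c(1, 2)]
  }
  xyzB[, 2] <- xyzB[, 2] + spec$separation
  B <- set_coords(B, xyzB)
  if (length(spec$contacts)) {
    anchors_b <- NULL; targets <- NULL
    for (ct in spec$contacts) {
      an <- contact_anchors(ct$type)
      pa <- as.numeric(get_atom(A, res_key("A", ct$res_a), an[1])[, c("x", "y", "z")])
      pb <- as.numeric(get_atom(B, res_key("B", ct$res_b), an[2])[, c("x", "y", "z")])
      if (length(pa) != 3 || length(pb) != 3)
        stop("anchor atom missing for planted ", ct$type)
      anchors_b <- rbind(anchors_b, pb)
      targets <- rbind(targets, pa + c(0, ct$dist, 0))
    }
    B <- set_coords(B, rigid_place(coords(B$atoms), anchors_b, targets))
    # salt bridges are detected on the minimum charged-group distance, which
    # can be shorter than the anchor pair (the other carboxylate oxygen);
    # nudge B vertically until the group minimum hits the target
    sb_group_min <- function(ct) {
      oa <- residue_atoms(A, res_key("A", ct$res_a))
      ob <- residue_atoms(B, res_key("B", ct$res_b))
      min(cross_dist(coords(oa[oa$elety %in% SB_ACIDIC$GLU, , drop = FALSE]),
                     coords(ob[ob$elety %in% SB_BASIC$LYS, , drop = FALSE])))
    }
    if (length(spec$contacts) == 1L && spec$contacts[[1]]$type == "salt_bridge") {
      ct <- spec$contacts[[1]]
      for (it in 1:8) {
        m <- sb_group_min(ct)
        if (abs(m - ct$dist) <= 0.02) break
        B <- set_coords(B, sweep(coords(B$atoms), 2, c(0, m - ct$dist, 0)))
      }
    }
    for (i in seq_along(spec$contacts)) {
      ct <- spec$contacts[[i]]
      an <- contact_anchors(ct$type)
      achieved <- if (ct$type == "salt_bridge") sb_group_min(ct) else {
        pa <- as.numeric(get_atom(A, res_key("A", ct$res_a), an[1])[, c("x", "y", "z")])
        pb <- as.numeric(get_atom(B, res_key("B", ct$res_b), an[2])[, c("x", "y", "z")])
        sqrt(sum((pa - pb)^2))
      }
      if (abs(achieved - ct$dist) > 0.05)
        stop("infeasible contact set: planted ", ct$type, " #", i,
             " missed its target distance")
    }
    # point each planted hydrogen-bond donor H along the D -> A axis
    if (spec$with_hydrogens) {
      for (ct in spec$contacts) {
        if (ct$type != "hbond") next
        key_b <- res_key("B", ct$res_b)
        an <- contact_anchors("hbond")
        dn <- as.numeric(get_atom(B, key_b, an[2])[, c("x", "y", "z")])
        ac <- as.numeric(get_atom(A, res_key("A", ct$res_a), an[1])[, c("x", "y", "z")])
        hpos <- dn + unit3(ac - dn) * 1.0
        hi <- which(atom_res_keys(B$atoms) == key_b & B$atoms$elety == "H")
        if (length(hi) == 1L) B$atoms[hi, c("x", "y", "z")] <- hpos
      }
    }
  }
  atoms <- rbind(A$atoms, B$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  if (spec$charges == "random") atoms$charge <- runif(nrow(atoms), -0.3, 0.3)
  else atoms$charge <- 0
  st <- new_structure(atoms)
  truth_contacts <- if (length(spec$contacts))
    do.call(rbind, lapply(spec$contacts, function(ct)
      data.frame(type = ct$type, res_a = ct$res_a, res_b = ct$res_b,
                 dist = ct$dist, stringsAsFactors = FALSE)))
  else data.frame(type = character(), res_a = integer(), res_b = integer(),
                  dist = numeric(), stringsAsFactors = FALSE)
  pairs <- enumerate_pairs(st, "A", "B", cutoff = 8.0)
  truth_energies <- data.frame(
    key_i = pairs$key_i, key_j = pairs$key_j, dist = pairs$dist,
    energy = vapply(seq_len(nrow(pairs)), function(k)
      direct_pair_energy(st, pairs$key_i[k], pairs$key_j[k], dielectric), 0),
    stringsAsFactors = FALSE)
  list(structure = st, truth_contacts = truth_contacts,
       truth_energies = truth_energies)
}

#' Specify a planted multi-mode conformer ensemble
#'
#' @param k_modes number of distinct perturbation modes.
#' @param n_frames frames drawn per mode.
#' @param sigma isotropic Gaussian noise per coordinate (A).
#' @param magnitude displacement magnitude of a mode's moved residues (A).
#' @param frac_moved fraction of residues displaced by each mode.
#' @param seed integer seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(k_modes = 3L, n_frames = 20L, sigma = 0.3,
                          magnitude = 3.0, frac_moved = 0.4, seed = 1L) {
  if (k_modes < 1L) stop("k_modes must be at least 1")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(k_modes = as.integer(k_modes), n_frames = as.integer(n_frames),
                 sigma = sigma, magnitude = magnitude,
                 frac_moved = frac_moved, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Draw a conformer ensemble from k Gaussian perturbation modes
#'
#' Each mode displaces a random subset of residues by a fixed random
#' direction of length `magnitude`; frames are the mode centre plus
#' isotropic Gaussian noise of width `sigma`.  Mode centres must be mutually
#' separated by more than five noise widths (RMS over coordinates), which
#' guarantees the planted partition is recoverable; violations are an error.
#'
#' @param base a `Structure` (the reference conformation).
#' @param spec an [ensemble_spec()].
#' @return List with `trajectory` (a `Trajectory`), `labels` (true mode of
#'   each frame) and `mode_centers` (list of coordinate matrices).
#' @export
make_conformers <- function(base, spec) {
  set.seed(spec$seed)
  x0 <- coords(base$atoms)
  rt <- residue_table(base)
  keys <- atom_res_keys(base$atoms)
  centers <- list()
  for (m in seq_len(spec$k_modes)) {
    moved <- sample(rt$key, max(1L, round(spec$frac_moved * nrow(rt))))
    disp <- matrix(0, nrow(x0), 3)
    for (k in moved) {
      dirv <- unit3(rnorm(3)) * spec$magnitude
      disp[keys == k, ] <- rep(dirv, each = sum(keys == k))
    }
    centers[[m]] <- x0 + disp
  }
  if (spec$k_modes > 1L && spec$sigma > 0) {
    for (m1 in seq_len(spec$k_modes - 1L)) for (m2 in (m1 + 1L):spec$k_modes) {
      rms <- sqrt(mean((centers[[m1]] - centers[[m2]])^2))
      if (rms <= 5 * spec$sigma)
        stop("mode centres ", m1, " and ", m2, " are separated by ",
             signif(rms, 3), " A RMS, not more than 5*sigma; ",
             "increase magnitude or lower sigma")
    }
  }
  frames <- list(); labels <- integer()
  for (m in seq_len(spec$k_modes)) for (f in seq_len(spec$n_frames)) {
    noise <- matrix(rnorm(length(x0), sd = spec$sigma), nrow(x0), 3)
    frames[[length(frames) + 1L]] <- set_coords(base, centers[[m]] + noise)
    labels <- c(labels, m)
  }
  list(trajectory = as_trajectory(frames), labels = labels,
       mode_centers = centers)
}

#' Sequence-level point mutation with an idealized side chain
#'
#' Replaces the residue's side chain by the idealized rotamer template of the
#' target residue, built on the unmoved backbone; the result is flagged
#' approximate (b-factor column set to 1 for rebuilt atoms).
#'
#' @param base a `Structure`.
#' @param site residue key of the mutation site.
#' @param to target residue (one- or three-letter code).
#' @return The mutated `Structure`.
#' @export
make_mutant <- function(base, site, to) {
  to3 <- if (nchar(to) == 1L) aa_one_to_three(to) else toupper(to)
  if (!to3 %in% AA_THREE) stop("unknown target residue: ", to)
  ra <- residue_atoms(base, site)
  if (nrow(ra) == 0L) stop("residue not found: ", site)
  if (ra$resid[1] == to3) return(base)
  keys <- atom_res_keys(base$atoms)
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HN")
  keep <- keys != site | base$atoms$elety %in% backbone
  atoms <- base$atoms[keep, , drop = FALSE]
  atoms$resid[atom_res_keys(atoms) == site] <- to3
  bb <- function(n) as.numeric(ra[ra$elety == n, c("x", "y", "z")])
  Ni <- bb("N"); CAi <- bb("CA"); Ci <- bb("C")
  if (length(Ni) != 3 || length(CAi) != 3 || length(Ci) != 3)
    stop("mutation site lacks a complete backbone")
  new_rows <- list()
  pos_tab <- list(N = Ni, CA = CAi, C = Ci)
  if (to3 != "GLY") {
    pos_tab$CB <- place_atom(Ci, Ni, CAi, 1.53, 110.5, 122.5)
    names_new <- "CB"
    for (tmpl in SIDECHAIN_TOPO[[to3]]) {
      pos_tab[[tmpl[1]]] <- place_atom(pos_tab[[tmpl[2]]], pos_tab[[tmpl[3]]],
                                       pos_tab[[tmpl[4]]], as.numeric(tmpl[5]),
                                       as.numeric(tmpl[6]), as.numeric(tmpl[7]))
      names_new <- c(names_new, tmpl[1])
    }
    ref <- parse_res_key(site)
    for (nm in names_new) {
      p <- pos_tab[[nm]]
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        type = "ATOM", eleno = 0L, elety = nm, resid = to3,
        chain = ref$chain, resno = ref$resno, insert = ref$insert,
        x = p[1], y = p[2], z = p[3], o = 1, b = 1,
        elesy = substr(nm, 1, 1), charge = NA_real_, fill = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  # insert the rebuilt side chain right after the site's backbone atoms
  at_site <- which(atom_res_keys(atoms) == site)
  ins <- max(at_site)
  atoms <- rbind(atoms[seq_len(ins), , drop = FALSE],
                 if (length(new_rows)) do.call(rbind, new_rows),
                 atoms[-seq_len(ins), , drop = FALSE])
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure(atoms, model_id = base$model_id)
}
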