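# Fixed chemistry tables: residue codes, hydrogen-bond donor/acceptor atoms,
# apolar carbons, average residue masses, pKa sets, and the small nonbonded
# parameter set used by the classical energy backend.

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA_ONE <- setNames(names(AA_THREE), AA_THREE)

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return The converted codes.
#' @export
aa_three_to_one <- function(x) {
  out <- AA_ONE[toupper(x)]
  if (any(is.na(out))) stop("unknown residue name(s): ",
                            paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  letters1 <- strsplit(toupper(paste(x, collapse = "")), "")[[1]]
  out <- AA_THREE[letters1]
  if (any(is.na(out))) stop("unknown amino-acid letter(s): ",
                            paste(unique(letters1[is.na(out)]), collapse = ", "))
  unname(out)
}

# Hydrogen-bond chemistry: N/O/S donors bearing hydrogens, N/O acceptors.
# Backbone N is a donor for all residues except proline; backbone O (and a
# terminal OXT) is always an acceptor.  His side-chain nitrogens are treated
# as both donor and acceptor.
HB_DONOR_SIDE <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", CYS = "SG", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH")

HB_ACCEPTOR_SIDE <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH")

hb_donor_atoms <- function(resid) {
  resid <- toupper(resid)
  if (is_water_resid(resid)) return("O")
  c(if (resid != "PRO") "N", HB_DONOR_SIDE[[resid]])
}

hb_acceptor_atoms <- function(resid) {
  resid <- toupper(resid)
  if (is_water_resid(resid)) return("O")
  c("O", "OXT", HB_ACCEPTOR_SIDE[[resid]])
}

# Apolar carbons: carbons not covalently bonded to N or O.
APOLAR_CARBONS <- list(
  ALA = "CB", ARG = c("CB", "CG"), ASN = "CB", ASP = "CB", CYS = "CB",
  GLN = c("CB", "CG"), GLU = c("CB", "CG"), GLY = character(),
  HIS = "CB", ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"), LYS = c("CB", "CG", "CD"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"), SER = character(), THR = "CG2",
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2"))

# Charged groups used for salt-bridge detection.
SB_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SB_BASIC  <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                  HIS = c("ND1", "NE2"))

# Average (isotope-weighted) residue masses, Da; plus one water per chain.
AA_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS_AVG <- 18.01524

# Bjellqvist pKa set (ProtParam convention): side chains, C-terminus, and
# residue-specific N-terminal pKa values.
PK_POSITIVE <- c(K = 10.0, R = 12.0, H = 5.98)
PK_NEGATIVE <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PK_CTERM <- 3.55
PK_CTERM_SIDE <- c(D = 4.55, E = 4.75)  # side-chain pKa when C-terminal
PK_NTERM_DEFAULT <- 7.5
PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
              V = 7.44, E = 7.70, G = 7.50)

# Lennard-Jones parameters per element (kcal/mol; Rmin/2 in Angstrom).
# Hydrogens carry no LJ term in this coarse stand-in model.
LJ_PARAMS <- list(
  C = c(eps = 0.110, rmin2 = 2.00),
  N = c(eps = 0.200, rmin2 = 1.85),
  O = c(eps = 0.120, rmin2 = 1.70),
  S = c(eps = 0.450, rmin2 = 2.00),
  H = c(eps = 0.000, rmin2 = 1.00))

# Coarse heavy-atom partial charges (e) for the classical backend: backbone
# amide dipole plus formal charges spread over the charged side-chain groups.
# Atoms not listed are neutral.  Structures may override these with an
# explicit per-atom `charge` column (the synthetic generators do).
BACKBONE_CHARGES <- c(N = -0.35, CA = 0.10, C = 0.45, O = -0.45, OXT = -0.45,
                      H = 0.25, HN = 0.25)
SIDECHAIN_CHARGES <- list(
  ASP = c(CG = 0.30, OD1 = -0.65, OD2 = -0.65),
  GLU = c(CD = 0.30, OE1 = -0.65, OE2 = -0.65),
  LYS = c(CE = 0.25, NZ = 0.75),
  ARG = c(CZ = 0.50, NH1 = 0.25, NH2 = 0.25),
  HIS = c(ND1 = -0.30, NE2 = -0.30, CE1 = 0.25),
  SER = c(CB = 0.25, OG = -0.50),
  THR = c(CB = 0.25, OG1 = -0.50),
  TYR = c(CZ = 0.25, OH = -0.50),
  ASN = c(CG = 0.45, OD1 = -0.45, ND2 = -0.30),
  GLN = c(CD = 0.45, OE1 = -0.45, NE2 = -0.30),
  CYS = c(CB = 0.10, SG = -0.20),
  TRP = c(NE1 = -0.30, CD1 = 0.15, CE2 = 0.15))
WATER_CHARGES <- c(O = -0.834, H1 = 0.417, H2 = 0.417, OW = -0.834,
                   HW1 = 0.417, HW2 = 0.417)

lookup_charges <- function(atoms) {
  q <- atoms$charge
  miss <- is.na(q)
  if (any(miss)) {
    qt <- numeric(sum(miss))
    resid <- toupper(atoms$resid[miss]); elety <- atoms$elety[miss]
    for (i in seq_along(qt)) {
      if (is_water_resid(resid[i])) {
        qt[i] <- if (elety[i] %in% names(WATER_CHARGES)) WATER_CHARGES[[elety[i]]] else 0
      } else if (elety[i] %in% names(BACKBONE_CHARGES)) {
        qt[i] <- BACKBONE_CHARGES[[elety[i]]]
      } else {
        sc <- SIDECHAIN_CHARGES[[resid[i]]]
        qt[i] <- if (!is.null(sc) && elety[i] %in% names(sc)) sc[[elety[i]]] else 0
      }
    }
    q[miss] <- qt
  }
  # fill hydrogens are geometric placeholders with no nonbonded parameters
  q[atoms$fill] <- 0
  q
}

lookup_lj <- function(atoms) {
  ele <- atoms$elesy
  eps <- vapply(ele, function(e)
    if (e %in% names(LJ_PARAMS)) LJ_PARAMS[[e]][["eps"]] else LJ_PARAMS$C[["eps"]],
    0)
  rmin2 <- vapply(ele, function(e)
    if (e %in% names(LJ_PARAMS)) LJ_PARAMS[[e]][["rmin2"]] else LJ_PARAMS$C[["rmin2"]],
    0)
  eps[atoms$fill] <- 0
  cbind(eps = unname(eps), rmin2 = unname(rmin2))
}
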