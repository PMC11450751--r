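# Shared fixtures, all generated in code.

# two short chains with one planted contact
planted_toy <- function(type, res_a = 3, res_b = 3, dist = 2.9, n_res = 6,
                        seed = 1, charges = "zero") {
  make_toy_complex(toy_complex_spec(
    n_res = n_res,
    contacts = list(list(type = type, res_a = res_a, res_b = res_b,
                         dist = dist)),
    charges = charges, seed = seed))
}

# an antibody-Fv-like synthetic complex: heavy chain H 1-126 (CDR2 50-60 and
# CDR3 101-109 carry the real segment sequences), light chain L 1-109
# (CDR3 90-96), and a 6-residue epitope chain A numbered 2-7 (amyloid-beta
# residues 2-7).  Chains are placed far apart; only identities/numbering
# matter for the tests that use it.
adu_like_structure <- function() {
  hseq <- strsplit(strrep("A", 126), "")[[1]]
  hseq[50:60] <- strsplit("VIWFDGTKKYY", "")[[1]]
  hseq[101:109] <- strsplit("GIGARRGPY", "")[[1]]
  lseq <- strsplit(strrep("A", 109), "")[[1]]
  lseq[90:96] <- strsplit("QSYSTPL", "")[[1]]
  h <- build_peptide(paste(hseq, collapse = ""), chain = "H")
  l <- build_peptide(paste(lseq, collapse = ""), chain = "L")
  ab <- build_peptide("AEFRHD", chain = "A", start_resno = 2)
  lx <- coords(l$atoms); lx[, 2] <- lx[, 2] + 40
  ax <- coords(ab$atoms); ax[, 2] <- ax[, 2] + 20
  l <- set_coords(l, lx)
  ab <- set_coords(ab, ax)
  atoms <- rbind(h$atoms, l$atoms, ab$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure(atoms)
}

# the eight mimetic peptides characterized in the reference tables
reference_peptides <- function() {
  list(
    list(name = "Pep-H2-L",  seq = "VIWFDGTKKYY",   cyclic = FALSE,
         mw = 1419.64, pi = 8.40,  charge = 1L,
         chymo_high = 4L, chymo_low = 4L, pepsin13 = 2L, pepsin2 = 4L,
         trypsin = 2L),
    list(name = "Pep-H2-C",  seq = "CVIWFDGTKKYYC", cyclic = TRUE,
         mw = 1625.92, pi = 8.02,  charge = 1L,
         chymo_high = 4L, chymo_low = 4L, pepsin13 = 2L, pepsin2 = 4L,
         trypsin = 2L),
    list(name = "Pep-H3-L",  seq = "GIGARRGPY",     cyclic = FALSE,
         mw = 946.08,  pi = 10.84, charge = 2L,
         chymo_high = 1L, chymo_low = 1L, pepsin13 = 0L, pepsin2 = 0L,
         trypsin = 2L),
    list(name = "Pep-H3-C",  seq = "CGIGARRGPYC",   cyclic = TRUE,
         mw = 1152.35, pi = 8.96,  charge = 2L,
         chymo_high = 1L, chymo_low = 1L, pepsin13 = 0L, pepsin2 = 0L,
         trypsin = 2L),
    list(name = "Pep-L3-L1", seq = "QSYSTPL",       cyclic = FALSE,
         mw = 794.86,  pi = 5.52,  charge = 0L,
         chymo_high = 1L, chymo_low = 2L, pepsin13 = 1L, pepsin2 = 3L,
         trypsin = 0L),
    list(name = "Pep-L3-C1", seq = "CQSYSTPLC",     cyclic = TRUE,
         mw = 1001.14, pi = 5.51,  charge = 0L,
         chymo_high = 1L, chymo_low = 2L, pepsin13 = 1L, pepsin2 = 3L,
         trypsin = 0L),
    list(name = "Pep-L3-L2", seq = "QYYSTPL",       cyclic = FALSE,
         mw = 870.96,  pi = 5.52,  charge = 0L,
         chymo_high = 2L, chymo_low = 3L, pepsin13 = 1L, pepsin2 = 4L,
         trypsin = 0L),
    list(name = "Pep-L3-C2", seq = "CQYYSTPLC",     cyclic = TRUE,
         mw = 1077.23, pi = 5.51,  charge = 0L,
         chymo_high = 2L, chymo_low = 3L, pepsin13 = 1L, pepsin2 = 4L,
         trypsin = 0L))
}

# published per-residue interaction energies (final conformations) shipped
# as a plain-text fixture
reference_energy_fixture <- function() {
  read.csv(system.file("extdata", "adu_abeta_fc_residue_energies.csv",
                       package = "epitopedecomp"), stringsAsFactors = FALSE)
}

# append a single water molecule at an offset from a named atom
add_water <- function(structure, near_key, near_atom, offset,
                      resno = 1L, charge = -0.8) {
  ra <- residue_atoms(structure, near_key)
  p <- as.numeric(ra[ra$elety == near_atom, c("x", "y", "z")]) + offset
  wat <- data.frame(type = "HETATM", eleno = 0L, elety = "O", resid = "HOH",
                    chain = "W", resno = resno, insert = "",
                    x = p[1], y = p[2], z = p[3], o = 1, b = 0, elesy = "O",
                    charge = charge, fill = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(structure$atoms, wat)
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure(atoms)
}
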