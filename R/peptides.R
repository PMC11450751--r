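#' Construct a peptide record
#'
#' @param sequence one-letter amino-acid sequence (20 standard letters).
#' @param name peptide name.
#' @param cyclic logical; head-to-tail disulfide-cyclized via terminal
#'   cysteines.
#' @param source optional [region_def()] the sequence was extracted from.
#' @param mutations list of applied mutations, each `c(position, from, to)`.
#' @return An object of class `peptide_record`.
#' @export
peptide_record <- function(sequence, name = NA_character_, cyclic = FALSE,
                           source = NULL, mutations = list()) {
  sequence <- toupper(sequence)
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) == 0L) stop("empty peptide sequence")
  if (!all(letters1 %in% names(AA_THREE)))
    stop("invalid amino-acid letter(s): ",
         paste(unique(letters1[!letters1 %in% names(AA_THREE)]), collapse = ", "))
  if (cyclic && (letters1[1] != "C" || letters1[length(letters1)] != "C"))
    stop("cyclic peptides must start and end with cysteine")
  structure(list(name = name, sequence = sequence, cyclic = cyclic,
                 source = source, mutations = mutations),
            class = "peptide_record")
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(if (is.na(x$name)) "peptide" else x$name, ": ", x$sequence,
      if (x$cyclic) " (cyclic, terminal disulfide)" else " (linear)",
      "\n", sep = "")
  if (length(x$mutations))
    cat("  mutations:",
        paste(vapply(x$mutations, function(m)
          paste0(m[2], m[1], m[3]), ""), collapse = ", "), "\n")
  invisible(x)
}

pep_seq <- function(x) if (inherits(x, "peptide_record")) x$sequence else
  toupper(as.character(x))

#' Extract a region's sequence from a structure as a linear peptide
#'
#' @param structure a `Structure`.
#' @param region a [region_def()].
#' @param name peptide name (defaults to the region name).
#' @return A linear `peptide_record` with the region recorded as source.
#' @export
extract_segment <- function(structure, region, name = region$name) {
  cr <- chain_residues(structure, region$chain)
  rows <- cr[vapply(cr$resno, function(n) region_member(region, region$chain, n),
                    TRUE), , drop = FALSE]
  expected <- sum(vapply(region$ranges, function(r) r[2] - r[1] + 1, 0))
  if (nrow(rows) == 0L) stop("region ", region$name, " matches no residues")
  if (nrow(rows) != expected)
    stop("missing residue(s) in region ", region$name, ": found ",
         nrow(rows), " of ", expected)
  peptide_record(paste(aa_three_to_one(rows$resid), collapse = ""),
                 name = name, source = region)
}

#' Apply a point substitution to a peptide
#'
#' @param peptide a `peptide_record`.
#' @param position residue position: author numbering of the source region
#'   when the peptide has one, else a 1-based index.
#' @param to one-letter code of the replacement residue.
#' @return The mutated `peptide_record`, with the mutation logged (identity
#'   substitutions are logged too, the sequence unchanged).
#' @export
mutate_peptide <- function(peptide, position, to) {
  to <- toupper(to)
  if (!to %in% names(AA_THREE)) stop("invalid replacement letter: ", to)
  letters1 <- strsplit(peptide$sequence, "")[[1]]
  idx <- position
  if (!is.null(peptide$source)) {
    offs <- 0L; idx <- NA_integer_
    for (r in peptide$source$ranges) {
      if (position >= r[1] && position <= r[2]) { idx <- offs + position - r[1] + 1L; break }
      offs <- offs + r[2] - r[1] + 1L
    }
    if (is.na(idx)) stop("position ", position, " outside source region ",
                         peptide$source$name)
  }
  if (is.na(idx) || idx < 1 || idx > length(letters1))
    stop("position ", position, " out of range")
  from <- letters1[idx]
  letters1[idx] <- to
  peptide_record(paste(letters1, collapse = ""), name = peptide$name,
                 cyclic = peptide$cyclic, source = peptide$source,
                 mutations = c(peptide$mutations,
                               list(c(position = position, from = from, to = to))))
}

#' Cyclize a linear peptide via terminal cysteines
#'
#' Adds one cysteine to each terminus (the disulfide partner pair), flags the
#' record cyclic.
#'
#' @param peptide a linear `peptide_record`.
#' @return The cyclic `peptide_record`.
#' @export
cyclize <- function(peptide) {
  if (peptide$cyclic) stop("peptide is already cyclic")
  peptide_record(paste0("C", peptide$sequence, "C"),
                 name = if (is.na(peptide$name)) NA_character_ else
                   paste0(peptide$name, "-C"),
                 cyclic = TRUE, source = peptide$source,
                 mutations = peptide$mutations)
}

#' Average molecular weight of a peptide (Da)
#'
#' Sum of average residue masses plus one water, the ProtParam convention;
#' cyclic peptides are computed on the linear chain (no disulfide -2H
#' correction).
#'
#' @param x a `peptide_record` or sequence string.
#' @return Molecular weight in Da (reported to two decimals).
#' @export
molecular_weight <- function(x) {
  letters1 <- strsplit(pep_seq(x), "")[[1]]
  if (!all(letters1 %in% names(AA_MASS_AVG)))
    stop("invalid amino-acid letter(s) in sequence")
  round(sum(AA_MASS_AVG[letters1]) + WATER_MASS_AVG, 2)
}

# net charge at a given pH under the Henderson-Hasselbalch model with the
# Bjellqvist pKa set (residue-specific N-terminal pKa; C-terminal Asp/Glu
# side chains use their terminal-specific pKa)
hh_charge <- function(sequence, pH) {
  letters1 <- strsplit(sequence, "")[[1]]
  n <- length(letters1)
  pos_pk <- PK_POSITIVE
  neg_pk <- PK_NEGATIVE
  last <- letters1[n]
  if (last %in% names(PK_CTERM_SIDE)) neg_pk[last] <- PK_CTERM_SIDE[[last]]
  first <- letters1[1]
  nterm_pk <- if (first %in% names(PK_NTERM)) PK_NTERM[[first]] else
    PK_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - nterm_pk))
  for (aa in names(pos_pk)) {
    cnt <- sum(letters1 == aa)
    if (cnt) pos <- pos + cnt / (1 + 10^(pH - pos_pk[[aa]]))
  }
  neg <- 1 / (1 + 10^(PK_CTERM - pH))
  for (aa in names(neg_pk)) {
    cnt <- sum(letters1 == aa)
    if (cnt) neg <- neg + cnt / (1 + 10^(neg_pk[[aa]] - pH))
  }
  pos - neg
}

#' Isoelectric point (ProtParam convention)
#'
#' Bisection root of the Henderson-Hasselbalch net-charge function using the
#' Bjellqvist pKa set (side chains D/E/C/Y/H/K/R, C-terminus 3.55 with
#' terminal-specific Asp/Glu values, and residue-specific N-terminal pKa).
#'
#' @param x a `peptide_record` or sequence string.
#' @return pI in pH units (reported to two decimals).
#' @export
isoelectric_point <- function(x) {
  sequence <- pep_seq(x)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (hh_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, 2)
}

#' Integer net charge at neutral pH (APD convention)
#'
#' `(#K + #R) - (#D + #E)`; histidine and the termini are not counted.
#'
#' @param x a `peptide_record` or sequence string.
#' @return Integer net charge.
#' @export
net_charge <- function(x) {
  letters1 <- strsplit(pep_seq(x), "")[[1]]
  if (!all(letters1 %in% names(AA_THREE)))
    stop("invalid amino-acid letter(s) in sequence")
  as.integer(sum(letters1 %in% c("K", "R")) - sum(letters1 %in% c("D", "E")))
}

#' Protease cleavage rules (PeptideCutter / Keil matrices)
#'
#' Returns the shipped deterministic window rules for trypsin, chymotrypsin
#' (high and low specificity) and pepsin (pH 1.3 and pH > 2).  Each rule
#' decides whether the bond C-terminal to position P1 is cleaved from the
#' local window P3..P2'.
#'
#' @return Character vector of available enzyme names.
#' @export
cleavage_enzymes <- function() {
  c("trypsin", "chymotrypsin_high", "chymotrypsin_low",
    "pepsin_1.3", "pepsin_gt2")
}

# Window predicate helpers.  Out-of-range positions are NA: membership tests
# ("must be X") fail on NA; exclusion tests ("must not be X") pass on NA when
# `lenient` (terminal counting) and fail otherwise.
w_is <- function(ch, set) !is.na(ch) & ch %in% set
w_not <- function(ch, set, lenient) if (is.na(ch)) lenient else !(ch %in% set)

cleaves_at <- function(letters1, i, enzyme, lenient) {
  at <- function(j) if (j >= 1 && j <= length(letters1)) letters1[j] else NA_character_
  p3 <- at(i - 2); p2 <- at(i - 1); p1 <- at(i); p1p <- at(i + 1); p2p <- at(i + 2)
  switch(enzyme,
    trypsin = {
      if (!w_is(p1, c("K", "R"))) return(FALSE)
      if (is.na(p1p)) return(lenient)
      # exception matrix (no cleavage), Keil rules
      if (w_is(p1p, "P")) {
        # WKP and MRP cleave despite the proline
        return((w_is(p2, "W") && p1 == "K") || (w_is(p2, "M") && p1 == "R"))
      }
      if (w_is(p2, c("C", "D")) && p1 == "K" && w_is(p1p, "D")) return(FALSE)
      if (w_is(p2, "C") && p1 == "K" && w_is(p1p, c("H", "Y"))) return(FALSE)
      if (w_is(p2, "C") && p1 == "R" && w_is(p1p, "K")) return(FALSE)
      if (w_is(p2, "R") && p1 == "R" && w_is(p1p, c("H", "R"))) return(FALSE)
      TRUE
    },
    chymotrypsin_high = {
      (w_is(p1, c("F", "Y")) && w_not(p1p, "P", lenient)) ||
        (w_is(p1, "W") && w_not(p1p, c("M", "P"), lenient))
    },
    chymotrypsin_low = {
      (w_is(p1, c("F", "L", "Y")) && w_not(p1p, "P", lenient)) ||
        (w_is(p1, "W") && w_not(p1p, c("M", "P"), lenient)) ||
        (w_is(p1, "M") && w_not(p1p, c("P", "Y"), lenient)) ||
        (w_is(p1, "H") && w_not(p1p, c("D", "M", "P", "W"), lenient))
    },
    pepsin_1.3 = pepsin_site(p3, p2, p1, p1p, p2p, c("F", "L"), lenient),
    pepsin_gt2 = pepsin_site(p3, p2, p1, p1p, p2p, c("F", "L", "W", "Y"),
                             lenient),
    stop("unknown enzyme: ", enzyme))
}

# pepsin position-specific matrix: cleavage between P1 and P1' when either
# P1' or P1 is in the preferred hydrophobic set, with no proline in P2/P2'
# and no H/K/R in P3 (and no R in P1 for the P1'-driven branch)
pepsin_site <- function(p3, p2, p1, p1p, p2p, pref, lenient) {
  common <- w_not(p2, "P", lenient) && w_not(p3, c("H", "K", "R"), lenient) &&
    w_not(p2p, "P", lenient)
  if (!common) return(FALSE)
  (w_is(p1p, pref) && w_not(p1, "R", lenient)) || w_is(p1, pref)
}

#' Count protease cleavage sites in a peptide
#'
#' Applies the shipped PeptideCutter-style window rules.  A site is the bond
#' C-terminal to residue `i`; with `terminal_counting` (the convention used
#' for reporting peptide susceptibility tables) window positions beyond the
#' termini are treated as unconstrained, so e.g. a C-terminal aromatic
#' residue still counts for chymotrypsin.
#'
#' @param x a `peptide_record` or sequence string.
#' @param enzyme one of [cleavage_enzymes()].
#' @param terminal_counting logical (default `TRUE`).
#' @return List with `count` and `sites` (positions of cleaved P1 residues).
#' @export
cleavage_sites <- function(x, enzyme, terminal_counting = TRUE) {
  if (!enzyme %in% cleavage_enzymes())
    stop("unknown enzyme: ", enzyme, " (available: ",
         paste(cleavage_enzymes(), collapse = ", "), ")")
  letters1 <- strsplit(pep_seq(x), "")[[1]]
  sites <- which(vapply(seq_along(letters1), function(i)
    cleaves_at(letters1, i, enzyme, terminal_counting), TRUE))
  list(count = length(sites), sites = sites)
}

#' Tabulate designed peptides with their physicochemical panel
#'
#' @param peptides list of `peptide_record` objects.
#' @param enzymes enzymes to include (default all of [cleavage_enzymes()]).
#' @return data.frame, one row per peptide (input order): `name`, `sequence`,
#'   `cyclic`, `mw`, `pi`, `net_charge`, and one cleavage-count column per
#'   enzyme.
#' @export
design_report <- function(peptides, enzymes = cleavage_enzymes()) {
  base <- data.frame(name = character(), sequence = character(),
                     cyclic = logical(), mw = numeric(), pi = numeric(),
                     net_charge = integer(), stringsAsFactors = FALSE)
  for (e in enzymes) base[[e]] <- integer()
  if (length(peptides) == 0L) return(base)
  rows <- lapply(peptides, function(p) {
    row <- data.frame(name = p$name, sequence = p$sequence, cyclic = p$cyclic,
                      mw = molecular_weight(p), pi = isoelectric_point(p),
                      net_charge = net_charge(p), stringsAsFactors = FALSE)
    for (e in enzymes) row[[e]] <- cleavage_sites(p, e)$count
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write peptide sequences as FASTA
#'
#' @param path FASTA file path.
#' @return `read_fasta_peptides` returns a list of `peptide_record`s.
#' @export
read_fasta_peptides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no FASTA records in ", path)
  ends <- c(heads[-1] - 1L, length(lines))
  lapply(seq_along(heads), function(i) {
    seqs <- paste(lines[(heads[i] + 1L):ends[i]], collapse = "")
    peptide_record(gsub("\\s", "", seqs),
                   name = sub("^>\\s*", "", lines[heads[i]]))
  })
}

#' @rdname read_fasta_peptides
#' @param peptides list of `peptide_record`s.
#' @export
write_fasta_peptides <- function(peptides, path) {
  lines <- unlist(lapply(peptides, function(p)
    c(paste0(">", if (is.na(p$name)) "peptide" else p$name), p$sequence)))
  writeLines(lines, path)
  invisible(path)
}
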