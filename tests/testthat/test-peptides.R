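test_that("CDR segments extract to the expected sequences", {
  st <- adu_like_structure()
  regs <- cdr_regions()
  expect_equal(extract_segment(st, regs[[1]])$sequence, "VIWFDGTKKYY")
  expect_equal(extract_segment(st, regs[[2]])$sequence, "GIGARRGPY")
  expect_equal(extract_segment(st, regs[[3]])$sequence, "QSYSTPL")
  one <- extract_segment(st, region_def("one", "L", list(c(92, 92))))
  expect_equal(one$sequence, "Y")
  # a gap in the region is an error
  broken <- select_residues(st, c("H", "L", "A"),
                            list(H = list(c(1, 54), c(56, 126)),
                                 L = list(c(1, 109)), A = list(c(2, 7))))
  expect_error(extract_segment(broken, regs[[1]]), "missing residue")
})

test_that("point mutation maps region numbering onto the sequence", {
  st <- adu_like_structure()
  p <- extract_segment(st, cdr_regions()[[3]])
  m <- mutate_peptide(p, 91, "Y")
  expect_equal(m$sequence, "QYYSTPL")
  expect_equal(m$mutations[[1]][["from"]], "S")
  # identity mutation: unchanged but logged
  id <- mutate_peptide(p, 91, "S")
  expect_equal(id$sequence, p$sequence)
  expect_length(id$mutations, 1L)
  expect_error(mutate_peptide(p, 89, "Y"), "outside")
  expect_error(mutate_peptide(p, 91, "Z"), "invalid")
})

test_that("cyclization adds terminal cysteines exactly once", {
  p <- peptide_record("QSYSTPL")
  cyc <- cyclize(p)
  expect_equal(cyc$sequence, "CQSYSTPLC")
  expect_true(cyc$cyclic)
  expect_equal(cyclize(peptide_record("GIGARRGPY"))$sequence, "CGIGARRGPYC")
  expect_error(cyclize(cyc), "already cyclic")
})

test_that("molecular weights follow the average-mass ProtParam convention", {
  expect_equal(molecular_weight("G"), 75.07)
  expect_equal(molecular_weight("VIWFDGTKKYY"), 1419.64, tolerance = 0.005)
  expect_equal(molecular_weight("CGIGARRGPYC"), 1152.35, tolerance = 0.005)
  expect_error(molecular_weight("ABZ"), "invalid")
  # additivity: MW(s1 + s2) = MW(s1) + MW(s2) - one water
  set.seed(4)
  aas <- names(epitopedecomp:::AA_THREE)
  for (i in 1:5) {
    s1 <- paste(sample(aas, 6, TRUE), collapse = "")
    s2 <- paste(sample(aas, 4, TRUE), collapse = "")
    expect_equal(molecular_weight(paste0(s1, s2)),
                 molecular_weight(s1) + molecular_weight(s2) - 18.0153,
                 tolerance = 0.02)
  }
  # cyclization adds exactly two cysteine residue masses
  for (s in c("QSYSTPL", "GIGARRGPY"))
    expect_equal(molecular_weight(cyclize(peptide_record(s))),
                 molecular_weight(s) + 2 * 103.1388, tolerance = 0.02)
})

test_that("isoelectric points match the Bjellqvist/ProtParam values", {
  expect_equal(isoelectric_point("GIGARRGPY"), 10.84)
  expect_equal(isoelectric_point("QSYSTPL"), 5.52)
  # termini-only peptide: pI is the midpoint of the two terminal pKa values
  expect_equal(isoelectric_point("AAAA"), round((7.59 + 3.55) / 2, 2),
               tolerance = 0.011)
  # the bisection root really neutralizes the full charge model
  for (s in c("GIGARRGPY", "QSYSTPL", "VIWFDGTKKYY", "CQYYSTPLC"))
    expect_lt(abs(epitopedecomp:::hh_charge(s, isoelectric_point(s))), 0.01)
})

test_that("integer net charge counts K/R against D/E only", {
  expect_equal(net_charge("GIGARRGPY"), 2L)
  expect_equal(net_charge("GGG"), 0L)
  expect_equal(net_charge("DKEKR"), 1L)
  expect_equal(net_charge("VIWFDGTKKYY"), 1L)  # His/termini excluded
  expect_equal(net_charge("HHHH"), 0L)
})

test_that("cleavage rules reproduce the canonical worked cases", {
  expect_equal(cleavage_sites("GIGARRGPY", "trypsin")$count, 2L)
  # K before P blocked, second K cleaved
  expect_equal(cleavage_sites("AKPAKA", "trypsin")$count, 1L)
  expect_equal(cleavage_sites("AKPAKA", "trypsin")$sites, 5L)
  # WKP cleaves despite the proline
  expect_equal(cleavage_sites("AWKPA", "trypsin")$count, 1L)
  expect_equal(cleavage_sites("ACKPA", "trypsin")$count, 0L)
  for (e in cleavage_enzymes())
    expect_equal(cleavage_sites("GGGG", e)$count, 0L)
  expect_error(cleavage_sites("GGG", "papain"), "unknown enzyme")
})

test_that("strict (non-terminal) counting matches an independent regex
           encoding of the same rule matrices", {
  # the Keil/PeptideCutter matrices as perl regexes over internal positions
  rules <- c(
    trypsin = "([KR](?=[^P]))|((?<=W)K(?=P))|((?<=M)R(?=P))",
    chymotrypsin_high = "([FY](?=[^P]))|(W(?=[^MP]))",
    chymotrypsin_low =
      "([FLY](?=[^P]))|(W(?=[^MP]))|(M(?=[^PY]))|(H(?=[^DMPW]))",
    pepsin_1.3 = paste0("((?<=[^HKR][^P])[^R](?=[FL][^P]))|",
                        "((?<=[^HKR][^P])[FL](?=[A-Z][^P]))"),
    pepsin_gt2 = paste0("((?<=[^HKR][^P])[^R](?=[FLWY][^P]))|",
                        "((?<=[^HKR][^P])[FLWY](?=[A-Z][^P]))"))
  trypsin_exc <- "((?<=[CD])K(?=D))|((?<=C)K(?=[HY]))|((?<=C)R(?=K))|((?<=R)R(?=[HR]))"
  regex_count <- function(s, enz) {
    hits <- gregexpr(rules[[enz]], s, perl = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (enz == "trypsin") {
      exc <- gregexpr(trypsin_exc, s, perl = TRUE)[[1]]
      hits <- setdiff(hits, exc[exc > 0])
    }
    length(hits)
  }
  set.seed(7)
  aas <- names(epitopedecomp:::AA_THREE)
  for (i in 1:40) {
    s <- paste(sample(aas, sample(6:14, 1), TRUE), collapse = "")
    for (enz in cleavage_enzymes()) {
      expect_equal(cleavage_sites(s, enz, terminal_counting = FALSE)$count,
                   regex_count(s, enz),
                   info = paste(enz, s))
    }
  }
})

test_that("design_report reproduces the full published peptide panel", {
  refs <- reference_peptides()
  peps <- lapply(refs, function(r)
    peptide_record(r$seq, name = r$name, cyclic = r$cyclic))
  rep <- design_report(peps)
  expect_equal(nrow(rep), 8L)
  expect_equal(rep$name, vapply(refs, `[[`, "", "name"))
  for (i in seq_along(refs)) {
    expect_equal(rep$mw[i], refs[[i]]$mw, tolerance = 0.02)
    expect_equal(rep$pi[i], refs[[i]]$pi, tolerance = 0.011)
    expect_identical(rep$net_charge[i], refs[[i]]$charge)
    expect_identical(rep$trypsin[i], refs[[i]]$trypsin)
    expect_identical(rep$chymotrypsin_high[i], refs[[i]]$chymo_high)
    expect_identical(rep$chymotrypsin_low[i], refs[[i]]$chymo_low)
    expect_identical(rep$pepsin_1.3[i], refs[[i]]$pepsin13)
    expect_identical(rep$pepsin_gt2[i], refs[[i]]$pepsin2)
  }
  # row order follows input order; empty input gives an empty table
  rev_rep <- design_report(rev(peps))
  expect_equal(rev_rep$name, rev(rep$name))
  expect_equal(nrow(design_report(list())), 0L)
})

test_that("peptide FASTA round-trips", {
  peps <- list(peptide_record("QSYSTPL", "p1"),
               peptide_record("GIGARRGPY", "p2"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_peptides(peps, f)
  back <- read_fasta_peptides(f)
  expect_equal(vapply(back, function(p) p$sequence, ""),
               c("QSYSTPL", "GIGARRGPY"))
  expect_equal(vapply(back, function(p) p$name, ""), c("p1", "p2"))
})

test_that("peptide records validate their sequences", {
  expect_error(peptide_record("QSYB"), "invalid")
  expect_error(peptide_record(""), "empty")
  expect_error(peptide_record("AGA", cyclic = TRUE), "cysteine")
})
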