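test_that("pair enumeration honours the distance cutoff and ordering", {
  # two single-residue chains 9 A apart: outside an 8 A cutoff
  a <- build_peptide("G", "A")
  b <- build_peptide("G", "B")
  b <- set_coords(b, sweep(coords(b$atoms), 2, c(0, -12, 0)))
  atoms <- rbind(a$atoms, b$atoms); atoms$eleno <- seq_len(nrow(atoms))
  st <- new_structure(atoms)
  d <- min_residue_distance(st, "A:1", "B:1")
  expect_gt(d, 8)
  expect_equal(nrow(enumerate_pairs(st, "A", "B", 8)), 0L)
  expect_equal(nrow(enumerate_pairs(st, "A", "B", d + 0.1)), 1L)
  expect_equal(nrow(enumerate_pairs(st, "A", "B", 0)), 0L)
  expect_error(enumerate_pairs(st, c("A", "B"), "B"), "overlap")

  # 3x3 toy interface: all cross pairs within a generous cutoff; the cutoff-8
  # list contains the cutoff-4 list
  toy <- make_toy_complex(toy_complex_spec(n_res = 3, separation = 4,
                                           seed = 1))$structure
  p_all <- enumerate_pairs(toy, "A", "B", 50)
  expect_equal(nrow(p_all), 9L)
  expect_equal(order(p_all$chain_i, p_all$resno_i, p_all$chain_j,
                     p_all$resno_j), seq_len(9L))
  p8 <- enumerate_pairs(toy, "A", "B", 8)
  p4 <- enumerate_pairs(toy, "A", "B", 4)
  key <- function(p) paste(p$key_i, p$key_j)
  expect_true(all(key(p4) %in% key(p8)))
  # enumerated distances equal the brute-force minima
  for (k in seq_len(nrow(p8)))
    expect_equal(p8$dist[k],
                 min_residue_distance(toy, p8$key_i[k], p8$key_j[k]),
                 tolerance = 1e-12)
})

test_that("quartets carry single-residue caps, fill hydrogens and waters", {
  # central glycines of two GGG tripeptides: caps are chain termini, so the
  # capped fragments have no outer cuts and S4 is caps-only
  a <- build_peptide("GGG", "A")
  b <- build_peptide("GGG", "B")
  b <- set_coords(b, sweep(coords(b$atoms), 2, c(0, -6, 0)))
  atoms <- rbind(a$atoms, b$atoms); atoms$eleno <- seq_len(nrow(atoms))
  st <- new_structure(atoms)
  qt <- build_quartet(st, "A:2", "B:2")
  expect_equal(sort(qt$caps_i), c("A:1", "A:3"))
  expect_equal(unname(qt$n_fill["S1"]), 0L)
  expect_equal(unname(qt$n_fill["S4"]), 4L)  # two inner cuts per removed core
  expect_false("A:2" %in% residue_table(qt$S4)$key)
  expect_false("B:2" %in% residue_table(qt$S4)$key)

  # mid-chain pair: each two-cap fragment has 2 cut bonds, hence 2 fill H
  toy <- planted_toy("hbond", n_res = 6)$structure
  q2 <- build_quartet(toy, "A:3", "B:3")
  expect_equal(unname(q2$n_fill["S1"]), 4L)   # 2 per fragment
  expect_equal(unname(q2$n_fill["S4"]), 8L)   # plus 2 inner cuts per side
  expect_equal(sum(q2$S1$atoms$fill), 4L)
  # fill hydrogens sit 1.09 A from their bonded heavy atom
  fills <- q2$S1$atoms[q2$S1$atoms$fill, ]
  for (i in seq_len(nrow(fills))) {
    res <- q2$S1$atoms[!q2$S1$atoms$fill &
                       res_key(q2$S1$atoms$chain, q2$S1$atoms$resno) ==
                         res_key(fills$chain[i], fills$resno[i]), ]
    dmin <- min(sqrt(rowSums(sweep(coords(res), 2,
                                   as.numeric(fills[i, c("x", "y", "z")]))^2)))
    expect_equal(dmin, 1.09, tolerance = 1e-6)
  }
  # chain-terminus residue: single cap, no error
  q3 <- build_quartet(toy, "A:1", "B:3")
  expect_equal(length(q3$caps_i), 1L)

  # a water within the shell of Ri appears exactly in the subsystems that
  # contain Ri (S1, S2)
  stw <- add_water(toy, "A:3", "OG", c(0, 0.8, 2.0))
  qw <- build_quartet(stw, "A:3", "B:3", water_shell = 2.5)
  in_sub <- vapply(c("S1", "S2", "S3", "S4"),
                   function(s) "HOH" %in% qw[[s]]$atoms$resid, TRUE)
  expect_equal(unname(in_sub), c(TRUE, TRUE, FALSE, FALSE))
  # outside the shell it is attached nowhere
  qfar <- build_quartet(add_water(toy, "A:3", "OG", c(0, 0, 3.0)),
                        "A:3", "B:3", water_shell = 2.5)
  expect_equal(length(qfar$waters_i) + length(qfar$waters_j), 0L)
  # same-chain pairs are rejected
  expect_error(build_quartet(toy, "A:2", "A:4"), "distinct chains")
})

test_that("the four-term combination is plain signed arithmetic", {
  expect_equal(mfcc_combine(0, 0, 0, 0), 0)
  expect_equal(mfcc_combine(-10, -4, -3, -1), -4)
  expect_error(mfcc_combine(NA, 0, 0, 0), "finite")
  expect_error(mfcc_combine(Inf, 0, 0, 0), "finite")
})

test_that("MFCC route reproduces the direct pair energy exactly for the
           pairwise-additive classical backend", {
  for (sd in 1:5) {
    toy <- make_toy_complex(toy_complex_spec(n_res = 5, charges = "random",
                                             seed = sd, separation = 7))
    st <- toy$structure
    prs <- enumerate_pairs(st, "A", "B", 8)
    for (k in seq_len(nrow(prs))) {
      pe <- pair_energy(st, prs$key_i[k], prs$key_j[k])
      expect_lt(abs(pe$energy -
                      direct_pair_energy(st, prs$key_i[k], prs$key_j[k])),
                1e-9)
      expect_equal(pe$backend_id, "classical(eps=40)")
    }
  }
})

test_that("the water-augmented identity holds: caps and water self-terms
           cancel, water-mediated terms remain", {
  toy <- planted_toy("hbond", charges = "random", seed = 11)
  stw <- add_water(toy$structure, "A:3", "OG", c(0, 0.5, 2.0))
  pe <- pair_energy(stw, "A:3", "B:3", water_shell = 2.5)
  expect_equal(pe$included_waters, 1L)
  expect_lt(abs(pe$energy -
                  direct_pair_energy(stw, "A:3", "B:3", waters_i = "W:1")),
            1e-8)
})

test_that("neutral glycines at 20 A interact negligibly", {
  a <- build_peptide("G", "A")
  b <- build_peptide("G", "B")
  b <- set_coords(b, sweep(coords(b$atoms), 2, c(0, -20, 0)))
  atoms <- rbind(a$atoms, b$atoms); atoms$eleno <- seq_len(nrow(atoms))
  atoms$charge <- 0   # Lennard-Jones only
  st <- new_structure(atoms)
  pe <- pair_energy(st, "A:1", "B:1")
  expect_lt(abs(pe$energy), 1e-3)
})

test_that("classical Coulomb matches the closed form through the quartet", {
  # two unit point charges 5 A apart with eps = 40: 332.0636/(40*5)
  at <- data.frame(elety = c("Q1", "Q2"), resid = "GLY",
                   chain = c("A", "B"), resno = 1L,
                   x = c(0, 5), y = 0, z = 0, elesy = "H",
                   charge = c(1, 1))
  st <- new_structure(at)
  pe <- pair_energy(st, "A:1", "B:1")
  expect_equal(pe$energy, 332.0636 / (40 * 5), tolerance = 1e-9)
})

test_that("the table backend is an exact pass-through of combine()", {
  toy <- planted_toy("hbond")$structure
  tab <- data.frame(pair_id = "A:3|B:3",
                    subsystem = c("S1", "S2", "S3", "S4"),
                    energy_kcal_mol = c(-10, -4, -3, -1))
  be <- backend_config("table", table = tab)
  pe <- pair_energy(toy, "A:3", "B:3", backend = be)
  expect_equal(pe$energy, -4)
  expect_equal(pe$backend_id, "table")
  expect_error(pair_energy(toy, "A:2", "B:3", backend = be),
               "missing energy .* S1")
})

test_that("interface totals match the brute-force double sum and are
           enumeration-order invariant", {
  toy <- make_toy_complex(toy_complex_spec(n_res = 4, charges = "random",
                                           seed = 21, separation = 7))
  ie <- interface_energies(toy$structure, "A", "B")
  expect_lt(abs(attr(ie, "total") - sum(toy$truth_energies$energy)), 1e-9)
  expect_equal(attr(ie, "total"), sum(ie$energy))
  # swapping the group roles transposes pairs but preserves the total
  ie_swap <- interface_energies(toy$structure, "B", "A")
  expect_lt(abs(attr(ie_swap, "total") - attr(ie, "total")), 1e-9)
  # empty interface
  far <- toy$structure
  fb <- far$atoms$chain == "B"
  far$atoms$y[fb] <- far$atoms$y[fb] - 50
  ie0 <- interface_energies(far, "A", "B")
  expect_equal(nrow(ie0), 0L)
  expect_equal(attr(ie0, "total"), 0)
})

test_that("subsystem export writes four re-readable files", {
  toy <- planted_toy("hbond")$structure
  qt <- build_quartet(toy, "A:3", "B:3")
  dir_pdb <- withr::local_tempdir()
  paths <- export_subsystems(qt, dir_pdb, "pdb")
  expect_length(paths, 4L)
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths[1]), "^pair_A3_B3_S1")
  for (k in 1:4) {
    rr <- read_pdb(paths[k])[[1]]
    expect_equal(nrow(rr$atoms), nrow(qt[[paste0("S", k)]]$atoms))
    expect_equal(coords(rr$atoms),
                 round(coords(qt[[paste0("S", k)]]$atoms), 3),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
  dir_xyz <- withr::local_tempdir()
  xpaths <- export_subsystems(qt, dir_xyz, "xyz")
  for (k in 1:4)
    expect_equal(nrow(read_xyz(xpaths[k])),
                 nrow(qt[[paste0("S", k)]]$atoms))
})
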