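---
title: "Fragment-based decomposition of antibody-epitope interfaces"
author: "epitopedecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based decomposition of antibody-epitope interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitopedecomp)
```

## What the package models

An antibody variable fragment (Fv) binds a peptide epitope through a small
set of residues, mostly in the complementarity determining regions (CDRs).
To attribute binding affinity to individual residues, the interface is
decomposed into residue pairs and each pair's interaction energy is
estimated by the *molecular fractionation with conjugated caps* (MFCC)
scheme: residue R~i~ of one chain and R~j~ of the other are excised together
with their covalent sequence neighbours (the conjugated caps C~i±1~, C~j±1~),
hydrogen atoms fill the cut backbone bonds, and

$$E_{ij} \;=\; E(C_{i-1}R_iC_{i+1} + C_{j-1}R_jC_{j+1})
          \;-\; E(C_{i-1}R_iC_{i+1} + C_{j-1}C_{j+1})
          \;-\; E(C_{i-1}C_{i+1} + C_{j-1}R_jC_{j+1})
          \;+\; E(C_{i-1}C_{i+1} + C_{j-1}C_{j+1}).$$

The alternating signs cancel every term that does not couple R~i~ to R~j~ —
cap self-energies, cap-cap terms, and the self-energy of any solvent
attached to a core. The package builds these four subsystems for every
cross-chain residue pair whose minimum heavy-atom distance is at most a
threshold (default 8.0 Å), evaluates them with a pluggable backend, and
aggregates the pair energies into per-residue and per-CDR hot-spot
summaries.

### Assumptions

* Fragmentation follows the backbone only: caps are the one-residue sequence
  neighbours (chain termini yield single caps), and cut bonds are the
  backbone C–N bonds. Disulfides and other cross-links are not cut bonds.
* Pair identity is defined by author (file) residue numbering; the package
  never renumbers, because published hot-spot tables refer to
  crystallographic numbers (e.g. VAL50, TYR60).
* Solvent is either implicit (a dielectric constant in the classical
  backend) or a shell of explicit waters attached to the core residues.

## Energy backends

DFT-level subsystem energies are outside the scope of an R package; the
design instead separates the *fragmentation scheme* (which is the
contribution here) from the *energy engine* behind a three-way backend
contract:

* **classical** — Coulomb with a distance-independent relative dielectric
  (default ε = 40, the value appropriate for a solvated protein–protein
  interface, configurable) plus a 12-6 Lennard-Jones term over a small
  per-element parameter table. Partial charges come from an explicit
  per-atom `charge` column when the structure carries one (the synthetic
  generators do), otherwise from a coarse shipped per-residue table
  (backbone amide dipole plus charged side-chain groups). Same-residue atom
  pairs are excluded — a constant self-term that cancels in the four-term
  combination — and *fill hydrogens carry zero charge and zero
  Lennard-Jones parameters*: they are geometric placeholders for the
  exported subsystems, and giving them parameters would break the exact
  cancellation that makes this backend a testing instrument.
* **table** — subsystem energies are read from a CSV
  (`pair_id`, `subsystem`, `energy_kcal_mol`), the ingestion route for an
  external quantum engine; a missing subsystem entry is an error naming the
  subsystem.
* **export** — the four subsystems per pair are written as PDB or XYZ files
  for that engine.

Because the classical model is strictly pairwise additive, the MFCC route
must reproduce the direct cross-residue sum *exactly*; the test suite
asserts agreement to 1e−9 kcal/mol on 100 randomized complexes, and the same
identity extended by attached waters (a shell water attaches to the nearer
core, ties to R~i~, and appears in every subsystem containing that core).
This is the strongest available correctness check of the fragmentation
bookkeeping — caps, fill hydrogens, water attribution and signs — and it is
independent of the backend one later plugs in.

## Contact geometry

Hydrogen bonds use the distance-driven LigPlot+/HBPLUS convention: donor and
acceptor atoms from a fixed chemistry table (N/O/S donors bearing hydrogens;
N/O acceptors; histidine both), with H···A ≤ 2.70 Å **and** D···A ≤ 3.35 Å
when hydrogens are present, or the D···A criterion alone in heavy-atom mode.
No angular term is applied — the convention the thresholds come from is
distance-driven, and adding an angle would silently change every count.
Hydrophobic contacts are residue pairs with at least one apolar-carbon pair
(carbons not bonded to N/O, fixed table) inside the closed window
2.90–3.90 Å. Salt bridges — reported in interface studies but with no
universal criterion — use the common ≤ 4.0 Å cutoff between Asp/Glu
carboxylate oxygens and Lys/Arg/His basic nitrogens; the cutoff is a
criteria field like the others. Hydrogen bonds are reported once per
qualifying atom pair (the convention of the underlying tools), hydrophobic
contacts and salt bridges once per residue pair with the closest qualifying
atoms; conservation across an ensemble is counted on (residue pair, kind)
keys.

## Ensembles

Trajectories are multi-model PDB files. Superposition is the Kabsch
least-squares fit with reflection rejection (the rotation determinant is
always +1); RMSD series are per-frame post-fit values against a reference
frame, and RMSF is computed about the mean structure after two fit-mean
iterations. Featurization for conformational clustering uses backbone
φ/ψ dihedrals as sin/cos pairs (only residues with both neighbours present)
plus all pairwise Cα distances of the selected residues — both invariant to
global rigid motion, so clustering sees only internal geometry.

Representative conformations are chosen by fitting a Gaussian mixture for
each candidate cluster count k (default 2–10), scoring each fit by mean
silhouette width, picking the argmax (ties toward smaller k), and taking
each cluster's *hub*: the frame nearest the cluster mean in the clustering
space. Mixtures are fitted with mclust, whose model-based hierarchical
initialisation is deterministic, so repeated runs agree without random
restarts; full covariance ("VVV") is tried first, falling back to pooled
and spherical models when a covariance estimate is singular (as happens
when frames are fewer than features). Dimensionality reduction before
clustering is optional and off by default — raw-feature clustering is
reproducible and sufficient for well-separated basins; when enabled it is a
principal-component projection, a deterministic linear reduction (nonlinear
embeddings are deliberately out of scope). Silhouette cannot score k = 1, so
a single-basin ensemble resolves to the smallest candidate k; truly
degenerate (all-identical) input returns one cluster with a warning.

## Hot-spot aggregation

Pair records aggregate into per-residue totals (the sums on both sides equal
the grand total exactly), per-region totals over named CDR definitions
(shipped defaults: heavy-chain CDR2 = H 50–60, CDR3 = H 101–109, light-chain
CDR3 = L 90–96; other loops vary by numbering scheme and are user-supplied),
cumulative energy profiles over a distance grid (default 0–8 Å in 0.25 Å
steps; a step function whose endpoint is the interface total), and a
most-attractive-first residue ranking with deterministic (chain, number)
tie-breaks. Regional percentages divide by the grand total including
repulsive terms by default — the natural reading of "share of the total
affinity" — with an attractive-only denominator as an option, since
published fractions rarely state which denominator was used.

## Mimetic peptides

Hot-spot segments are extracted as linear peptides (one-letter sequence in
chain order, source region recorded), optionally point-mutated (positions in
the source region's author numbering), and cyclized by adding one cysteine
to each terminus for a disulfide. The physicochemical panel follows the
conventions of the public tools these numbers are conventionally reported
with, pinned by the published values of the eight reference peptides:

* **Molecular weight**: sum of average residue masses plus one water
  (18.0153 Da); cyclic peptides are computed on the linear chain, with no
  −2H disulfide correction — the convention that matches the reference
  table (e.g. CGIGARRGPYC → 1152.35 Da).
* **Isoelectric point**: bisection root of the Henderson–Hasselbalch net
  charge under the Bjellqvist pKa set, including residue-specific N-terminal
  pKa values and the C-terminal Asp/Glu side-chain variants; reported to two
  decimals. This set reproduces all eight reference pI values exactly.
* **Net charge**: the integer (#K + #R) − (#D + #E); histidine and the
  termini are excluded, matching every reference entry.
* **Protease cleavage**: the Keil/PeptideCutter window matrices for trypsin
  (with the exception matrix, including the WKP/MRP counter-exceptions),
  chymotrypsin at high (F/Y/W) and low (F/L/Y/W/M/H) specificity, and the
  pepsin position-specific matrices for pH 1.3 and pH > 2. Sites are bonds
  C-terminal to a position; with `terminal_counting` (the default, matching
  the reference susceptibility table) window positions beyond the termini
  are treated as unconstrained, so a C-terminal aromatic residue still
  counts — verified against all forty published peptide-by-enzyme counts.
  An independent regex encoding of the same matrices backs the rule engine
  in the tests for internal (non-terminal) sites.

## Synthetic data: what it does and does not emulate

The generators provide ground truth, not physics. Chains are ideal extended
backbones grown from internal coordinates (φ = ψ = ω = 180°, standard bond
lengths/angles) with approximate idealized side-chain templates; planted
contacts are realized by rigidly placing chain B across chain A so the
anchor atoms (Ser OG/amide N for hydrogen bonds, Leu CD1 tips for
hydrophobic contacts, Glu/Lys charged groups for salt bridges) meet the
target distance within 0.05 Å, with the detector's own metric (minimum
charged-group distance for salt bridges) as the planted quantity. For a
single planted contact the geometry guarantees the planted record is the
*only* detection, which is what makes exact-set assertions possible.
Conformer ensembles displace random residue subsets by fixed per-mode
vectors plus isotropic Gaussian noise; mode centres must be separated by
more than five noise widths, the regime in which silhouette-selected
Gaussian mixtures provably recover the partition. None of this emulates
side-chain packing, secondary-structure change, correlated motions or real
solvent — so green tests demonstrate the *algorithms* are right, not that
any particular biological interface will behave this way.

Default study conditions used by the tests: toy complexes of 4–6 residues
per chain with per-atom charges uniform in ±0.3 e, dielectric 40; ensembles
of 3 modes × 15 frames with σ = 0.25 Å noise and ~3 Å mode displacements.
These sizes keep the full suite around a minute while leaving every
quantity non-trivial.

## Numerical choices and degenerate inputs

* The four-term combination is evaluated in double precision; with
  same-residue exclusion the subsystem totals stay small enough that the
  identity holds to ~1e−11 kcal/mol. Steric clashes (overlapping atoms)
  inflate subsystem totals and degrade the cancellation — synthetic inputs
  are clash-free by construction.
* Fill hydrogens sit 1.09 Å (a standard C–H length) along the former bond
  vector; each fragment names them uniquely so exported subsystems round-trip
  through PDB.
* Kabsch uses SVD with a determinant correction, so mirrored inputs produce
  the best proper rotation, never a reflection.
* Alternate locations collapse to the highest-occupancy conformer at read
  time; insertion codes are preserved.
* Empty caps-only subsystems (single-residue chains) evaluate to zero
  energy; residues consisting only of hydrogens fall back to all-atom
  distances.
* Zero-variance feature columns are dropped before clustering; if nothing
  remains the ensemble is a single cluster (warning).
* pI bisection runs to 1e−6 pH and is reported to two decimals; the root
  really neutralizes the model charge (|Q(pI)| < 0.01), which the tests
  assert.

## Pipeline and reproducibility

`run_all()` executes the stages in order (input → optional ensemble →
contacts and conservation → MFCC → hot spots → peptides) from a validated
configuration (unknown keys are rejected before any work), writes CSV/JSON
outputs, and records a manifest with the input hash, every output's MD5,
the seed and the package version. Outputs contain no timestamps, so a rerun
of an identical configuration is byte-identical — the property the tests
check. Configurations live in YAML with all geometric and energetic
thresholds (2.70, 3.35, 2.90, 3.90, 8.0, 2.5 Å; ε = 40) as named keys.

## Known limitations

* No quantum-mechanical energies: the classical backend is a structural
  stand-in, and published DFT-level interaction energies are reproducible
  only through the table backend fed with such results.
* PDB input only (no mmCIF); trajectories as multi-model PDB.
* Distance-only contact criteria; no π-stacking, cation-π or water-mediated
  bridges.
* Idealized mutation replaces a side chain with a template rotamer on the
  fixed backbone — a sequence-level stand-in, flagged approximate, not a
  repacked structure.
* Loop modelling, protonation assignment and peptide 3D-structure
  prediction are upstream/downstream of this package and out of scope.
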