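Package: epitopedecomp
Title: Fragment-Based Energy Decomposition of Antibody-Epitope Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antibody::epitope interfaces built around the
    molecular fractionation with conjugated caps (MFCC) scheme. Enumerates
    interface residue pairs, builds the four capped subsystems whose energies
    combine into residue-residue interaction energies, and supports pluggable
    energy backends (a classical Coulomb/Lennard-Jones stand-in, external
    energy tables, and subsystem export for quantum engines). Also provides
    geometric detection of hydrogen bonds, hydrophobic contacts and salt
    bridges, conformational-ensemble descriptors (RMSD/RMSF) and
    representative-structure selection by Gaussian-mixture clustering with
    silhouette model selection, per-residue/per-CDR hot-spot aggregation, and
    design of linear and cyclic mimetic peptides with a sequence-based
    physicochemical panel (molecular weight, isoelectric point, net charge,
    protease cleavage sites).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    mclust,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
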