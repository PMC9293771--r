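Package: asphkit
Title: Consensus-Motif Scanning, MS/MS Site Localization, and Kinetics
    for EGF-Like Domain Hydroxylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying aspartate/asparagine beta-hydroxylase
    (AspH) substrates. Scans protein sequences for candidate
    hydroxylation sites under the legacy 12-residue consensus
    (C3-X-D/N-X-X-X-X-F/Y-X-C4-X-C5) and the revised 10-residue
    disulfide-macrocycle rule; indexes domain cysteines and computes
    C4-C5 spacing; computes modification-aware peptide and b/y fragment
    masses, matches peak lists, localizes the +15.9949 Da hydroxylation
    shift, and estimates label-free site occupancy; simulates and fits
    integrated Michaelis-Menten progress curves with active-site
    titration corrected turnover numbers. Includes seeded synthetic-data
    generators (proteomes with planted motifs, MS/MS spectra, intensity
    pairs, time courses) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
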