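Package: repairmap
Title: Indel Pattern-Guided Mapping of CRISPR/Cas9 Double-Strand Break Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies CRISPR/Cas9 amplicon repair outcomes into seven
    mechanistic indel patterns (1 bp insertions, large insertions,
    microhomology-associated and non-microhomology small and large deletions,
    and localized substitutions), fits a three-state kinetic model of
    cleavage and repair to editing time courses, and runs pooled-screen
    statistics (Fisher exact tests versus non-targeting controls, directional
    Robust Rank Aggregation with permutation null distributions, and
    cross-library z-score integration) that link gene knockouts to shifts in
    repair-outcome spectra. Includes seed-deterministic generators for edited
    amplicon reads, kinetic time courses, and pooled-screen count tables with
    planted effects, so every stage is testable without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
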