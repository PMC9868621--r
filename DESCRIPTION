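Package: pmhcprofiler
Title: Interface Profiling of Immunoglobulin-pMHC Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how T-cell-receptor-like an immunoglobulin:peptide-MHC
    complex is. Implements per-residue solvent-accessible surface area by the
    Shrake-Rupley method and buried-surface-area decompositions over IMGT-defined
    CDR loops, residue-level interface interaction typing with salt-bridge
    consolidation, docking/crossing-angle and binding-polarity classification
    against the peptide-binding groove, greedy sequence-identity clustering for
    redundancy-aware dataset curation, and post-processing of per-residue
    binding-energy decomposition tables (regional fractions and hotspot calls).
    Includes deterministic synthetic fixture generators (idealised MHC grooves,
    planted-cluster sequence sets, energy tables with planted hotspots) so the
    whole pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
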