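Package: combilib
Title: Verification of Combinatorial Promoter Libraries from Long Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Combilib", "Developers", email = "combilib@example.org", role = c("aut", "cre"))
Description: Tools to verify combinatorial Golden Gate promoter libraries from
    long (nanopore-class) sequencing reads. Models a multi-slot promoter/gene
    library design, parses tabular local-alignment output (LAST -fTAB dialect),
    chains per-read alignments and classifies each read as a multigene assembly,
    a digested or undigested single-gene assembly, or a contaminant, recording
    the promoter installed at each gene slot. Provides chi-squared and exact
    tests for promoter-incorporation bias against the random-assembly null,
    Fisher's exact test for category enrichment among producer strains, a
    ground-truthed synthetic read generator (random assemblies, restriction
    digest size selection, per-base error model), a slow exact local aligner
    for test-scale data, and assay arithmetic for plate-based growth-inhibition
    percentages and LCMS calibration-curve quantification with LOD/LOQ flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
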