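Package: ssrcore
Title: SSR-Based Germplasm Characterization, Core Collections and Molecular Identity Codes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for microsatellite (SSR) based characterization of
    germplasm collections, developed around dikaryotic fungal strain panels
    such as cultivated Hypsizygus marmoreus. Mines perfect SSR tracts from
    genome assemblies under MISA-style repeat-count thresholds; computes
    per-locus genetic diversity statistics (polymorphic information content,
    observed and effective allele numbers, Nei gene diversity, Shannon
    information index); clusters accessions by simple-matching similarity on
    binary band profiles with UPGMA dendrograms and threshold cuts; selects
    core collections by a greedy maximization strategy that retains full
    allele-class coverage; and assembles per-accession molecular identity
    codes (binary fingerprint, trait code, supplementary code) with 2D-barcode
    payloads. Includes seed-deterministic synthetic-data generators (genomes
    with planted repeats, structured multi-allelic populations, trait
    metadata) that carry ground truth for every pipeline stage, and a
    single-call pipeline runner with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
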