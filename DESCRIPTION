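Package: karyopaint
Title: Oligopaint FISH Probe Design and FISH-Guided Chromosome Assembly Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing Oligopaint fluorescence in situ hybridization
    (FISH) probe libraries against a draft genome and for curating the
    assembly with the resulting hybridization evidence. Includes candidate
    oligo mining under melting-temperature, GC, k-mer-abundance and
    secondary-structure filters; probe-window selection and per-scaffold
    probe-count allocation; orthogonal barcode (primer/adapter/detector)
    screening and 79-mer assembly with fluorophore colour schemes;
    interpretation of hybridization observations to assign scaffolds to
    chromosomes, detect chimeric and internally reordered scaffolds,
    localize breakpoints by synteny, and emit a chromosome-level AGP build
    with an idiogram table; assembly contiguity statistics (N50, L90);
    synteny-block chaining and parsimony classification of chromosome
    rearrangements. A synthetic-data module generates toy genomes with
    planted mis-assemblies and simulated hybridization observations so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
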