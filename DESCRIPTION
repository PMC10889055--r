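Package: caism
Title: Context-Aware In Silico Mutagenesis for Regulatory Variant Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the predicted chromatin-level effect of single-nucleotide
    variants by in silico mutagenesis: fixed-length sequence windows are built
    around a candidate variant with controlled allele substitution, a pluggable
    sequence-to-chromatin-feature annotator predicts per-feature probabilities
    for reference and alternate alleles, and effects are summarised as
    log-odds changes and an E statistic calibrated against an empirical
    background null of randomly sampled variants. Neighbouring variants inside
    the window define the genetic context; all major/minor combinations can be
    enumerated to test whether an allele's effect depends on its haplotype
    background. Companion stages compare effects across linkage-disequilibrium
    groups (r-squared from phased haplotypes) and validate candidate pairs in
    case/control genotype data with carrier-group proportions and an
    allele-based epistasis test. A deterministic synthetic annotator with
    planted motif effects, plus generators for genomes, haplotypes and
    cohorts, provide ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
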