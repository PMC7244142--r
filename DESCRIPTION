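Package: migseqr
Title: Museomics Phylogenomics for MIGseq Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for reduced-representation
    (MIGseq / ISSR-anchored) sequencing of herbarium and silica-dried plant
    material. Provides locus assembly with an explicit filter cascade
    (depth, allele, ambiguity, heterozygosity, indel and taxon-occupancy
    filters), joint maximum-likelihood estimation of heterozygosity and
    sequencing error, read-versus-consensus deamination damage profiling,
    genomic-context characterization of locus positions (nearest annotated
    feature, density per chromosome, spacing randomness), pooled per-locus
    pairwise p-distance divergence statistics across biogeographic zone
    configurations with two-way ANOVA and Tukey HSD, neighbor-joining trees
    on locus presence-absence with bootstrap supports, and penalized-likelihood
    divergence dating with fossil calibration and cross-validated rate
    smoothing. A seeded synthetic-data module generates dated species trees,
    Jukes-Cantor loci, age- and preservation-dependent locus dropout and
    damaged or damage-free reads so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
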