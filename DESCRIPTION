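Package: epimark
Title: Methylation-Sensitive AFLP Scoring, Epigenetic Population
    Statistics, and CpG Depletion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population epigenetics with anonymous dominant
    markers and sequence composition. Scores methylation-sensitive AFLP
    (MS-AFLP) band profiles from parallel MspI/HpaII digests into
    four-state methylation patterns, classifies methylation-susceptible
    loci, and derives binary epilocus matrices under the MSL and Mixed
    Scoring 2 conventions. Quantifies within-group epigenetic diversity
    (polymorphism, private markers, Shannon information) and among-group
    differentiation by permutation AMOVA (Phi-ST/PhiPT). Computes
    per-contig CpG, GpC and TpG observed/expected ratios from
    transcriptome contigs, applies ORF/GO/expression filters, bins
    contigs into GO Slim categories and runs the category and
    between-group comparisons. Calls per-cytosine methylation by
    comparing bisulfite-converted reads against an untreated reference.
    Includes seeded simulators for MS-AFLP profiles, CpG-depleted coding
    sequence, and bisulfite conversion, so every stage can be exercised
    end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
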