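Package: cugscribe
Title: Predicting CUG Codon Translation (Leucine versus Serine) in Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines the most probable translation of the CUG codon
    (leucine under the standard genetic code, serine under the Alternative
    Yeast Codon Usage) for yeast genome or transcriptome assemblies.
    Candidate homologs of a reference set of protein families are located by
    translated k-mer seeding and local alignment, mapped onto the reference
    multiple sequence alignments by sequence-to-profile alignment, and every
    CUG site is scored on amino-acid composition and CUG-position
    conservation in the reference data, with per-protein and genome-wide
    majority-rule verdicts. Also provides translation utilities for both
    codes, translation checking of annotated proteins, classification of
    tRNA-CAG genes as leucine- or serine-type by nearest-reference alignment,
    four classic pairwise alignment algorithms (Needleman-Wunsch, Gotoh,
    Smith-Waterman, longest common subsequence), and a synthetic-data
    generator that emits reference bundles, query genomes and tRNA sets with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
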