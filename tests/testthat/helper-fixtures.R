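# Shared fixtures, built in code.

# scaled-down simulation settings for fast unit tests
small_cfg <- function(...) {
  sim_config(n_families = 3, family_length = 120, n_standard = 6, n_aycu = 6,
             n_cug_columns = 3, flank = 120, genes_per_contig = 2, ...)
}

# a hand-built reference family with fully known structure:
#   col 1: M everywhere (anchor)
#   col 2: serine-type CUG column -- S in every row, CUG-annotated in the
#          aycu rows (a1, a2, a3)
#   col 3: leucine-type CUG column -- L in every row, CUG-annotated in the
#          standard rows (s1, s2)
#   col 4: mixed column, no annotation
#   col 5: gap in row a3
#   col 6: K everywhere
# row s3 is incomplete and CUG-annotated at column 4 (its residue there is
# non-gap), for exercising the completeness restriction.
toy_family <- function() {
  msa <- c(a1 = "MSLGAK", a2 = "MSLGAK", a3 = "MSLP-K",
           s1 = "MSLGAK", s2 = "MSLPAK", s3 = "MSLGAK")
  cug <- data.frame(
    seq_id = c("a1", "a2", "a3", "s1", "s2", "s3"),
    column = c(2L, 2L, 2L, 3L, 3L, 4L),
    stringsAsFactors = FALSE)
  species <- setNames(c("spA1", "spA2", "spA3", "spS1", "spS2", "spS3"),
                      names(msa))
  complete <- setNames(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), names(msa))
  decoding <- c(spA1 = "aycu", spA2 = "aycu", spA3 = "aycu",
                spS1 = "standard", spS2 = "standard", spS3 = "standard")
  reference_family("toy", msa, cug, species, complete, decoding)
}

# a predicted_gene object assembled by hand (no search involved)
toy_gene <- function(codons, contig = "c1", strand = "+", start = 1L) {
  protein <- vapply(codons, function(cd) translate_dna(cd, "standard"), "")
  structure(list(contig = contig, strand = strand,
                 protein = paste(protein, collapse = ""),
                 codons = codons,
                 codon_start = as.integer(start + 3L * (seq_along(codons) - 1L)),
                 score = 100, frame = 1L),
            class = "predicted_gene")
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")
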