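test_that("six-frame translation covers both strands with traceable codons", {
  f <- six_frame_translate("ATGAAA")
  expect_identical(f[[1]]$protein, "MK")
  expect_identical(f[[1]]$codon_start, c(1L, 4L))
  # reverse complement of CTG is CAG
  expect_identical(six_frame_translate("CTG")[[4]]$protein, "Q")
  # frame -1 equals frame +1 of the reverse complement
  set.seed(13)
  for (i in 1:10) {
    dna <- random_dna_str(sample(30:60, 1))
    f <- six_frame_translate(dna)
    g <- six_frame_translate(reverse_complement(dna))
    expect_identical(f[[4]]$protein, g[[1]]$protein)
  }
})

test_that("every six-frame residue traces back to its codon", {
  set.seed(17)
  dna <- random_dna_str(100)
  L <- nchar(dna)
  for (fr in six_frame_translate(dna)) {
    prot <- strsplit(fr$protein, "")[[1]]
    for (i in seq_along(prot)) {
      s <- fr$codon_start[i]
      codon <- substr(dna, s, s + 2L)
      if (fr$strand == "-") codon <- reverse_complement(codon)
      expect_identical(translate_dna(codon, "standard"), prot[i])
    }
  }
})

test_that("candidate regions are seeded, merged and flanked correctly", {
  set.seed(23)
  ref <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      100, replace = TRUE), collapse = "")
  code <- genetic_code("standard")
  back <- vapply(strsplit(ref, "")[[1]],
                 function(a) sample(names(code)[code == a], 1), "")
  gene <- paste(back, collapse = "")
  contig <- paste0(random_dna_str(800), gene, random_dna_str(800))
  regions <- find_candidate_regions(c(c1 = contig), ref, k = 4,
                                    min_word_hits = 2, flank = 500)
  expect_identical(nrow(regions), 1L)
  expect_identical(regions$strand, "+")
  expect_lte(regions$start, 801 - 500 + 3)
  expect_gte(regions$end, 800 + nchar(gene) + 500 - 3)
  # no shared words at all -> no regions
  none <- find_candidate_regions(c(c1 = random_dna_str(300)),
                                 strrep("W", 50), k = 4)
  expect_identical(nrow(none), 0L)
  expect_error(find_candidate_regions(c(c1 = contig), "MK", k = 4),
               "shorter than")
})

test_that("nearby seed clusters merge after flank extension", {
  set.seed(29)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  code <- genetic_code("standard")
  bt <- function(p) paste(vapply(strsplit(p, "")[[1]],
                                 function(a) sample(names(code)[code == a], 1),
                                 ""), collapse = "")
  # two halves of the reference 100 nt apart: extended intervals overlap
  contig <- paste0(random_dna_str(700), bt(substr(ref, 1, 30)),
                   random_dna_str(100), bt(substr(ref, 31, 60)),
                   random_dna_str(700))
  regions <- find_candidate_regions(c(c1 = contig), ref, k = 4, flank = 500)
  expect_identical(nrow(regions), 1L)
})

test_that("extract_best_gene recovers a planted gene exactly", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, 80, replace = TRUE), collapse = "")
  code <- genetic_code("standard")
  back <- vapply(strsplit(ref, "")[[1]],
                 function(a) sample(names(code)[code == a], 1), "")
  gene <- paste(back, collapse = "")
  contig <- c(c1 = paste0(random_dna_str(300), gene, random_dna_str(300)))
  region <- find_candidate_regions(contig, ref, flank = 200)
  g <- extract_best_gene(contig, region[1, ], ref)
  expect_s3_class(g, "predicted_gene")
  expect_identical(g$protein, ref)
  expect_identical(g$strand, "+")
  # self-score of the reference under BLOSUM62
  self <- smith_waterman(ref, ref, protein_scheme())$score
  expect_equal(g$score, self)
  # the codon coordinate map reproduces every codon
  for (i in seq_along(back))
    expect_identical(substr(contig[[1]], g$codon_start[i],
                            g$codon_start[i] + 2L), back[[i]])
  # a hopeless region yields NULL
  expect_null(extract_best_gene(contig,
                                list(contig = "c1", strand = "+",
                                     start = 1L, end = 90L),
                                strrep("W", 60), min_score = 50))
})

test_that("a CTG planted at a leucine codon is rendered L and traceable", {
  set.seed(37)
  aa <- strsplit("ACDEFGHIKMNPQRSTVWY", "")[[1]]  # no L yet
  ref <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  substr(ref, 30, 30) <- "L"
  code <- genetic_code("standard")
  back <- vapply(strsplit(ref, "")[[1]],
                 function(a) sample(names(code)[code == a], 1), "")
  back[30] <- "CTG"
  contig <- c(c1 = paste0(random_dna_str(250),
                          paste(back, collapse = ""), random_dna_str(250)))
  g <- find_family_gene(contig, ref, flank = 200)
  expect_identical(substr(g$protein, 30, 30), "L")
  expect_identical(g$codons[30], "CTG")
  expect_identical(substr(contig[[1]], g$codon_start[30],
                          g$codon_start[30] + 2L), "CTG")
})

test_that("minus-strand genes are recovered with mirrored coordinates", {
  set.seed(41)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, 80, replace = TRUE), collapse = "")
  code <- genetic_code("standard")
  back <- vapply(strsplit(ref, "")[[1]],
                 function(a) sample(names(code)[code == a], 1), "")
  gene <- paste(back, collapse = "")
  fwd <- c(c1 = paste0(random_dna_str(300), gene, random_dna_str(300)))
  rev <- c(c1 = reverse_complement(fwd[[1]]))
  gf <- find_family_gene(fwd, ref, flank = 200)
  gr <- find_family_gene(rev, ref, flank = 200)
  expect_identical(gf$protein, gr$protein)
  expect_identical(gr$strand, "-")
  L <- nchar(fwd[[1]])
  # codon i at forward position s maps to L - s - 1 on the mirrored contig
  expect_identical(gr$codon_start, L - gf$codon_start - 1L)
})
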