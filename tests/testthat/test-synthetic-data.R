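test_that("the same seed reproduces every simulated object exactly", {
  cfg <- small_cfg()
  b1 <- simulate_reference_bundle(cfg, seed = 11)
  b2 <- simulate_reference_bundle(cfg, seed = 11)
  expect_identical(b1, b2)
  g1 <- simulate_query_genome(b1, "aycu", cfg, seed = 12)
  g2 <- simulate_query_genome(b2, "aycu", cfg, seed = 12)
  expect_identical(g1, g2)
  expect_false(identical(b1, simulate_reference_bundle(cfg, seed = 13)))
})

test_that("simulated bundles honour purity and completeness settings", {
  cfg <- small_cfg(purity = 1, fraction_incomplete = 0)
  b <- simulate_reference_bundle(cfg, seed = 21)
  expect_true(all(b$sequences$complete))
  for (fid in names(b$families)) {
    fam <- b$families[[fid]]
    gt <- b$ground_truth$families[[fid]]
    ayc <- names(fam$msa)[fam$decoding == "aycu"]
    for (sid in ayc)
      for (col in gt$ser_cols)
        expect_identical(substr(fam$msa[[sid]], col, col), "S")
  }
})

test_that("simulated bundles satisfy the reference invariants", {
  b <- simulate_reference_bundle(small_cfg(fraction_incomplete = 0.3),
                                 seed = 31)
  expect_true(validate_reference_bundle(b))
  # annotated columns carry class-consistent residues in their rows
  for (fam in b$families) {
    for (i in seq_len(nrow(fam$cug))) {
      res <- substr(fam$msa[[fam$cug$seq_id[i]]], fam$cug$column[i],
                    fam$cug$column[i])
      dec <- fam$decoding[[fam$cug$seq_id[i]]]
      expect_identical(res, if (dec == "aycu") "S" else "L")
    }
  }
})

test_that("query genomes plant CUG codons exactly where recorded", {
  cfg <- small_cfg(query_identity = 1, query_indel_rate = 0)
  b <- simulate_reference_bundle(cfg, seed = 41)
  for (dec in c("aycu", "standard")) {
    g <- simulate_query_genome(b, dec, cfg, seed = 42)
    expect_identical(g$truth$decoding, dec)
    for (gene in g$truth$genes) {
      codons <- substring(gene$dna, seq(1, nchar(gene$dna), 3),
                          seq(3, nchar(gene$dna), 3))
      expect_identical(which(codons == "CTG"), gene$sites$residue)
      # planted columns belong to the class designated for this decoding
      gt <- b$ground_truth$families[[gene$family]]
      want <- if (dec == "aycu") gt$ser_cols else gt$leu_cols
      expect_true(all(gene$sites$column %in% want))
      # the gene really sits where the truth says
      placed <- substr(g$contigs[[gene$contig]], gene$start, gene$end)
      if (gene$strand == "-") placed <- reverse_complement(placed)
      expect_identical(placed, gene$dna)
    }
  }
})

test_that("a clean query gene is recovered exactly by the homolog finder", {
  cfg <- small_cfg(query_identity = 1, query_indel_rate = 0)
  b <- simulate_reference_bundle(cfg, seed = 51)
  g <- simulate_query_genome(b, "aycu", cfg, seed = 52)
  gene <- g$truth$genes[[1]]
  found <- find_family_gene(g$contigs, gene$protein, flank = cfg$flank)
  # predicted proteins render CUG-encoded residues as leucine
  want <- strsplit(gene$protein, "")[[1]]
  want[gene$sites$residue] <- "L"
  expect_identical(found$protein, paste(want, collapse = ""))
  expect_identical(found$codons[gene$sites$residue],
                   rep("CTG", nrow(gene$sites)))
})

test_that("tRNA reference sets are built around divergent class consensi", {
  cfg <- sim_config(trna_noise = 0)
  trna <- simulate_trna_refs(cfg, seed = 61)
  # zero noise: every member equals its class consensus
  expect_identical(length(unique(unname(trna$refs$leu_cag))), 1L)
  expect_identical(length(unique(unname(trna$refs$ser_cag))), 1L)
  # class sizes follow the configuration
  expect_length(trna$refs$leu_cag, 51)
  expect_length(trna$refs$ser_cag, 22)
  expect_length(trna$refs$other, 34)
  # every CAG-class reference carries its anticodon inside the window
  trna2 <- simulate_trna_refs(sim_config(), seed = 62)
  for (x in c(trna2$refs$leu_cag, trna2$refs$ser_cag))
    expect_identical(find_cag_anticodon(x), 34L)
  # the two consensi differ by at least a quarter of their positions
  lc <- strsplit(trna$refs$leu_cag[[1]], "")[[1]]
  sc <- strsplit(trna$refs$ser_cag[[1]], "")[[1]]
  expect_gte(mean(lc != sc), 0.25)
})
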