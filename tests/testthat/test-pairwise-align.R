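unit <- scoring_scheme(match = 1, mismatch = -1, gap = 1,
                       gap_open = 0, gap_extend = 1)

test_that("needleman_wunsch matches hand-derived global optima", {
  r <- needleman_wunsch("ACGT", "ACGT", unit)
  expect_equal(r$score, 4)
  expect_identical(r$aligned_a, "ACGT")
  expect_identical(r$aligned_b, "ACGT")
  # optimum confirmed by exhaustive enumeration of all global alignments
  expect_equal(needleman_wunsch("ACGT", "AGT", unit)$score, 2)
  # substitution ties two gaps (-1 vs -2); the diagonal-first tie-break
  # resolves to the substitution
  r <- needleman_wunsch("A", "T", unit)
  expect_equal(r$score, -1)
  expect_identical(r$aligned_a, "A")
  expect_identical(r$aligned_b, "T")
  # empty input aligns all-gaps at pure gap cost
  r <- needleman_wunsch("", "ACG", unit)
  expect_equal(r$score, -3)
  expect_identical(r$aligned_a, "---")
})

test_that("gotoh charges affine gaps open + k * extend", {
  aff <- scoring_scheme(match = 1, mismatch = -1, gap_open = 2, gap_extend = 1)
  # one 2-gap (cost 4) beats two 1-gaps (cost 6): 2 matches - 4 = -2,
  # confirmed by brute force over all alignments
  r <- gotoh("AAAA", "AA", aff)
  expect_equal(r$score, -2)
  expect_equal(gotoh("ACGT", "ACGT", aff)$score, 4)
  # with zero open cost the affine score collapses to the linear one
  set.seed(3)
  open0 <- scoring_scheme(match = 1, mismatch = -1, gap_open = 0,
                          gap_extend = 1)
  for (i in 1:100) {
    p <- random_seq_pair()
    a <- paste(p$a, collapse = ""); b <- paste(p$b, collapse = "")
    expect_equal(gotoh(a, b, open0)$score,
                 needleman_wunsch(a, b, unit)$score)
  }
})

test_that("smith_waterman finds local optima and never goes negative", {
  r <- smith_waterman("TTTACGTTT", "ACG", unit)
  expect_equal(r$score, 3)
  expect_identical(r$aligned_a, "ACG")
  expect_identical(substr("TTTACGTTT", r$start_a, r$end_a - 1L), "ACG")
  expect_equal(smith_waterman("ACGTT", "ACGTT", unit)$score, 5)
  # disjoint alphabets: the empty alignment at score 0
  r <- smith_waterman("AAAA", "CCCC", unit)
  expect_equal(r$score, 0)
  expect_identical(r$aligned_a, "")
})

test_that("lcs_align scores longest common subsequences", {
  expect_equal(lcs_align("ABCBDAB", "BDCABA")$score, 4)  # e.g. BCBA
  expect_equal(lcs_align("GATTACA", "GATTACA")$score, 7)
  expect_equal(lcs_align("AAAA", "CC")$score, 0)
  # diagonal ops occur only at matches
  r <- lcs_align("ACGT", "AGTC")
  a <- strsplit(r$aligned_a, "")[[1]]; b <- strsplit(r$aligned_b, "")[[1]]
  both <- a != "-" & b != "-"
  expect_true(all(a[both] == b[both]))
})

test_that("alignment results are structurally sound", {
  set.seed(9)
  for (i in 1:40) {
    p <- random_seq_pair()
    a <- paste(p$a, collapse = ""); b <- paste(p$b, collapse = "")
    for (f in list(needleman_wunsch, gotoh,
                   function(x, y, s) smith_waterman(x, y, s))) {
      r <- f(a, b, unit)
      expect_identical(nchar(r$aligned_a), nchar(r$aligned_b))
      # removing gaps recovers the aligned spans of the inputs
      expect_identical(gsub("-", "", r$aligned_a, fixed = TRUE),
                       substr(a, r$start_a, r$end_a - 1L))
      expect_identical(gsub("-", "", r$aligned_b, fixed = TRUE),
                       substr(b, r$start_b, r$end_b - 1L))
    }
    # global spans cover the full inputs
    r <- needleman_wunsch(a, b, unit)
    expect_identical(gsub("-", "", r$aligned_a, fixed = TRUE), a)
    expect_identical(gsub("-", "", r$aligned_b, fixed = TRUE), b)
  }
})

test_that("scores are symmetric and local dominates global", {
  set.seed(21)
  for (i in 1:50) {
    p <- random_seq_pair()
    a <- paste(p$a, collapse = ""); b <- paste(p$b, collapse = "")
    expect_equal(needleman_wunsch(a, b, unit)$score,
                 needleman_wunsch(b, a, unit)$score)
    expect_equal(smith_waterman(a, b, unit)$score,
                 smith_waterman(b, a, unit)$score)
    expect_equal(lcs_align(a, b)$score, lcs_align(b, a)$score)
    expect_gte(smith_waterman(a, b, unit)$score,
               max(0, needleman_wunsch(a, b, unit)$score))
  }
})

test_that("scores agree with an established implementation", {
  # cross-check against Biostrings::pairwiseAlignment on protein pairs
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sch <- protein_scheme(gap_open = 10, gap_extend = 1)
  for (i in 1:10) {
    a <- paste(sample(aa, 25, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 20, replace = TRUE), collapse = "")
    ours <- gotoh(a, b, sch)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 1, type = "global", scoreOnly = TRUE)
    expect_equal(ours, ref)
    ours_l <- smith_waterman(a, b, sch)$score
    ref_l <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 1, type = "local", scoreOnly = TRUE)
    expect_equal(ours_l, ref_l)
  }
})
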