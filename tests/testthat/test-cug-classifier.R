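test_that("composition verdicts follow the majority rule over residue classes", {
  expect_identical(composition_verdict(c(L = 30, I = 5, S = 2)), "standard")
  expect_identical(composition_verdict(c(S = 20, T = 5, L = 3)), "aycu")
  # majority in neither class
  expect_identical(composition_verdict(c(G = 10, P = 8, L = 2)), "ambiguous")
  # exact tie between the classes
  expect_identical(composition_verdict(c(L = 5, S = 5)), "ambiguous")
  # a class must also beat the unclassified remainder
  expect_identical(composition_verdict(c(L = 5, S = 3, G = 6)), "ambiguous")
  # scale invariance
  set.seed(59)
  for (i in 1:30) {
    comp <- setNames(sample.int(20, 4),
                     sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 4))
    k <- sample(2:7, 1)
    expect_identical(composition_verdict(comp), composition_verdict(comp * k))
  }
  # sparse columns give no verdict
  expect_identical(composition_verdict(c(L = 3), min_occupancy = 5),
                   "ambiguous")
})

test_that("conservation counts only complete rows and follows the majority", {
  fam <- toy_family()
  # column 2: CUG in 3 complete aycu rows
  expect_identical(conservation_verdict(fam, 2), "aycu")
  # column 3: CUG in 2 complete standard rows
  expect_identical(conservation_verdict(fam, 3), "standard")
  # column 4: annotated only in the incomplete row s3 -> excluded
  expect_identical(conservation_verdict(fam, 4), "ambiguous")
  # column 6: no reference CUG at all
  expect_identical(conservation_verdict(fam, 6), "ambiguous")
})

test_that("swapping all decoding labels flips every conservation verdict", {
  fam <- toy_family()
  flipped <- fam
  flipped$decoding <- ifelse(fam$decoding == "aycu", "standard", "aycu")
  for (col in 1:6) {
    v <- conservation_verdict(fam, col)
    w <- conservation_verdict(flipped, col)
    expect_identical(w, switch(v, standard = "aycu", aycu = "standard",
                               ambiguous = "ambiguous"))
  }
})

test_that("annotate_cug_sites pairs CTG codons with mapped columns", {
  g <- toy_gene(c("ATG", "AAA", "CTG", "GGT"))
  cm <- structure(c(1L, 2L, 3L, 4L), class = "column_map")
  sites <- annotate_cug_sites(g, cm)
  expect_identical(sites$residue, 3L)
  expect_identical(sites$column, 3L)
  # no CTG -> empty
  g2 <- toy_gene(c("ATG", "AAA"))
  expect_identical(nrow(annotate_cug_sites(g2, cm)), 0L)
  # CTG in a query-only insertion keeps a null column
  cm3 <- structure(c(1L, 2L, NA, 3L), class = "column_map")
  sites3 <- annotate_cug_sites(toy_gene(c("ATG", "AAA", "CTG", "GGT")), cm3)
  expect_identical(sites3$residue, 3L)
  expect_true(is.na(sites3$column))
})

test_that("composition uses all rows while conservation uses complete rows", {
  fam <- toy_family()
  g <- toy_gene(c("ATG", "CTG"))  # CUG at residue 2
  tab <- classify_cug_sites(fam, annotate_cug_sites(
    g, structure(c(1L, 2L), class = "column_map")))
  # column 2 composition: S from all six rows, incomplete s3 included
  expect_identical(tab$occupancy, 6L)
  expect_identical(tab$polar_small, 6L)
  expect_identical(tab$composition_verdict, "aycu")
  expect_identical(tab$cug_as_ser, 3L)
  expect_identical(tab$conservation_verdict, "aycu")
})

test_that("aggregation applies majority rule per feature and combines", {
  mk <- function(comp, cons) {
    n <- length(comp)
    data.frame(family = rep("f", n), residue = seq_len(n),
               column = seq_len(n), occupancy = rep(10L, n),
               hydrophobic = rep(0L, n), polar_small = rep(0L, n),
               cug_as_leu = rep(0L, n), cug_as_ser = rep(0L, n),
               composition_verdict = comp, conservation_verdict = cons,
               stringsAsFactors = FALSE)
  }
  v <- aggregate_verdicts(mk(rep(c("aycu", "standard"), c(35, 4)),
                             rep("aycu", 39)))
  expect_identical(v$composition$verdict, "aycu")
  expect_identical(v$combined, "aycu")
  expect_identical(unname(v$composition$tally["standard"]), 4L)
  # features disagreeing -> combined ambiguous, both reported
  v2 <- aggregate_verdicts(mk(rep("standard", 5), rep("aycu", 5)))
  expect_identical(v2$composition$verdict, "standard")
  expect_identical(v2$conservation$verdict, "aycu")
  expect_identical(v2$combined, "ambiguous")
  # no CUG sites at all is a distinct state
  v3 <- aggregate_verdicts(mk(character(0), character(0)))
  expect_identical(v3$combined, "no-evidence")
  expect_identical(v3$n_sites, 0L)
})

test_that("reference_family enforces its invariants", {
  msa <- c(a = "MS-K", b = "MSLK")
  species <- c(a = "spa", b = "spb")
  complete <- c(a = TRUE, b = TRUE)
  decoding <- c(spa = "aycu", spb = "standard")
  ok <- reference_family("f", msa,
                         data.frame(seq_id = "a", column = 2L), species,
                         complete, decoding)
  expect_s3_class(ok, "reference_family")
  # annotation at a gap column
  expect_error(reference_family("f", msa,
                                data.frame(seq_id = "a", column = 3L),
                                species, complete, decoding), "gap")
  # missing decoding label
  expect_error(reference_family("f", msa,
                                data.frame(seq_id = "a", column = 2L),
                                species, complete, c(spa = "aycu")),
               "decoding")
  # unequal row lengths
  expect_error(reference_family("f", c(a = "MS", b = "MSL"),
                                data.frame(seq_id = character(),
                                           column = integer()),
                                species, complete, decoding), "length")
})
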