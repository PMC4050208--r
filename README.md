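# cugscribe

Predicting how a yeast genome translates the CUG codon: leucine (standard
genetic code) or serine (Alternative Yeast Codon Usage, AYCU).

## The problem

Most *Saccharomycetes*, including *Saccharomyces cerevisiae*, read CUG as
leucine, but many — though not all — of the yeasts called "*Candida*"
(e.g. *C. albicans*, *Debaryomyces hansenii*, *Lodderomyces elongisporus*)
read the same codon as serine, decoded by a mutant ser-tRNA-CAG. Species
names do not predict the code, and public taxonomy-based code assignments
are wrong for several species, so genome annotation pipelines need a way to
determine the decoding directly from assembly data.

The reassignment left a strong comparative signature: nearly all ancestral
CUG codons were lost, so the alignment positions where extant species place
CUG are highly discriminative. A CUG of a standard-code species sits at a
position enriched in large hydrophobic residues (L, I, V, M, F); a CUG of an
AYCU species sits at a small-polar position (S, T, C, A). cugscribe exploits
this with two per-site features computed against a reference set of
annotated protein-family alignments:

* **amino-acid composition** at the query CUG's alignment column
  (hydrophobic majority ⇒ standard, small-polar majority ⇒ AYCU, otherwise
  ambiguous), counted over all reference sequences;
* **CUG-position conservation**: whether completely assembled reference
  genes carry a CUG at the same column, and under which decoding.

A simple majority rule per feature, per protein, and genome-wide yields the
verdict; the two features are reported separately and combined only when
they agree. Independent evidence comes from classifying tRNA genes with a
CAG anticodon as leucine-type or serine-type by nearest-reference local
alignment score.

## What the package provides

* `predict_cug_usage()` — the full pipeline: translated k-mer seeding and
  local alignment locate one homolog per reference family
  (`find_candidate_regions()`, `extract_best_gene()`), the predicted
  protein is mapped onto the family alignment (`align_to_profile()`,
  `align_to_single()`, `nearest_reference_row()`), and every CUG site is
  scored and aggregated (`classify_cug_sites()`, `aggregate_verdicts()`).
* `translate_dna()` / `check_translation()` — translation under either code
  and verification of annotated proteins against their cDNA.
* `classify_trna()` / `find_cag_anticodon()` / `scan_trna_genes()` —
  tRNA-CAG identity calls with score margins.
* `needleman_wunsch()`, `gotoh()`, `smith_waterman()`, `lcs_align()` — the
  four classic pairwise algorithms (Rcpp kernels, deterministic
  tie-breaking).
* `simulate_reference_bundle()` / `simulate_query_genome()` /
  `simulate_trna_refs()` — a synthetic-data generator that emits reference
  bundles, query genomes and tRNA sets with known ground truth, so the
  whole pipeline is testable without any download.
* `read_fasta()`, `load_reference_bundle()`, `render_report()` — I/O,
  validation and JSON/TSV/text reports, plus a CLI
  (`inst/scripts/cugscribe`) with `predict`, `translate`, `check`,
  `classify-trna` and `simulate` subcommands.

## Worked example

```r
library(cugscribe)

cfg    <- sim_config()                                   # 10 families x 30 species x 400 aa
bundle <- simulate_reference_bundle(cfg, seed = 1)
genome <- simulate_query_genome(bundle, decoding = "aycu", cfg, seed = 2)
pred   <- predict_cug_usage(genome$contigs, bundle)
pred
#> CUG decoding prediction: 10 famil(ies) with a predicted gene, 48 CUG site(s)
#> CUG verdict over 48 site(s): aycu
#>   composition   aycu      (standard 0, aycu 48, ambiguous 0)
#>   conservation  aycu      (standard 0, aycu 48, ambiguous 0)
```

All 48 CUG codons found in the predicted genes map to alignment columns
dominated by small polar residues, and every reference CUG at those columns
comes from serine-decoding species — the genome uses the AYCU, as simulated.
The per-site evidence is in `pred$sites`:

```r
head(pred$sites[, c("family", "residue", "column", "hydrophobic",
                    "polar_small", "cug_as_leu", "cug_as_ser")], 3)
#>   family residue column hydrophobic polar_small cug_as_leu cug_as_ser
#> 1  fam01      23     27           0          30          0         12
#> 2  fam01      41     45           0          30          0         14
#> 3  fam01      82     86           0          30          0         11
```

Checking an annotated protein that was translated with the wrong code:

```r
check_translation("MLDS", "ATGCTGGATTCT", code = "aycu")
#> Translation check (code: aycu)
#>   CUG-encoded residues: 2
#>   1 mismatch(es):
#>     residue 2: given L, translated S
```

And the tRNA line of evidence:

```r
classify_trna(bundle$trna$ser_cag[[3]], bundle$trna)
#> tRNA-CAG call: ser (margin 230)
#>   leu    best score 145 (nearest: leu_41)
#>   ser    best score 375 (nearest: ser_03)
#>   other  best score 68 (nearest: oth_29)
```

## Scope notes

The extractor assumes single-exon coding regions (yeast genomes are
intron-poor); spliced genes, pseudogene detection, tRNA secondary-structure
prediction and phylogenetic placement are out of scope. See the methods
vignette (`vignettes/cug-decoding.Rmd`) for the model, parameter choices
and limitations.
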