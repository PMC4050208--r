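---
title: "Predicting CUG decoding in yeasts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CUG decoding in yeasts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cugscribe)
```

## The model

Two genetic codes are in play in yeasts: the standard code, in which CUG is
leucine, and the Alternative Yeast Codon Usage (AYCU), in which a mutant
ser-tRNA-CAG decodes CUG as serine. Because the reassignment proceeded
through near-complete loss of ancestral CUG codons, the positions at which
extant species place CUG codons are strongly class-conserved: CUGs of
standard-code species occur at positions enriched for large hydrophobic
residues (L, I, V, M, F), CUGs of AYCU species at positions enriched for
small polar residues (S, T, C, A). Given a query assembly and a reference
set of annotated protein-family alignments, the decoding can therefore be
inferred from where the query's CUG codons land in those alignments.

Each query CUG site is scored on two features:

* **Composition.** The amino-acid counts at the site's alignment column,
  over *all* reference rows (complete and partial assemblies alike — a
  truncated gene still reports correct residues where it is present). With
  `h` hydrophobic-class, `p` polar-small-class and `n` total residues, the
  verdict is *standard* if `h > p` and `h > n − h − p`, *aycu* if `p > h`
  and `p > n − h − p`, otherwise *ambiguous*. The rule is scale-invariant,
  and columns occupied by fewer than `min_occupancy` residues (default 5)
  are always ambiguous — a handful of residues is no basis for a majority
  claim.
* **CUG-position conservation.** Among reference rows annotated as
  CUG-encoded at the same column, the majority decoding of their species
  wins. Only *completely assembled* reference genes contribute here:
  a partial assembly's missing or truncated regions make its CUG annotation
  unreliable, whereas its residues remain informative for composition.

Verdicts aggregate by simple majority over the non-ambiguous site verdicts,
per feature, at protein and genome level. The two features are always
reported separately — their predictive power differs between positions, and
a core packing position carries more weight in the reader's eye than a
surface loop — and the combined call requires them to agree; disagreement is
ambiguous. A query without any CUG codon yields the distinct state
`no-evidence`, which is not the same as conflicting evidence.

Ties at every level resolve to *ambiguous*. This is deliberate: the method
should never manufacture a decoding call from balanced evidence.

An independent second line of evidence is the identity of the tRNA with a
CAG anticodon: `classify_trna()` assigns a query tRNA to leucine-type,
serine-type, or other by the best local alignment score against three
labelled reference sets, reporting the margin between the top two classes.
Nearest-neighbour raw score is used rather than an E-value model because
the reference sets are small, fixed, and highly structured; the margin is
the honest confidence statement.

## Pipeline and its assumptions

1. **Homolog search.** Each reference family is represented by its
   column-wise consensus. Exact protein 4-mers shared between the consensus
   and the six-frame translation of each contig are clustered by alignment
   diagonal (band of 10 residues, tolerating small indels); clusters with
   at least `min_word_hits = 2` seeds define candidate regions, extended by
   `flank = 500` nt on both sides and merged when they overlap. Diagonal
   clustering matters: isolated chance 4-mer matches are common in
   20-letter space, and merging them naively chains into contig-sized
   regions.
2. **Gene extraction.** Each region is translated in the three frames of
   its strand and locally aligned (Smith-Waterman, BLOSUM62, affine 10/1)
   to the representative; the best-scoring aligned stretch above
   `min_score = 50` becomes the predicted gene — one per family, mirroring
   the one-prediction-per-reference-protein design. The model is strictly
   single-exon; yeast genomes are intron-poor, and spliced genes are a
   documented limitation, not a silent failure mode.
3. **Column mapping.** The predicted protein is mapped onto the family
   alignment; every CUG codon inherits its residue's column. Two design
   points deserve explanation:

   *CUG residues are rendered as leucine but scored as an L/S mixture.*
   Predicted proteins spell CUG-encoded residues as `L` by convention, so
   that downstream software sees one consistent rendering and the decoding
   decision is made only by the classifier. But during column mapping that
   rendering would systematically bias CUG residues away from serine-rich
   columns — the very columns an AYCU genome's CUGs belong to. All mapping
   modes therefore score CUG-encoded residues as an even mixture of the
   leucine and serine substitution rows, which is exactly neutral between
   the two hypotheses.

   *Nearest-row mapping is the default.* `align_to_profile()` implements
   classic sequence-to-profile alignment (match score = occupancy-weighted
   mean substitution score, gap costs scaled by column occupancy). On
   simulated data, however, its optimal paths occasionally slide an indel
   along weakly conserved spans, shifting a stretch of residues — and any
   CUG site in it — by one column. Aligning instead to the single
   best-matching reference row (`nearest_reference_row()`, then global
   affine alignment, transferring columns through that row's own gap
   pattern) places site columns measurably more accurately: the reference
   spans many related species, so a close relative of the query is
   essentially always present, and its gap structure is sharper information
   than the averaged profile. The profile mode and the four classic
   pairwise algorithms remain available via the `aligner` argument.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `k`, `min_word_hits` | 4, 2 | protein word size and minimum seeds per diagonal cluster; permissive, since false regions are filtered by `min_score` |
| `flank` | 500 nt | region extension; partial seed hits of one gene must merge |
| `min_score` | 50 | BLOSUM62 local score to accept a gene; rejects chance seed clusters |
| `min_occupancy` | 5 residues | minimum column occupancy for a composition verdict |
| gap model | affine 10/1 | conventional BLOSUM62 pairing; `gotoh(open = 0)` reduces to linear-gap alignment |
| nucleotide scores | +5/−4 | conventional match/mismatch for tRNA comparison |
| tRNA `min_score` | 100 | roughly a 20-nt exact match; below it the call is `none` |
| anticodon window | positions 32–38 | where a CAG triplet counts as an anticodon in a 70–95 nt tRNA |

## The synthetic-data generator

No curated reference bundle ships with the package, so
`simulate_reference_bundle()` generates one with known ground truth. Per
family it draws a consensus (default 400 residues), then emits rows for 15
standard-decoding and 15 AYCU species, each column mutated at a per-column
rate drawn from U(0.5, 0.95) — spanning weakly to strongly conserved
positions. Each family designates six *serine-type* and six *leucine-type*
CUG columns: at a serine-type column every row keeps a small polar residue
(S with probability `purity = 0.9`, else T/C/A) and AYCU rows are
CUG-annotated where the residue is serine (probability `cug_fraction =
0.9`); leucine-type columns mirror this with L/I/V/M/F and annotation of
standard rows (`standard_cug_fraction = 0.5` — in real data many leucines
are encoded by non-CUG codons). This two-class structure is what the
comparative signature actually looks like: the residue *class* is conserved
across both clades while the *codon* differs between them. A configurable
10% of rows are marked incomplete and tail-truncated; 5% of ordinary
columns carry gaps in a random 30% of rows.

`simulate_query_genome()` back-translates one mutated copy of a complete
reference row per family (70% identity, 1% single-residue indels) with
uniform synonymous codon choice, emitting CTG exactly at the designated
columns (with probability `purity`) and nowhere else, so the planted
positions are provably the genome's complete CUG site set. Genes are packed
onto contigs behind random spacers of at least twice the flank length,
optionally on the reverse strand. `simulate_trna_refs()` builds 51/22/34
leucine/serine/other reference tRNAs from two class consensi at ≥25% mutual
divergence with 10% within-class noise.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate — includes tree-structured sequence evolution (rows are
independent draws around a consensus), codon-usage bias, introns, sequencing
error, and the paralogy traps of real multi-gene families (actins vs
actin-related proteins, tubulin subfamilies), where a transcriptome missing
the true ortholog can pull a paralog onto the wrong reference alignment.

## Numerical and degenerate-input choices

* All DP kernels are exact (no banding, no heuristics); integer schemes
  produce integer scores in double storage. Traceback tie-breaks are fixed
  — diagonal over up over left, and match-state over up-gap over left-gap —
  so results are bit-reproducible.
* Stop codons translate to `*` and do not truncate (`trim_at_stop`
  opts in); the translator is a display-and-check utility, and keeping
  positions aligned with codons is what makes `check_translation()` able to
  point at the exact offending residue. `N`-containing codons give `X`,
  which never counts as a translation mismatch — unknowable is not wrong.
* Alignment against an empty sequence is the all-gap alignment at pure gap
  cost; the empty local alignment at score 0 is allowed.
* All-gap alignment columns are excluded from profile alignment. They can
  never hold a query residue, and charging any gap cost for skipping them
  would make alignment scores depend on representation, not content. (The
  column-scaled open cost would otherwise also let deletion runs "enter"
  free through an all-gap column and evade the open penalty entirely.)
* 1-based, inclusive coordinates everywhere, matching how positions are
  reported; minus-strand codons are addressed by the forward-strand
  position of their leftmost base.
* Bundle validation reports *all* violations at once (annotations pointing
  at gaps, missing decoding labels, ragged alignments), not just the first.

## Test scale

The shipped suite runs the complete pipeline end-to-end on 40 simulated
genomes (seeds 1–20 under each decoding, 10 families each), checks all four
aligners against a brute-force alignment-enumeration oracle on 2,000 random
sequence pairs, re-inserts every reference row of a simulated bundle into
its family profile at 10% divergence, and leave-one-out-classifies a full
51/22/34 tRNA reference set — a few minutes on one CPU. These sizes are the
package's chosen benchmark conditions; `scripts/acceptance.R` recomputes
the same quantities from scratch for any seed.

## Known limitations

* Single-exon gene models only; a gene split by introns will be truncated
  at the best exon.
* The conservation feature inherits the reference annotation's coverage: a
  CUG at a column never CUG-annotated in any complete reference gene is
  ambiguous for that feature no matter how clear the composition is.
* No per-position structural weighting: positions important for folding are
  treated like any other column beyond the occupancy threshold, and the
  per-site evidence is exposed raw instead of folded into a weighted score.
* tRNA scanning is alignment-based; tRNA genes with long introns will be
  missed, and no secondary-structure validation is attempted.
* Transcriptome input is subject to the paralogy caveat above.
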