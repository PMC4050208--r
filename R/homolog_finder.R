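#' Six-frame translation with coordinate maps
#'
#' Translates a contig in all six reading frames under the standard code, so
#' CTG renders as leucine. This deliberate choice keeps homology search
#' agnostic to the CUG decoding question: whether a CUG is "really" serine
#' is decided downstream by the classifier, never during search. Stop codons
#' render as `"*"` (which scores negatively against every residue and so
#' naturally interrupts local alignments); ambiguous IUPAC bases become `N`
#' and translate to `"X"`.
#'
#' @param contig a single DNA string.
#' @return a list of six frames, each a list with `frame` (`+1,+2,+3,-1,-2,-3`),
#'   `strand` (`"+"`/`"-"`), `protein`, and `codon_start`: for residue `i`,
#'   the 1-based forward-strand position of the leftmost base of its codon.
#' @examples
#' six_frame_translate("ATGAAA")[[1]]$protein  # "MK"
#' @export
six_frame_translate <- function(contig) {
  stopifnot(is.character(contig), length(contig) == 1L)
  fwd <- normalize_dna(contig, lenient = TRUE, what = "contig")
  rev <- reverse_complement(fwd)
  L <- nchar(fwd)
  out <- vector("list", 6L)
  k <- 1L
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") fwd else rev
    for (off in 0:2) {
      n <- (nchar(seq) - off) %/% 3L
      prot <- if (n > 0) translate_dna(substring(seq, off + 1L, off + 3L * n)) else ""
      if (n > 0) {
        s <- off + 1L + 3L * (seq_len(n) - 1L)  # codon start in `seq` coords
        codon_start <- if (strand == "+") s else L - s - 1L
      } else codon_start <- integer(0)
      out[[k]] <- list(frame = if (strand == "+") off + 1L else -(off + 1L),
                       strand = strand, protein = prot,
                       codon_start = as.integer(codon_start))
      k <- k + 1L
    }
  }
  out
}

# k-mer matches between a frame translation and the reference protein:
# data frame of (frame position, reference position) pairs
kmer_hits <- function(frame_prot, ref_kmer_pos, k) {
  n <- nchar(frame_prot) - k + 1L
  if (n < 1L)
    return(data.frame(qpos = integer(), rpos = integer()))
  words <- substring(frame_prot, seq_len(n), seq_len(n) + k - 1L)
  m <- ref_kmer_pos[words]
  qpos <- rep.int(seq_len(n), lengths(m))
  data.frame(qpos = qpos, rpos = unlist(m, use.names = FALSE))
}

#' Locate candidate coding regions for a reference protein
#'
#' A deterministic stand-in for a translated (TBLASTN-style) search. Exact
#' protein k-mers shared between the reference and each six-frame
#' translation of a contig are collected as seeds; seeds lying on nearly
#' the same alignment diagonal (within `diag_band` residues, tolerating
#' small indels) are clustered, and only clusters holding at least
#' `min_word_hits` seeds become candidates -- isolated chance word matches
#' are discarded. Each candidate's nucleotide footprint is extended by
#' `flank` nucleotides in both directions (gene predictions improve when
#' intergenic context is included), and overlapping extended intervals on
#' the same contig and strand are combined, mirroring the merging of
#' partial hits that belong to one gene.
#'
#' @param contigs named character vector of contig sequences.
#' @param reference_protein a single amino-acid string.
#' @param k protein word size for seeding.
#' @param min_word_hits minimum number of seed words per diagonal cluster.
#' @param flank extension in nucleotides on both sides.
#' @param diag_band maximum diagonal offset (in residues) within a seed
#'   cluster.
#' @param frame_translations optional precomputed [six_frame_translate()]
#'   results, a named list parallel to `contigs` (re-used across families
#'   by [predict_cug_usage()]).
#' @return a data frame with columns `contig`, `strand`, `start`, `end`
#'   (1-based, inclusive, forward strand, clamped to the contig), and
#'   `n_seeds`.
#' @export
find_candidate_regions <- function(contigs, reference_protein, k = 4,
                                   min_word_hits = 2, flank = 500,
                                   diag_band = 10,
                                   frame_translations = NULL) {
  stopifnot(is.character(contigs), length(contigs) >= 1L,
            !is.null(names(contigs)))
  if (nchar(reference_protein) < k)
    stop("reference protein is shorter than the word size k", call. = FALSE)
  ref <- toupper(reference_protein)
  nref <- nchar(ref) - k + 1L
  words <- substring(ref, seq_len(nref), seq_len(nref) + k - 1L)
  ref_kmer_pos <- split(seq_len(nref), words)
  rows <- list()
  for (cid in names(contigs)) {
    frames <- if (!is.null(frame_translations)) frame_translations[[cid]]
              else six_frame_translate(contigs[[cid]])
    L <- nchar(contigs[[cid]])
    for (fr in frames) {
      hits <- kmer_hits(fr$protein, ref_kmer_pos, k)
      if (!nrow(hits)) next
      diag <- hits$qpos - hits$rpos
      ord <- order(diag, hits$qpos)
      diag <- diag[ord]; hits <- hits[ord, ]
      cl <- cumsum(c(1L, diff(diag) > diag_band))
      cs <- fr$codon_start
      for (g in split(seq_along(cl), cl)) {
        if (length(g) < min_word_hits) next
        q <- hits$qpos[g]
        span <- range(c(cs[q], cs[pmin(q + k - 1L, length(cs))]))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cid, strand = fr$strand,
          start = max(1L, span[1] - as.integer(flank)),
          end = min(L, span[2] + 2L + as.integer(flank)),
          n_seeds = length(g), stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_seeds = integer(), stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  cand <- do.call(rbind, rows)
  out <- list()
  for (key in unique(paste(cand$contig, cand$strand))) {
    h <- cand[paste(cand$contig, cand$strand) == key, ]
    h <- h[order(h$start, h$end), ]
    cur <- h[1, ]
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] <= cur$end) {
        cur$end <- max(cur$end, h$end[i])
        cur$n_seeds <- cur$n_seeds + h$n_seeds[i]
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- h[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract the best single-exon gene model from a candidate region
#'
#' Translates the region in the three reading frames of its strand, locally
#' aligns each translation to the reference protein, and returns the
#' highest-scoring aligned stretch as a predicted gene: its protein (with
#' CTG rendered as leucine), the codon of every residue, and a codon
#' coordinate map giving, for each residue, the forward-strand position of
#' the leftmost base of its codon. Single-exon only; intron-containing genes
#' are out of scope (yeast genomes are intron-poor).
#'
#' @param contigs named character vector of contigs.
#' @param region one row of [find_candidate_regions()] output (or any list
#'   with `contig`, `strand`, `start`, `end`).
#' @param reference_protein the family representative used for seeding.
#' @param scheme a [scoring_scheme()]; defaults to BLOSUM62, affine 10/1.
#' @param min_score minimum local alignment score to accept a gene.
#' @return a `predicted_gene` object (list with `contig`, `strand`,
#'   `protein`, `codons`, `codon_start`, `score`, `frame`), or `NULL` if no
#'   frame reaches `min_score`.
#' @export
extract_best_gene <- function(contigs, region, reference_protein,
                              scheme = protein_scheme(), min_score = 50) {
  cid <- as.character(region$contig)
  sub <- substring(contigs[[cid]], region$start, region$end)
  sub <- normalize_dna(sub, lenient = TRUE, what = "region")
  if (region$strand == "-") sub <- reverse_complement(sub)
  best <- NULL
  for (off in 0:2) {
    n <- (nchar(sub) - off) %/% 3L
    if (n < 1L) next
    prot <- translate_dna(substring(sub, off + 1L, off + 3L * n))
    aln <- smith_waterman(prot, toupper(reference_protein), scheme)
    if (is.null(best) || aln$score > best$score)
      best <- list(score = aln$score, off = off, prot = prot, aln = aln)
  }
  if (is.null(best) || best$score < min_score) return(NULL)
  aln <- best$aln
  if (aln$end_a <= aln$start_a) return(NULL)
  idx <- seq.int(aln$start_a, aln$end_a - 1L)     # residues in frame coords
  s_local <- best$off + 1L + 3L * (idx - 1L)      # codon start within `sub`
  codons <- substring(sub, s_local, s_local + 2L)
  regL <- region$end - region$start + 1L
  codon_start <- if (region$strand == "+") {
    region$start + s_local - 1L
  } else {
    # position of the codon's leftmost forward-strand base
    region$start + (regL - s_local - 2L)
  }
  structure(list(
    contig = cid, strand = region$strand,
    protein = substring(best$prot, aln$start_a, aln$end_a - 1L),
    codons = codons,
    codon_start = as.integer(codon_start),
    score = best$score,
    frame = if (region$strand == "+") best$off + 1L else -(best$off + 1L)
  ), class = "predicted_gene")
}

#' @export
print.predicted_gene <- function(x, ...) {
  cat(sprintf("predicted gene on %s (%s strand, frame %+d), score %g\n",
              x$contig, x$strand, x$frame, x$score))
  cat(sprintf("  %d residues, %d CTG codon(s)\n", nchar(x$protein),
              sum(toupper(x$codons) == "CTG")))
  invisible(x)
}

#' Find the best gene for one reference protein across a whole assembly
#'
#' Convenience wrapper: seeds candidate regions with
#' [find_candidate_regions()], extracts the best gene model from each with
#' [extract_best_gene()], and keeps the single highest-scoring gene -- one
#' gene per reference family, matching the one-prediction-per-family design
#' of the pipeline.
#'
#' @inheritParams find_candidate_regions
#' @inheritParams extract_best_gene
#' @return a `predicted_gene` or `NULL`.
#' @export
find_family_gene <- function(contigs, reference_protein, k = 4,
                             min_word_hits = 2, flank = 500,
                             scheme = protein_scheme(), min_score = 50,
                             frame_translations = NULL) {
  regions <- find_candidate_regions(contigs, reference_protein, k = k,
                                    min_word_hits = min_word_hits,
                                    flank = flank,
                                    frame_translations = frame_translations)
  best <- NULL
  for (i in seq_len(nrow(regions))) {
    g <- extract_best_gene(contigs, regions[i, ], reference_protein,
                           scheme = scheme, min_score = min_score)
    if (!is.null(g) && (is.null(best) || g$score > best$score)) best <- g
  }
  best
}
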