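#' Locate a CAG anticodon in a tRNA sequence
#'
#' Looks for the `CAG` triplet within the expected anticodon window of a
#' tRNA gene (the anticodon sits in the anticodon loop, around position
#' 34-36 of a typical 70-95 nt tRNA). No secondary-structure prediction is
#' attempted; the window is a configurable positional heuristic.
#'
#' @param trna a single DNA/RNA string (introns removed).
#' @param window allowed 1-based start positions of the anticodon.
#' @return the 1-based start position of the anticodon, or `NA` if no CAG
#'   starts within the window.
#' @export
find_cag_anticodon <- function(trna, window = c(32, 38)) {
  x <- normalize_dna(trna, lenient = TRUE, what = "tRNA")
  hits <- gregexpr("CAG", x, fixed = TRUE)[[1]]
  hits <- hits[hits >= window[1] & hits <= window[2]]
  if (!length(hits) || hits[1] < 0) return(NA_integer_)
  as.integer(hits[1])
}

#' Classify a tRNA-CAG as leucine-type, serine-type, or other
#'
#' The amino-acid identity of the tRNA with a CAG anticodon determines the
#' CUG decoding of a species, so this classification is the pipeline's
#' independent second line of evidence. The query is locally aligned
#' against three labelled reference sets (leu-tRNA-CAG, ser-tRNA-CAG, and
#' tRNAs with other anticodons); the best-scoring class wins. The score
#' margin between the best and second-best class is reported so users can
#' judge confidence, and the call is `"none"` when the best score stays
#' below `min_score` or the top two classes tie. Case and U/T spelling of
#' the query are irrelevant.
#'
#' @param query a single tRNA gene sequence.
#' @param refs a `trna_reference_set`: list with non-empty character vectors
#'   `leu_cag`, `ser_cag` and optionally `other`.
#' @param scheme nucleotide [scoring_scheme()] (default +5/-4, affine 10/1).
#' @param min_score minimum acceptable best alignment score.
#' @return a `trna_call`: list with `label` (`"leu"`, `"ser"`, `"other"`,
#'   `"none"`), `scores` (best per class), `margin`, `nearest` (reference id
#'   per class), and `alignment` (query vs nearest reference of the winning
#'   class, for visual inspection).
#' @export
classify_trna <- function(query, refs, scheme = scoring_scheme(),
                          min_score = 100) {
  stopifnot(is.list(refs), length(refs$leu_cag) > 0, length(refs$ser_cag) > 0)
  q <- normalize_dna(query, lenient = TRUE, what = "query tRNA")
  classes <- list(leu = refs$leu_cag, ser = refs$ser_cag,
                  other = refs$other %||% character(0))
  classes <- classes[vapply(classes, length, 1L) > 0]
  best <- setNames(rep(-Inf, length(classes)), names(classes))
  nearest <- setNames(rep(NA_character_, length(classes)), names(classes))
  best_aln <- setNames(vector("list", length(classes)), names(classes))
  for (cl in names(classes)) {
    for (i in seq_along(classes[[cl]])) {
      ref <- normalize_dna(classes[[cl]][[i]], lenient = TRUE)
      aln <- smith_waterman(q, ref, scheme)
      if (aln$score > best[[cl]]) {
        best[[cl]] <- aln$score
        nearest[[cl]] <- names(classes[[cl]])[i] %||% as.character(i)
        best_aln[[cl]] <- aln
      }
    }
  }
  ord <- order(best, decreasing = TRUE)
  top <- names(best)[ord[1]]
  second <- if (length(best) > 1) best[[ord[2]]] else 0
  label <- if (best[[ord[1]]] < min_score) "none"
           else if (length(best) > 1 && best[[ord[1]]] == second) "none"
           else top
  structure(list(label = label,
                 scores = best,
                 margin = if (label == "none") 0 else best[[ord[1]]] - second,
                 nearest = nearest,
                 alignment = if (label %in% names(best_aln)) best_aln[[label]]
                             else best_aln[[ord[1]]]),
            class = "trna_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trna_call <- function(x, ...) {
  cat(sprintf("tRNA-CAG call: %s (margin %g)\n", x$label, x$margin))
  for (cl in names(x$scores))
    cat(sprintf("  %-6s best score %g (nearest: %s)\n", cl, x$scores[[cl]],
                x$nearest[[cl]]))
  invisible(x)
}

#' Scan contigs for tRNA-CAG candidates
#'
#' A deliberately simple heuristic stand-in for a structure-aware tRNA gene
#' finder: slides the pooled reference tRNAs over each contig (both
#' strands) with local alignment and reports non-overlapping hits above
#' `min_score`, classified with [classify_trna()]. Intron-containing tRNA
#' genes (introns can exceed 250 nt) will evade this scan.
#'
#' @param contigs named character vector of contigs.
#' @param refs a `trna_reference_set`.
#' @param scheme nucleotide [scoring_scheme()].
#' @param min_score minimum local alignment score for a candidate.
#' @return a list of `trna_call` objects with `contig` and `strand` fields.
#' @export
scan_trna_genes <- function(contigs, refs, scheme = scoring_scheme(),
                            min_score = 200) {
  pooled <- c(refs$leu_cag, refs$ser_cag)
  out <- list()
  for (cid in names(contigs)) {
    for (strand in c("+", "-")) {
      seq <- normalize_dna(contigs[[cid]], lenient = TRUE)
      if (strand == "-") seq <- reverse_complement(seq)
      best <- NULL
      for (ref in pooled) {
        aln <- smith_waterman(seq, ref, scheme)
        if (aln$score >= min_score && (is.null(best) || aln$score > best$score))
          best <- aln
      }
      if (is.null(best)) next
      cand <- substring(seq, best$start_a, best$end_a - 1L)
      call <- classify_trna(cand, refs, scheme,
                            min_score = min(min_score, 100))
      call$contig <- cid; call$strand <- strand
      out[[length(out) + 1L]] <- call
    }
  }
  out
}
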