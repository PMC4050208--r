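#' Scoring scheme for pairwise and profile alignment
#'
#' Bundles a substitution scoring rule with gap penalties. Either a
#' `(match, mismatch)` pair or a full substitution `matrix` (e.g. BLOSUM62)
#' may be given; the matrix wins when both are present. Gap penalties are
#' magnitudes (non-negative) and applied negatively: a linear-gap algorithm
#' charges `gap` per gapped position, an affine algorithm charges
#' `gap_open + k * gap_extend` for a gap of length `k`.
#'
#' Defaults follow common practice for the two alphabets: nucleotide
#' match/mismatch +5/-4 with affine 10/1, and BLOSUM62 with affine 10/1 for
#' proteins ([protein_scheme()]).
#'
#' @param match,mismatch scores for identical / differing symbols.
#' @param gap linear gap penalty (default: `gap_extend`).
#' @param gap_open,gap_extend affine gap penalties.
#' @param matrix optional substitution matrix with symbol dimnames.
#' @return a `scoring_scheme` object.
#' @examples
#' scoring_scheme(match = 1, mismatch = -1, gap = 1)
#' protein_scheme()  # BLOSUM62, affine 10/1
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap = NULL,
                           gap_open = 10, gap_extend = 1, matrix = NULL) {
  if (is.null(gap)) gap <- gap_extend
  stopifnot(gap >= 0, gap_open >= 0, gap_extend >= 0)
  if (!is.null(matrix))
    stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
              !is.null(colnames(matrix)))
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 gap_open = gap_open, gap_extend = gap_extend,
                 matrix = matrix),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
protein_scheme <- function(gap = NULL, gap_open = 10, gap_extend = 1) {
  scoring_scheme(gap = gap, gap_open = gap_open, gap_extend = gap_extend,
                 matrix = blosum62())
}

# position-wise score matrix for two character vectors under a scheme;
# symbols missing from a substitution matrix are looked up as "X" when
# available, else scored as mismatches
scheme_matrix <- function(a, b, scheme) {
  if (!is.null(scheme$matrix)) {
    syms <- rownames(scheme$matrix)
    fix <- function(x) {
      x[!(x %in% syms)] <- if ("X" %in% syms) "X" else syms[1]
      x
    }
    S <- scheme$matrix[fix(a), fix(b), drop = FALSE]
    dimnames(S) <- NULL
    matrix(as.numeric(S), nrow = length(a))
  } else {
    ifelse(outer(a, b, "=="), scheme$match, scheme$mismatch) * 1.0
  }
}

# assemble an alignment_result from an op path (1 diag, 2 up, 3 left)
path_to_result <- function(a, b, path, score, algorithm,
                           start_a = 1L, start_b = 1L) {
  ia <- cumsum(path != 3L) + (start_a - 1L)
  ib <- cumsum(path != 2L) + (start_b - 1L)
  ca <- rep("-", length(path)); cb <- ca
  ca[path != 3L] <- a[ia[path != 3L]]
  cb[path != 2L] <- b[ib[path != 2L]]
  structure(list(
    score = score,
    aligned_a = paste(ca, collapse = ""),
    aligned_b = paste(cb, collapse = ""),
    start_a = start_a, end_a = if (length(ia)) max(ia, start_a - 1L) + 1L else start_a,
    start_b = start_b, end_b = if (length(ib)) max(ib, start_b - 1L) + 1L else start_b,
    path = path,
    algorithm = algorithm
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, width = 60, ...) {
  cat(sprintf("%s alignment, score %g\n", x$algorithm, x$score))
  a <- x$aligned_a; b <- x$aligned_b
  for (off in seq(1, max(nchar(a), 1), by = width)) {
    cat(substr(a, off, off + width - 1), "\n")
    cat(substr(b, off, off + width - 1), "\n\n")
  }
  invisible(x)
}

# shared preparation: uppercase character vectors
align_prep <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  list(a = chars(toupper(a)), b = chars(toupper(b)))
}

# degenerate global alignment against an empty sequence
empty_global <- function(a, b, per_gap_cost, algorithm) {
  path <- c(rep(2L, length(a)), rep(3L, length(b)))
  path_to_result(a, b, path, -per_gap_cost * length(path), algorithm)
}

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment with a linear gap cost (`scheme$gap` per gapped
#' position). Traceback ties are resolved deterministically, preferring
#' diagonal over up (gap in `b`) over left (gap in `a`). Aligning against an
#' empty sequence yields the all-gap alignment at pure gap cost.
#'
#' @param a,b sequences (single strings; DNA or protein).
#' @param scheme a [scoring_scheme()].
#' @return an `alignment_result` with `score`, gapped `aligned_a` /
#'   `aligned_b`, 1-based coordinates (`end_*` exclusive), and the op path.
#' @examples
#' needleman_wunsch("ACGT", "AGT", scoring_scheme(match = 1, mismatch = -1, gap = 1))
#' @export
needleman_wunsch <- function(a, b, scheme = scoring_scheme()) {
  p <- align_prep(a, b)
  if (length(p$a) == 0L || length(p$b) == 0L)
    return(empty_global(p$a, p$b, scheme$gap, "needleman-wunsch"))
  r <- nw_core(scheme_matrix(p$a, p$b, scheme), scheme$gap)
  path_to_result(p$a, p$b, r$path, r$score, "needleman-wunsch")
}

#' Gotoh global alignment with affine gaps
#'
#' Optimal global alignment where a gap of length `k` costs
#' `gap_open + k * gap_extend`; with `gap_open = 0` the score equals
#' [needleman_wunsch()] with `gap = gap_extend`.
#'
#' @inheritParams needleman_wunsch
#' @return an `alignment_result`.
#' @examples
#' gotoh("AAAA", "AA", scoring_scheme(match = 1, mismatch = -1,
#'                                    gap_open = 2, gap_extend = 1))
#' @export
gotoh <- function(a, b, scheme = scoring_scheme()) {
  p <- align_prep(a, b)
  if (length(p$a) == 0L && length(p$b) == 0L)
    return(path_to_result(p$a, p$b, integer(0), 0, "gotoh"))
  if (length(p$a) == 0L || length(p$b) == 0L) {
    n <- length(p$a) + length(p$b)
    path <- c(rep(2L, length(p$a)), rep(3L, length(p$b)))
    return(path_to_result(p$a, p$b, path,
                          -(scheme$gap_open + n * scheme$gap_extend), "gotoh"))
  }
  S <- scheme_matrix(p$a, p$b, scheme)
  r <- gotoh_core(S, scheme$gap_open, scheme$gap_extend,
                  rep(1.0, length(p$b)))
  path_to_result(p$a, p$b, r$path, r$score, "gotoh")
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment with affine gaps (set `gap_open = 0` for a linear
#' gap cost). The score is never negative; when no positive-scoring pair of
#' substrings exists the result is the empty alignment at score 0.
#'
#' @inheritParams needleman_wunsch
#' @return an `alignment_result`; `start_*` / `end_*` delimit the aligned
#'   spans (1-based, `end_*` exclusive).
#' @examples
#' smith_waterman("TTTACGTTT", "ACG",
#'                scoring_scheme(match = 1, mismatch = -1, gap_open = 0,
#'                               gap_extend = 1))
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  p <- align_prep(a, b)
  if (length(p$a) == 0L || length(p$b) == 0L)
    return(path_to_result(p$a, p$b, integer(0), 0, "smith-waterman"))
  S <- scheme_matrix(p$a, p$b, scheme)
  r <- sw_core(S, scheme$gap_open, scheme$gap_extend)
  res <- path_to_result(p$a, p$b, r$path, r$score, "smith-waterman",
                        start_a = r$start_a, start_b = r$start_b)
  if (length(r$path) == 0L) {
    res$start_a <- res$end_a <- 1L
    res$start_b <- res$end_b <- 1L
  }
  res
}

#' Longest common subsequence
#'
#' Scores the length of a longest common subsequence; equivalent to global
#' alignment with unit match reward, forbidden mismatches, and free gaps.
#' In the returned alignment, diagonal positions occur only where the two
#' sequences agree; all other symbols sit opposite gaps.
#'
#' @param a,b sequences (single strings).
#' @return an `alignment_result` with integer `score`.
#' @examples
#' lcs_align("ABCBDAB", "BDCABA")$score  # 4
#' @export
lcs_align <- function(a, b) {
  p <- align_prep(a, b)
  syms <- unique(c(p$a, p$b))
  r <- lcs_core(match(p$a, syms), match(p$b, syms))
  path_to_result(p$a, p$b, r$path, r$score, "lcs")
}
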