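#' Build a frequency profile from a multiple sequence alignment
#'
#' Summarises an aligned protein family as per-column amino-acid frequency
#' vectors. Frequencies are computed over the canonical 20 amino acids among
#' non-gap residues of each column and sum to 1 wherever the column is
#' occupied; gap content is tracked separately as `occupancy` (number of
#' non-gap residues) so that sparsely occupied columns can be down-weighted
#' during alignment. All-gap columns keep zero occupancy and a zero
#' frequency vector.
#'
#' @param msa named character vector of equal-length gapped rows (uppercase
#'   amino acids and `-`).
#' @return a `profile` object: list with `freq` (20 x ncol matrix), `occupancy`,
#'   `nseq`, `ncol`.
#' @export
build_profile <- function(msa) {
  stopifnot(is.character(msa))
  if (length(msa) == 0L) stop("empty alignment", call. = FALSE)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  M <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  nc <- ncol(M)
  freq <- matrix(0, nrow = length(AA20), ncol = nc, dimnames = list(AA20, NULL))
  for (i in seq_along(AA20)) freq[i, ] <- colSums(M == AA20[i])
  occupancy <- colSums(freq)
  nz <- occupancy > 0
  freq[, nz] <- sweep(freq[, nz, drop = FALSE], 2, occupancy[nz], "/")
  structure(list(freq = freq, occupancy = as.integer(occupancy),
                 nseq = length(msa), ncol = nc),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf("alignment profile: %d columns from %d sequences (%d all-gap)\n",
              x$ncol, x$nseq, sum(x$occupancy == 0)))
  invisible(x)
}

# turn a global op path over (query, columns) into a column map
path_to_colmap <- function(path, nres) {
  col <- cumsum(path != 2L)
  res <- cumsum(path != 3L)
  out <- rep(NA_integer_, nres)
  keep <- path == 1L
  out[res[keep]] <- col[keep]
  structure(out, class = "column_map")
}

#' Align a protein to a family profile
#'
#' Globally aligns a query protein against the columns of a reference
#' alignment profile, returning for every query residue the 1-based
#' alignment column it occupies (or `NA` for residues inserted relative to
#' the reference). The reference alignment itself is never modified. The
#' match score of residue `r` against column `c` is the occupancy-weighted
#' mean substitution score `occ_frac(c) * sum_a freq(c, a) * S(r, a)`, and
#' gap costs for skipping column `c` scale with `occ_frac(c)`, so poorly
#' occupied columns attract weak match scores and are cheap to delete;
#' all-gap columns are free and never affect the score.
#'
#' @param protein query amino-acid string.
#' @param profile a [build_profile()] object.
#' @param scheme a [scoring_scheme()]; defaults to BLOSUM62, affine 10/1.
#' @param cug_residues optional 1-based indices of query residues encoded by
#'   CUG. Such residues are leucine in the rendered protein but may "really"
#'   be serine -- the very question under test -- so they are scored as an
#'   even leucine/serine mixture. This keeps their placement neutral between
#'   the two hypotheses instead of biasing CUG sites away from serine-rich
#'   columns.
#' @return a `column_map`: integer vector, one entry per query residue,
#'   strictly increasing over its non-`NA` entries.
#' @export
align_to_profile <- function(protein, profile, scheme = protein_scheme(),
                             cug_residues = integer(0)) {
  stopifnot(inherits(profile, "profile"))
  if (sum(profile$occupancy) == 0L)
    stop("profile has zero total occupancy", call. = FALSE)
  q <- chars(toupper(protein))
  if (length(q) == 0L)
    return(structure(integer(0), class = "column_map"))
  sub <- if (is.null(scheme$matrix)) blosum62() else scheme$matrix
  qq <- q
  qq[!(qq %in% rownames(sub))] <- "X"
  qsub <- sub[qq, AA20, drop = FALSE]
  if (length(cug_residues))
    qsub[cug_residues, ] <- matrix((sub["L", AA20] + sub["S", AA20]) / 2,
                                   nrow = length(cug_residues),
                                   ncol = length(AA20), byrow = TRUE)
  # all-gap columns are invisible to the alignment: they can never hold a
  # query residue and skipping them must be free
  keep <- which(profile$occupancy > 0L)
  occf <- profile$occupancy[keep] / profile$nseq
  S <- (qsub %*% profile$freq[, keep, drop = FALSE]) *
    rep(occf, each = length(q))
  r <- gotoh_core(S, scheme$gap_open, scheme$gap_extend, occf)
  cm <- path_to_colmap(r$path, length(q))
  cm[] <- keep[as.integer(cm)]
  cm
}

#' Align a protein to a single gapped reference row
#'
#' Pairwise fallback to profile alignment: aligns the query to one reference
#' sequence with the chosen algorithm and transfers alignment columns
#' through that reference row's own gap pattern. Residues aligned to a gap
#' in the reference (or, for the local and LCS algorithms, residues outside
#' the matched region) map to `NA`.
#'
#' @param protein query amino-acid string.
#' @param reference_row one gapped row of the reference alignment.
#' @param algorithm `"nw"`, `"gotoh"`, `"sw"`, or `"lcs"`.
#' @param scheme a [scoring_scheme()].
#' @param cug_residues optional indices of CUG-encoded query residues,
#'   scored as an even leucine/serine mixture as in [align_to_profile()]
#'   (ignored by the `"lcs"` algorithm, which has no substitution scores).
#' @return a `column_map` as in [align_to_profile()].
#' @export
align_to_single <- function(protein, reference_row,
                            algorithm = c("gotoh", "nw", "sw", "lcs"),
                            scheme = protein_scheme(),
                            cug_residues = integer(0)) {
  algorithm <- match.arg(algorithm)
  ref_cols <- which(chars(reference_row) != "-")  # residue -> column
  ref <- gsub("-", "", reference_row, fixed = TRUE)
  p <- align_prep(protein, ref)
  nres <- length(p$a)
  out <- rep(NA_integer_, nres)
  if (nres == 0L || length(p$b) == 0L)
    return(structure(out, class = "column_map"))
  if (algorithm == "lcs") {
    aln <- lcs_align(protein, ref)
  } else {
    S <- scheme_matrix(p$a, p$b, scheme)
    if (length(cug_residues))
      S[cug_residues, ] <- matrix(cug_mixture_scores(p$b, scheme),
                                  nrow = length(cug_residues),
                                  ncol = length(p$b), byrow = TRUE)
    r <- switch(algorithm,
      nw = nw_core(S, scheme$gap),
      gotoh = gotoh_core(S, scheme$gap_open, scheme$gap_extend,
                         rep(1.0, length(p$b))),
      sw = sw_core(S, scheme$gap_open, scheme$gap_extend))
    aln <- path_to_result(p$a, p$b, r$path, r$score, algorithm,
                          start_a = r$start_a %||% 1L,
                          start_b = r$start_b %||% 1L)
  }
  path <- aln$path
  ia <- cumsum(path != 3L) + (aln$start_a - 1L)
  ib <- cumsum(path != 2L) + (aln$start_b - 1L)
  keep <- path == 1L
  if (algorithm == "lcs") {
    keep <- keep & p$a[ia] == p$b[ib]  # defensive; lcs path matches by design
  }
  out[ia[keep]] <- ref_cols[ib[keep]]
  structure(out, class = "column_map")
}

# substitution scores of the ambiguous CUG residue (leucine or serine, the
# question under test) against each reference symbol: even L/S mixture
cug_mixture_scores <- function(ref_chars, scheme) {
  if (!is.null(scheme$matrix)) {
    syms <- rownames(scheme$matrix)
    rc <- ref_chars
    rc[!(rc %in% syms)] <- if ("X" %in% syms) "X" else syms[1]
    (scheme$matrix["L", rc] + scheme$matrix["S", rc]) / 2
  } else {
    (ifelse(ref_chars == "L", scheme$match, scheme$mismatch) +
       ifelse(ref_chars == "S", scheme$match, scheme$mismatch)) / 2
  }
}

#' Find the nearest reference row of a family
#'
#' Returns the sequence id of the reference row with the highest local
#' alignment score against the query -- typically a close relative of the
#' query species, whose own gap pattern then transfers alignment columns
#' more faithfully than the averaged family profile does.
#'
#' @param protein query amino-acid string.
#' @param family a [reference_family()].
#' @param scheme a [scoring_scheme()].
#' @return the sequence id of the best-matching row.
#' @export
nearest_reference_row <- function(protein, family, scheme = protein_scheme()) {
  scores <- vapply(names(family$msa), function(sid)
    smith_waterman(protein, gsub("-", "", family$msa[[sid]], fixed = TRUE),
                   scheme)$score, 0.0)
  names(which.max(scores))
}
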