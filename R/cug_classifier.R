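#' Construct a reference family
#'
#' One protein family of the reference data: a gapped multiple sequence
#' alignment, the per-row annotation of which alignment columns are
#' CUG-encoded, per-row completeness flags, and the decoding label of each
#' row's species. Annotated columns must hold a non-gap residue in their
#' row, and every row needs a decoding label; violations are reported
#' together.
#'
#' @param id family identifier.
#' @param msa named character vector of equal-length gapped rows (names are
#'   sequence ids).
#' @param cug data frame with columns `seq_id`, `column` (1-based alignment
#'   columns encoded by CUG in that row).
#' @param species named character vector: sequence id -> species.
#' @param complete named logical vector: sequence id -> completely assembled.
#' @param decoding named character vector: species -> `"standard"` or
#'   `"aycu"`.
#' @return a `reference_family` object.
#' @export
reference_family <- function(id, msa, cug, species, complete, decoding) {
  probs <- character()
  widths <- unique(nchar(msa))
  if (length(widths) != 1L)
    probs <- c(probs, sprintf("family %s: rows differ in length", id))
  ids <- names(msa)
  for (nm in c("seq_id", "column"))
    if (!nm %in% names(cug))
      probs <- c(probs, sprintf("family %s: cug table lacks column '%s'", id, nm))
  if (!length(probs)) {
    miss <- setdiff(cug$seq_id, ids)
    if (length(miss))
      probs <- c(probs, sprintf("family %s: cug annotation for unknown sequence %s",
                                id, paste(miss, collapse = ", ")))
    for (i in seq_len(nrow(cug))) {
      sid <- cug$seq_id[i]; col <- cug$column[i]
      if (!sid %in% ids) next
      if (col < 1 || col > widths[1] ||
          substr(msa[[sid]], col, col) == "-")
        probs <- c(probs,
                   sprintf("family %s: row %s annotates CUG at gap or out-of-range column %d",
                           id, sid, col))
    }
    nolab <- ids[!(species[ids] %in% names(decoding)) |
                   is.na(species[ids])]
    if (length(nolab))
      probs <- c(probs, sprintf("family %s: no decoding label for rows %s",
                                id, paste(nolab, collapse = ", ")))
    if (any(is.na(complete[ids])))
      probs <- c(probs, sprintf("family %s: missing completeness flag", id))
  }
  if (length(probs)) stop(paste(probs, collapse = "\n"), call. = FALSE)
  structure(list(id = id, msa = msa, ncol = widths[1],
                 cug = cug[, c("seq_id", "column")],
                 species = species[ids],
                 complete = complete[ids],
                 decoding = setNames(unname(decoding[species[ids]]), ids)),
            class = "reference_family")
}

#' List the CUG sites of a predicted gene
#'
#' Pairs every CTG codon of a predicted gene with the reference alignment
#' column its residue maps to. Residues that fall into query-only
#' insertions keep an `NA` column: they exist as CUG sites but cannot be
#' compared against the reference composition.
#'
#' @param gene a `predicted_gene` from [extract_best_gene()].
#' @param colmap a `column_map` from [align_to_profile()] or
#'   [align_to_single()].
#' @return data frame with 1-based `residue` and `column` (may be `NA`).
#' @export
annotate_cug_sites <- function(gene, colmap) {
  stopifnot(inherits(gene, "predicted_gene"))
  codons <- gsub("U", "T", toupper(gene$codons), fixed = TRUE)
  idx <- which(codons == "CTG")
  data.frame(residue = as.integer(idx),
             column = as.integer(colmap[idx]),
             stringsAsFactors = FALSE)
}

#' Amino-acid composition verdict for one alignment column
#'
#' Applies the majority rule to the residue composition at a CUG-bearing
#' column: a majority of large hydrophobic residues (L, I, V, M, F)
#' indicates the standard code, a majority of small polar residues
#' (S, T, C, A) indicates the AYCU, and anything else -- including ties and
#' columns occupied by fewer than `min_occupancy` reference residues -- is
#' ambiguous. A class has the majority when it outnumbers both the other
#' class and all remaining residues. The verdict is scale invariant.
#'
#' @param composition named integer vector of residue counts at the column
#'   (gaps excluded).
#' @param min_occupancy minimum total residue count for a verdict.
#' @return `"standard"`, `"aycu"`, or `"ambiguous"`.
#' @examples
#' composition_verdict(c(L = 30, I = 5, S = 2))  # "standard"
#' composition_verdict(c(L = 5, S = 5))          # tie -> "ambiguous"
#' @export
composition_verdict <- function(composition, min_occupancy = 5) {
  n <- sum(composition)
  if (n < min_occupancy) return("ambiguous")
  h <- sum(composition[names(composition) %in% HYDROPHOBIC_CLASS])
  p <- sum(composition[names(composition) %in% POLAR_SMALL_CLASS])
  rest <- n - h - p
  if (h > p && h > rest) return("standard")
  if (p > h && p > rest) return("aycu")
  "ambiguous"
}

# residue counts at a column over all rows (complete and incomplete)
composition_at_column <- function(family, column) {
  res <- substr(family$msa, column, column)
  res <- res[res != "-"]
  if (!length(res)) return(integer(0))
  tab <- table(res)
  setNames(as.integer(tab), names(tab))
}

# CUG conservation evidence at a column: counts of complete reference rows
# annotated CUG there, split by the decoding of their species
conservation_counts <- function(family, column) {
  ann <- family$cug[family$cug$column == column, , drop = FALSE]
  ann <- ann[family$complete[ann$seq_id], , drop = FALSE]
  dec <- family$decoding[ann$seq_id]
  c(cug_as_leu = sum(dec == "standard"), cug_as_ser = sum(dec == "aycu"))
}

#' CUG-position conservation verdict for one alignment column
#'
#' Checks whether reference genes carry a CUG codon at the same alignment
#' column as the query's CUG, and if so in which decoding context. Only
#' completely assembled reference genes contribute: partial assemblies may
#' miss or truncate the region and their CUG annotation is unreliable.
#' A majority of CUG-bearing rows from standard-decoding species votes
#' standard, from AYCU species votes aycu; no matching CUG in the reference,
#' or a tie, is ambiguous.
#'
#' @param family a [reference_family()].
#' @param column 1-based alignment column.
#' @return `"standard"`, `"aycu"`, or `"ambiguous"`.
#' @export
conservation_verdict <- function(family, column) {
  counts <- conservation_counts(family, column)
  if (counts[["cug_as_leu"]] > counts[["cug_as_ser"]]) return("standard")
  if (counts[["cug_as_ser"]] > counts[["cug_as_leu"]]) return("aycu")
  "ambiguous"
}

#' Score every CUG site of a predicted gene against its reference family
#'
#' Builds the per-site evidence table on which all aggregation rests: for
#' each CUG site, the reference amino-acid composition at its column (over
#' all rows, complete or not), the composition verdict, the CUG
#' conservation counts (complete rows only) and the conservation verdict.
#' Sites in query-only insertions get ambiguous verdicts with zero counts.
#'
#' @param family a [reference_family()].
#' @param sites output of [annotate_cug_sites()].
#' @param min_occupancy minimum column occupancy for a composition verdict.
#' @return data frame with one row per CUG site: `family`, `residue`,
#'   `column`, `occupancy`, `hydrophobic`, `polar_small`, `cug_as_leu`,
#'   `cug_as_ser`, `composition_verdict`, `conservation_verdict`.
#' @export
classify_cug_sites <- function(family, sites, min_occupancy = 5) {
  n <- nrow(sites)
  out <- data.frame(
    family = rep(family$id, n), residue = sites$residue,
    column = sites$column, occupancy = integer(n),
    hydrophobic = integer(n), polar_small = integer(n),
    cug_as_leu = integer(n), cug_as_ser = integer(n),
    composition_verdict = rep("ambiguous", n),
    conservation_verdict = rep("ambiguous", n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    col <- sites$column[i]
    if (is.na(col)) next
    comp <- composition_at_column(family, col)
    cons <- conservation_counts(family, col)
    out$occupancy[i] <- sum(comp)
    out$hydrophobic[i] <- sum(comp[names(comp) %in% HYDROPHOBIC_CLASS])
    out$polar_small[i] <- sum(comp[names(comp) %in% POLAR_SMALL_CLASS])
    out$cug_as_leu[i] <- cons[["cug_as_leu"]]
    out$cug_as_ser[i] <- cons[["cug_as_ser"]]
    out$composition_verdict[i] <- composition_verdict(comp, min_occupancy)
    out$conservation_verdict[i] <-
      if (cons[["cug_as_leu"]] > cons[["cug_as_ser"]]) "standard"
      else if (cons[["cug_as_ser"]] > cons[["cug_as_leu"]]) "aycu"
      else "ambiguous"
  }
  out
}

# majority over non-ambiguous site verdicts; "no-evidence" when there are
# no sites at all
majority_verdict <- function(verdicts) {
  if (!length(verdicts)) return("no-evidence")
  s <- sum(verdicts == "standard"); a <- sum(verdicts == "aycu")
  if (s > a) "standard" else if (a > s) "aycu" else "ambiguous"
}

#' Aggregate per-site verdicts into a protein- or genome-level call
#'
#' Majority vote per feature over the non-ambiguous site verdicts, reported
#' separately for the composition and the conservation feature because
#' their predictive power differs between positions. The combined verdict
#' requires the two feature majorities to agree; disagreement is ambiguous.
#' A query without any CUG site yields the distinct state `"no-evidence"`
#' (a gene simply may not contain the codon in question).
#'
#' @param site_table output of [classify_cug_sites()] (possibly several
#'   families concatenated).
#' @return a `cug_verdict` object: list with `n_sites`, per-feature tallies
#'   (`standard`, `aycu`, `ambiguous`) and verdicts, and `combined`.
#' @export
aggregate_verdicts <- function(site_table) {
  tally <- function(v) c(standard = sum(v == "standard"),
                         aycu = sum(v == "aycu"),
                         ambiguous = sum(v == "ambiguous"))
  comp <- site_table$composition_verdict
  cons <- site_table$conservation_verdict
  vc <- majority_verdict(comp)
  vn <- majority_verdict(cons)
  combined <-
    if (nrow(site_table) == 0L) "no-evidence"
    else if (vc == vn) vc
    else if (vc == "no-evidence") vn   # unreachable once n_sites > 0
    else "ambiguous"
  structure(list(n_sites = nrow(site_table),
                 composition = list(verdict = vc, tally = tally(comp)),
                 conservation = list(verdict = vn, tally = tally(cons)),
                 combined = combined),
            class = "cug_verdict")
}

#' @export
print.cug_verdict <- function(x, ...) {
  if (x$n_sites == 0L) {
    cat("CUG verdict: no-evidence (no CUG codons in the query)\n")
    return(invisible(x))
  }
  cat(sprintf("CUG verdict over %d site(s): %s\n", x$n_sites, x$combined))
  for (f in c("composition", "conservation")) {
    t <- x[[f]]$tally
    cat(sprintf("  %-13s %-9s (standard %d, aycu %d, ambiguous %d)\n",
                f, x[[f]]$verdict, t[["standard"]], t[["aycu"]],
                t[["ambiguous"]]))
  }
  invisible(x)
}

#' Predict the CUG decoding scheme of a genome or transcriptome assembly
#'
#' The full pipeline: for every family of the reference bundle, a
#' representative (the family consensus) seeds a translated homology search
#' over the contigs, the best gene model is extracted, its protein is
#' mapped onto the family alignment, every CUG codon is scored on
#' composition and conservation, and verdicts are aggregated per protein
#' and over the whole assembly.
#'
#' Column mapping defaults to `"nearest"`: the query is globally aligned to
#' the best-matching single reference row and that row's gap pattern
#' transfers the alignment columns. Because the reference spans many
#' related species, the nearest row is usually a close relative whose gap
#' structure places residues more faithfully than the averaged family
#' profile, which blurs clade-specific indel patterns. `"profile"` selects
#' sequence-to-profile alignment instead; `"nw"`, `"gotoh"`, `"sw"`,
#' `"lcs"` map through a pairwise alignment against the family consensus.
#' In every mode CUG-encoded residues are scored as an even
#' leucine/serine mixture (see [align_to_profile()]).
#'
#' @param contigs named character vector of contig sequences (or a FASTA
#'   path).
#' @param bundle a reference bundle from [load_reference_bundle()] or
#'   [simulate_reference_bundle()].
#' @param aligner `"nearest"` (default), `"profile"`, or `"nw"`, `"gotoh"`,
#'   `"sw"`, `"lcs"`.
#' @param k,min_word_hits,flank seeding parameters, see
#'   [find_candidate_regions()].
#' @param min_score minimum local alignment score to accept a gene.
#' @param min_occupancy minimum column occupancy for a composition verdict.
#' @param scheme protein [scoring_scheme()].
#' @return a `cug_prediction` object: list with `genes` (per-family
#'   `predicted_gene`s), `sites` (genome-wide site table), `proteins`
#'   (per-family `cug_verdict`s), `genome` (overall `cug_verdict`), and the
#'   parameters used.
#' @export
predict_cug_usage <- function(contigs, bundle,
                              aligner = c("nearest", "profile", "nw", "gotoh",
                                          "sw", "lcs"),
                              k = 4, min_word_hits = 2, flank = 500,
                              min_score = 50, min_occupancy = 5,
                              scheme = protein_scheme()) {
  aligner <- match.arg(aligner)
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_fasta(contigs)
  genes <- list(); proteins <- list(); site_rows <- list()
  frame_translations <- lapply(contigs, six_frame_translate)
  for (fid in names(bundle$families)) {
    fam <- bundle$families[[fid]]
    rep_info <- family_representative(fam)
    gene <- find_family_gene(contigs, rep_info$protein, k = k,
                             min_word_hits = min_word_hits, flank = flank,
                             scheme = scheme, min_score = min_score,
                             frame_translations = frame_translations)
    if (is.null(gene)) next
    gene$family <- fid
    cug_res <- which(gsub("U", "T", toupper(gene$codons), fixed = TRUE) == "CTG")
    colmap <- if (aligner == "nearest") {
      nn <- nearest_reference_row(gene$protein, fam, scheme)
      align_to_single(gene$protein, fam$msa[[nn]], algorithm = "gotoh",
                      scheme = scheme, cug_residues = cug_res)
    } else if (aligner == "profile") {
      align_to_profile(gene$protein, build_profile(fam$msa), scheme,
                       cug_residues = cug_res)
    } else {
      align_to_single(gene$protein, rep_info$row, algorithm = aligner,
                      scheme = scheme, cug_residues = cug_res)
    }
    sites <- annotate_cug_sites(gene, colmap)
    tab <- classify_cug_sites(fam, sites, min_occupancy = min_occupancy)
    genes[[fid]] <- gene
    proteins[[fid]] <- aggregate_verdicts(tab)
    site_rows[[fid]] <- tab
  }
  sites <- if (length(site_rows)) do.call(rbind, c(site_rows, make.row.names = FALSE))
           else classify_cug_sites(list(id = character(0)),
                                   data.frame(residue = integer(), column = integer()))
  structure(list(genes = genes, sites = sites, proteins = proteins,
                 genome = aggregate_verdicts(sites),
                 params = list(aligner = aligner, k = k,
                               min_word_hits = min_word_hits, flank = flank,
                               min_score = min_score,
                               min_occupancy = min_occupancy)),
            class = "cug_prediction")
}

# family consensus: most frequent non-gap residue per occupied column, and
# the same sequence as a gapped row (gaps at all-gap columns) for
# column-map transfer
family_representative <- function(family) {
  prof <- build_profile(family$msa)
  res <- rep("-", prof$ncol)
  occ <- prof$occupancy > 0
  if (any(occ))
    res[occ] <- AA20[apply(prof$freq[, occ, drop = FALSE], 2, which.max)]
  list(protein = paste(res[occ], collapse = ""),
       row = paste(res, collapse = ""))
}

#' @export
print.cug_prediction <- function(x, ...) {
  cat(sprintf("CUG decoding prediction: %d famil(ies) with a predicted gene, %d CUG site(s)\n",
              length(x$genes), nrow(x$sites)))
  print(x$genome)
  invisible(x)
}
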