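#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings with the conventions used throughout the
#' package: sequences are plain named character vectors, the name is the
#' first whitespace-delimited token of the header, the remainder of the
#' header is kept in a `description` attribute, duplicate ids are an error,
#' and output wraps at 80 columns. Reading and writing round-trips ids,
#' descriptions and sequence content exactly.
#'
#' @param path file path.
#' @return `read_fasta()`: a named character vector with attribute
#'   `description`; an empty file yields an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("empty FASTA file: ", path)
    return(structure(character(0), description = character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  out <- setNames(as.character(set), ids)
  if (any(nzchar(desc))) attr(out, "description") <- desc
  out
}

#' @param sequences named character vector; an optional `description`
#'   attribute (or `descriptions` argument) is appended to the headers.
#' @param descriptions optional character vector of header descriptions.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path, descriptions = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  dup <- names(sequences)[duplicated(names(sequences))]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (is.null(descriptions)) descriptions <- attr(sequences, "description")
  headers <- names(sequences)
  if (!is.null(descriptions)) {
    stopifnot(length(descriptions) == length(sequences))
    headers <- ifelse(nzchar(descriptions),
                      paste(headers, descriptions), headers)
  }
  set <- Biostrings::BStringSet(unname(sequences))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Write a reference bundle to a directory
#'
#' Emits the on-disk layout consumed by [load_reference_bundle()] and the
#' `predict` command: one aligned FASTA per family under `families/`,
#' `cug_annotations.tsv` (family, seq_id, column), `sequences.tsv`
#' (seq_id, family, species, complete), `species.tsv` (species, decoding),
#' the tRNA reference sets under `trna/`, and -- for simulated bundles --
#' `ground_truth.json`.
#'
#' @param bundle a `reference_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "families"), recursive = TRUE, showWarnings = FALSE)
  for (fid in names(bundle$families))
    write_fasta(bundle$families[[fid]]$msa,
                file.path(dir, "families", paste0(fid, ".fa")))
  ann <- do.call(rbind, lapply(bundle$families, function(f)
    if (nrow(f$cug)) cbind(family = f$id, f$cug) else NULL))
  if (is.null(ann))
    ann <- data.frame(family = character(), seq_id = character(),
                      column = integer())
  write.table(ann, file.path(dir, "cug_annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  seqs <- bundle$sequences
  seqs$complete <- ifelse(seqs$complete, "yes", "no")
  write.table(seqs, file.path(dir, "sequences.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$species, file.path(dir, "species.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$trna)) {
    dir.create(file.path(dir, "trna"), showWarnings = FALSE)
    write_fasta(bundle$trna$leu_cag, file.path(dir, "trna", "leu_cag.fa"))
    write_fasta(bundle$trna$ser_cag, file.path(dir, "trna", "ser_cag.fa"))
    if (length(bundle$trna$other))
      write_fasta(bundle$trna$other, file.path(dir, "trna", "other.fa"))
  }
  if (!is.null(bundle$ground_truth))
    jsonlite::write_json(bundle$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load and validate a reference bundle
#'
#' Reads the directory layout written by [write_reference_bundle()],
#' enforcing every structural invariant: equal row lengths per family, CUG
#' annotations pointing at non-gap residues, a completeness flag for every
#' sequence, and a decoding label for every species. All violations are
#' reported together.
#'
#' @param dir bundle directory.
#' @return a `reference_bundle`.
#' @export
load_reference_bundle <- function(dir) {
  need <- c("cug_annotations.tsv", "sequences.tsv", "species.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("reference bundle at ", dir, " lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ann <- read.delim(file.path(dir, "cug_annotations.tsv"),
                    stringsAsFactors = FALSE)
  seqs <- read.delim(file.path(dir, "sequences.tsv"),
                     stringsAsFactors = FALSE)
  spec <- read.delim(file.path(dir, "species.tsv"), stringsAsFactors = FALSE)
  probs <- character()
  if (!all(c("seq_id", "family", "species", "complete") %in% names(seqs)))
    probs <- c(probs, "sequences.tsv must have seq_id, family, species, complete")
  if (!all(c("species", "decoding") %in% names(spec)))
    probs <- c(probs, "species.tsv must have species, decoding")
  if (length(probs)) stop(paste(probs, collapse = "\n"), call. = FALSE)
  bad <- setdiff(unique(spec$decoding), c("standard", "aycu"))
  if (length(bad))
    stop("species.tsv: unknown decoding label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  seqs$complete <- seqs$complete %in% c("yes", "TRUE", "true", "1")
  decoding <- setNames(spec$decoding, spec$species)
  fasta_files <- list.files(file.path(dir, "families"), pattern = "\\.fa$",
                            full.names = TRUE)
  if (!length(fasta_files))
    stop("reference bundle has no families/*.fa alignments", call. = FALSE)
  families <- list(); errors <- character()
  for (fp in fasta_files) {
    fid <- sub("\\.fa$", "", basename(fp))
    msa <- read_fasta(fp)
    info <- seqs[match(names(msa), seqs$seq_id), ]
    if (any(is.na(info$seq_id))) {
      errors <- c(errors, sprintf("%s: sequences.tsv lacks rows for %s", fid,
                                  paste(names(msa)[is.na(info$seq_id)],
                                        collapse = ", ")))
      next
    }
    fam <- tryCatch(
      reference_family(fid, msa,
                       ann[ann$family == fid, c("seq_id", "column")],
                       setNames(info$species, names(msa)),
                       setNames(info$complete, names(msa)),
                       decoding),
      error = function(e) conditionMessage(e))
    if (is.character(fam)) errors <- c(errors, fam)
    else families[[fid]] <- fam
  }
  if (length(errors))
    stop("invalid reference bundle:\n", paste(errors, collapse = "\n"),
         call. = FALSE)
  trna <- NULL
  tdir <- file.path(dir, "trna")
  if (file.exists(file.path(tdir, "leu_cag.fa"))) {
    trna <- structure(list(
      leu_cag = read_fasta(file.path(tdir, "leu_cag.fa")),
      ser_cag = read_fasta(file.path(tdir, "ser_cag.fa")),
      other = if (file.exists(file.path(tdir, "other.fa")))
        read_fasta(file.path(tdir, "other.fa")) else character(0)),
      class = "trna_reference_set")
  }
  gt <- NULL
  if (file.exists(file.path(dir, "ground_truth.json")))
    gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  structure(list(families = families, sequences = seqs, species = spec,
                 trna = trna, ground_truth = gt),
            class = "reference_bundle")
}

#' Validate a reference bundle in memory
#'
#' Re-runs every [reference_family()] invariant check on an existing bundle
#' object and returns all violations instead of stopping at the first.
#'
#' @param bundle a `reference_bundle`.
#' @return invisibly `TRUE`; otherwise an error listing every violation.
#' @export
validate_reference_bundle <- function(bundle) {
  errors <- character()
  for (fid in names(bundle$families)) {
    f <- bundle$families[[fid]]
    res <- tryCatch({
      reference_family(f$id, f$msa, f$cug, f$species, f$complete,
                       setNames(bundle$species$decoding,
                                bundle$species$species))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors <- c(errors, res)
  }
  if (length(errors))
    stop("invalid reference bundle:\n", paste(errors, collapse = "\n"),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.reference_bundle <- function(x, ...) {
  nfam <- length(x$families)
  ncug <- sum(vapply(x$families, function(f) nrow(f$cug), 1L))
  cat(sprintf("reference bundle: %d families, %d sequences, %d species, %d annotated CUG codons\n",
              nfam, nrow(x$sequences), nrow(x$species), ncug))
  invisible(x)
}

#' Render a CUG prediction report
#'
#' Serialises a [predict_cug_usage()] result. `"json"` is the canonical
#' machine-readable form (round-trips without loss), `"tsv"` is the
#' per-site table for spreadsheets, and `"text"` mirrors the
#' summary-plus-detail layout of the original web report: the genome-wide
#' call first, then each reference protein down to single CUG codons. All
#' residue and column indices are 1-based.
#'
#' @param prediction a `cug_prediction`.
#' @param format `"json"`, `"tsv"`, or `"text"`.
#' @param path optional output file; when `NULL` the rendering is returned
#'   as a character value.
#' @return the rendering, invisibly when written to `path`.
#' @export
render_report <- function(prediction, format = c("json", "tsv", "text"),
                          path = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    json = {
      x <- list(
        params = prediction$params,
        genome = unclass(prediction$genome),
        proteins = lapply(prediction$proteins, unclass),
        genes = lapply(prediction$genes, function(g)
          list(family = g$family, contig = g$contig, strand = g$strand,
               frame = g$frame, score = g$score, protein = g$protein,
               start = min(g$codon_start), end = max(g$codon_start) + 2L)),
        sites = prediction$sites)
      jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
    },
    tsv = {
      con <- textConnection("tsv_out", "w", local = TRUE)
      write.table(prediction$sites, con, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      close(con)
      paste(tsv_out, collapse = "\n")
    },
    text = {
      lines <- c("CUG decoding prediction", "=======================", "")
      g <- prediction$genome
      lines <- c(lines, sprintf("Genome verdict: %s", g$combined),
                 sprintf("  CUG sites analysed: %d", g$n_sites))
      if (g$n_sites > 0) {
        for (f in c("composition", "conservation")) {
          t <- g[[f]]$tally
          lines <- c(lines, sprintf(
            "  %-13s %-11s (standard %d | aycu %d | ambiguous %d)",
            f, g[[f]]$verdict, t[["standard"]], t[["aycu"]], t[["ambiguous"]]))
        }
      } else {
        lines <- c(lines, "  no-evidence: the query contains no CUG codons")
      }
      lines <- c(lines, "", "Per-protein detail", "------------------")
      for (fid in names(prediction$proteins)) {
        v <- prediction$proteins[[fid]]
        gene <- prediction$genes[[fid]]
        lines <- c(lines, sprintf("%s: %s (%d site(s); gene on %s, score %g)",
                                  fid, v$combined, v$n_sites, gene$contig,
                                  gene$score))
        st <- prediction$sites[prediction$sites$family == fid, , drop = FALSE]
        for (i in seq_len(nrow(st)))
          lines <- c(lines, sprintf(
            "  CUG at residue %d -> column %s: composition %s (H %d, P %d), conservation %s (leu %d, ser %d)",
            st$residue[i],
            ifelse(is.na(st$column[i]), "insertion", st$column[i]),
            st$composition_verdict[i], st$hydrophobic[i], st$polar_small[i],
            st$conservation_verdict[i], st$cug_as_leu[i], st$cug_as_ser[i]))
      }
      paste(lines, collapse = "\n")
    })
  if (!is.null(path)) {
    writeLines(as.character(out), path)
    return(invisible(out))
  }
  out
}
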