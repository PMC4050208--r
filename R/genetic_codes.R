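#' Genetic code tables for yeasts
#'
#' Returns a codon table as a named character vector of all 64 DNA codons
#' (uppercase, T not U) mapping to amino-acid one-letter codes, with `"*"`
#' for stop codons. Two codes are available: `"standard"` (CUG = leucine)
#' and `"aycu"`, the Alternative Yeast Codon Usage in which CUG is decoded
#' as serine by a mutant ser-tRNA-CAG. The two tables differ at exactly one
#' codon, CTG.
#'
#' @param name `"standard"` or `"aycu"`.
#' @return a named character vector of length 64 with class `genetic_code`
#'   and a `name` attribute.
#' @examples
#' genetic_code("standard")[["CTG"]]  # "L"
#' genetic_code("aycu")[["CTG"]]      # "S"
#' @export
genetic_code <- function(name = c("standard", "aycu")) {
  name <- match.arg(name)
  key <- paste0("code_", name)
  if (is.null(.pkg_cache[[key]])) {
    tab <- Biostrings::GENETIC_CODE
    tab <- setNames(as.character(tab), names(tab))
    if (name == "aycu") tab[["CTG"]] <- "S"
    attr(tab, "name") <- name
    class(tab) <- "genetic_code"
    .pkg_cache[[key]] <- tab
  }
  .pkg_cache[[key]]
}

# accept either a code name or a genetic_code object
as_genetic_code <- function(code) {
  if (inherits(code, "genetic_code")) return(code)
  genetic_code(code)
}

# uppercase, RNA -> DNA; validate alphabet unless lenient
normalize_dna <- function(x, allow = c("A", "C", "G", "T", "N"),
                          lenient = FALSE, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  cc <- chars(x)
  bad <- which(!(cc %in% allow))
  if (length(bad)) {
    if (!lenient)
      stop(sprintf("invalid character '%s' at position %d of %s",
                   cc[bad[1]], bad[1], what), call. = FALSE)
    cc[bad] <- "N"
    x <- paste(cc, collapse = "")
  }
  x
}

#' Translate a DNA/RNA sequence
#'
#' Splits the sequence into codons and translates them under the chosen
#' code. Trailing 1-2 nucleotides that do not fill a codon are ignored.
#' Codons containing `N` translate to `"X"`; stop codons render as
#' `stop_char` and, by default, do not truncate the translation, so that
#' output positions stay aligned with input codons (useful for checking
#' annotated proteins that may span sequencing artefacts).
#'
#' @param dna a single DNA or RNA string over `A,C,G,T,U,N` (case
#'   insensitive).
#' @param code `"standard"`, `"aycu"`, or a [genetic_code()] object.
#' @param stop_char character used for stop codons (default `"*"`).
#' @param trim_at_stop if `TRUE`, the translation stops before the first
#'   stop codon.
#' @return a single amino-acid string of length `floor(nchar(dna) / 3)`
#'   (shorter when `trim_at_stop = TRUE` and a stop occurs).
#' @examples
#' translate_dna("ATGCTGA", "standard")  # "ML"; the 7th nucleotide is ignored
#' translate_dna("ATGCTGA", "aycu")      # "MS"
#' @export
translate_dna <- function(dna, code = "standard", stop_char = "*",
                          trim_at_stop = FALSE) {
  stopifnot(is.character(dna), length(dna) == 1L)
  code <- as_genetic_code(code)
  dna <- normalize_dna(dna)
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  aa[aa == "*"] <- stop_char
  if (trim_at_stop) {
    s <- which(aa == stop_char)
    if (length(s)) aa <- aa[seq_len(s[1] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Check a protein translation against its cDNA
#'
#' Re-translates `cdna` under `code` and compares it position-wise with the
#' given protein. All CTG-encoded residues are reported, together with every
#' mismatch between the given and the re-computed translation, and the
#' corrected protein. The typical use is checking whether an annotated
#' protein from a database was translated with the right CUG decoding:
#' if the only disagreement between candidate codes is CUG, every mismatch
#' falls on a CUG position.
#'
#' A single trailing stop codon on the cDNA is tolerated; `"X"` on either
#' side (unknowable residue) never counts as a mismatch.
#'
#' @param protein the given amino-acid sequence.
#' @param cdna the coding sequence, `nchar(cdna) >= 3 * nchar(protein)`.
#' @param code the code assumed correct for the species.
#' @return an object of class `translation_check`: a list with
#'   `cug_positions` (1-based residue indices encoded by CTG), `mismatches`
#'   (data frame with `position`, `given`, `translated`), `is_consistent`,
#'   and `corrected` (the re-translated protein).
#' @examples
#' check_translation("ML", "ATGCTG", "aycu")  # mismatch at residue 2 (L -> S)
#' @export
check_translation <- function(protein, cdna, code = "standard") {
  stopifnot(is.character(protein), length(protein) == 1L)
  code <- as_genetic_code(code)
  cdna <- normalize_dna(cdna, what = "cdna")
  protein <- toupper(protein)
  np <- nchar(protein)
  ncod <- nchar(cdna) %/% 3L
  if (ncod < np)
    stop(sprintf("cdna holds %d codons but protein has %d residues",
                 ncod, np), call. = FALSE)
  if (ncod > np + 1L)
    stop(sprintf(
      "cdna holds %d codons for a %d-residue protein; at most one trailing stop codon is tolerated",
      ncod, np), call. = FALSE)
  starts <- seq.int(1L, by = 3L, length.out = np)
  codons <- substring(cdna, starts, starts + 2L)
  if (ncod == np + 1L) {
    extra <- substring(cdna, 3L * np + 1L, 3L * np + 3L)
    if (!identical(unname(code[extra]), "*"))
      stop("trailing codon beyond the protein is not a stop codon",
           call. = FALSE)
  }
  translated <- translate_dna(paste(codons, collapse = ""), code)
  given <- chars(protein)
  trans <- chars(translated)
  cug_positions <- which(codons == "CTG")
  differs <- given != trans & given != "X" & trans != "X"
  mism <- which(differs)
  res <- list(
    cug_positions = as.integer(cug_positions),
    mismatches = data.frame(position = as.integer(mism),
                            given = given[mism],
                            translated = trans[mism],
                            stringsAsFactors = FALSE),
    is_consistent = length(mism) == 0L,
    corrected = translated,
    code = attr(code, "name")
  )
  class(res) <- "translation_check"
  res
}

#' @export
print.translation_check <- function(x, ...) {
  cat(sprintf("Translation check (code: %s)\n", x$code))
  cat(sprintf("  CUG-encoded residues: %s\n",
              if (length(x$cug_positions)) paste(x$cug_positions, collapse = ", ")
              else "none"))
  if (x$is_consistent) {
    cat("  given translation is consistent\n")
  } else {
    cat(sprintf("  %d mismatch(es):\n", nrow(x$mismatches)))
    for (i in seq_len(nrow(x$mismatches)))
      cat(sprintf("    residue %d: given %s, translated %s\n",
                  x$mismatches$position[i], x$mismatches$given[i],
                  x$mismatches$translated[i]))
  }
  invisible(x)
}

# codons encoding an amino acid under a code, optionally excluding some
codons_for <- function(aa, code, exclude = character()) {
  code <- as_genetic_code(code)
  out <- names(code)[code == aa]
  setdiff(out, exclude)
}
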