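#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults describe a
#' desk-scale reference bundle (10 families of 400 residues across 15
#' standard-decoding and 15 AYCU species) in which each family carries
#' designated serine-conserved and leucine-conserved CUG columns: at a
#' serine-type CUG column every species keeps a small polar residue
#' (serine with probability `purity`, else T/C/A) and AYCU species encode
#' their serines there by CUG; at a leucine-type column every species
#' keeps a large hydrophobic residue (leucine with probability `purity`)
#' and standard-code species encode a fraction of those leucines by CUG.
#' This mirrors the empirical signature that makes CUG positions
#' discriminative: the residue class at a CUG-bearing column is conserved
#' across both clades while the codon choice differs between them.
#'
#' @param n_families number of protein families.
#' @param family_length alignment length (residues) per family.
#' @param n_standard,n_aycu species per decoding clade.
#' @param conservation range of per-column consensus-match probabilities
#'   for ordinary columns.
#' @param n_cug_columns serine-type and leucine-type CUG columns per family
#'   (each).
#' @param purity probability of the class-defining residue (S or L) at a
#'   CUG column; the remainder is spread over the rest of its class.
#' @param cug_fraction probability that an eligible AYCU row (serine at a
#'   serine-type column) is CUG-annotated.
#' @param standard_cug_fraction likewise for standard rows at leucine-type
#'   columns.
#' @param fraction_incomplete fraction of reference rows marked as
#'   incompletely assembled (tail-truncated).
#' @param gap_column_fraction,gap_row_prob fraction of ordinary columns
#'   carrying indels, and the per-row gap probability at those columns.
#' @param query_identity residue identity of simulated query genes to their
#'   donor reference row (outside CUG columns).
#' @param query_indel_rate per-residue indel probability in query genes.
#' @param flank intergenic spacing unit; genes are separated by at least
#'   twice this many nucleotides so that flank extension cannot merge
#'   neighbouring genes.
#' @param genes_per_contig packing of genes onto contigs.
#' @param minus_strand `FALSE` (all genes on the forward strand), `TRUE`
#'   (all reverse), or `"alternate"`.
#' @param n_leu,n_ser,n_other tRNA reference set sizes (51/22/34 by
#'   default, the composition of the curated tRNA reference set).
#' @param trna_length tRNA gene length in nucleotides.
#' @param trna_noise per-position mutation probability within a tRNA class.
#' @param trna_divergence mutual divergence of the class consensus
#'   sequences.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 10, family_length = 400,
                       n_standard = 15, n_aycu = 15,
                       conservation = c(0.5, 0.95),
                       n_cug_columns = 6, purity = 0.9,
                       cug_fraction = 0.9, standard_cug_fraction = 0.5,
                       fraction_incomplete = 0.1,
                       gap_column_fraction = 0.05, gap_row_prob = 0.3,
                       query_identity = 0.7, query_indel_rate = 0.01,
                       flank = 500, genes_per_contig = 5,
                       minus_strand = FALSE,
                       n_leu = 51, n_ser = 22, n_other = 34,
                       trna_length = 75, trna_noise = 0.1,
                       trna_divergence = 0.3) {
  cfg <- as.list(environment())
  probs <- c(cfg$purity, cfg$cug_fraction, cfg$standard_cug_fraction,
             cfg$fraction_incomplete, cfg$gap_column_fraction,
             cfg$gap_row_prob, cfg$query_identity, cfg$query_indel_rate,
             cfg$trna_noise, cfg$trna_divergence, cfg$conservation)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(cfg, class = "sim_config")
}

# sample a residue different from `aa`
other_residue <- function(aa, pool = AA20) {
  sample(setdiff(pool, aa), 1L)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Simulate a reference bundle with known ground truth
#'
#' Generates per-family alignments, CUG annotations, completeness flags and
#' species decoding labels as described in [sim_config()]. The output has
#' the same structure as a curated reference bundle and passes
#' [validate_reference_bundle()]; the attached `ground_truth` records every
#' designated CUG column so downstream calls can be scored.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @return a `reference_bundle`: list with `families` (named
#'   [reference_family()] list), `sequences`, `species` data frames, `trna`
#'   ([simulate_trna_refs()] output), and `ground_truth`.
#' @export
simulate_reference_bundle <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  species <- c(sprintf("std_%02d", seq_len(config$n_standard)),
               sprintf("ayc_%02d", seq_len(config$n_aycu)))
  decoding <- setNames(rep(c("standard", "aycu"),
                           c(config$n_standard, config$n_aycu)), species)
  families <- list(); seq_rows <- list(); truth <- list()
  L <- config$family_length
  for (f in seq_len(config$n_families)) {
    fid <- sprintf("fam%02d", f)
    consensus <- sample(AA20, L, replace = TRUE)
    cug_cols <- sample.int(L, 2L * config$n_cug_columns)
    ser_cols <- sort(cug_cols[seq_len(config$n_cug_columns)])
    leu_cols <- sort(cug_cols[-seq_len(config$n_cug_columns)])
    consensus[ser_cols] <- "S"; consensus[leu_cols] <- "L"
    cons_rate <- runif(L, config$conservation[1], config$conservation[2])
    normal_cols <- setdiff(seq_len(L), cug_cols)
    gap_cols <- sample(normal_cols,
                       round(config$gap_column_fraction * length(normal_cols)))
    incomplete <- setNames(runif(length(species)) < config$fraction_incomplete,
                           species)
    msa <- character(length(species))
    ann <- list()
    for (s in seq_along(species)) {
      sp <- species[s]
      row <- consensus
      for (c in normal_cols)
        if (runif(1) > cons_rate[c]) row[c] <- other_residue(consensus[c])
      row[ser_cols] <- ifelse(runif(length(ser_cols)) < config$purity, "S",
                              sample(c("T", "C", "A"), length(ser_cols),
                                     replace = TRUE))
      row[leu_cols] <- ifelse(runif(length(leu_cols)) < config$purity, "L",
                              sample(c("I", "V", "M", "F"), length(leu_cols),
                                     replace = TRUE))
      gaps <- gap_cols[runif(length(gap_cols)) < config$gap_row_prob]
      row[gaps] <- "-"
      if (incomplete[[sp]]) {
        cut <- floor(L * runif(1, 0.75, 0.9))
        row[seq.int(cut + 1L, L)] <- "-"
      }
      # CUG annotations: AYCU rows encode (most) serines at serine-type
      # columns by CUG; standard rows a fraction of leucines at
      # leucine-type columns
      if (decoding[[sp]] == "aycu") {
        elig <- ser_cols[row[ser_cols] == "S"]
        ann_cols <- elig[runif(length(elig)) < config$cug_fraction]
      } else {
        elig <- leu_cols[row[leu_cols] == "L"]
        ann_cols <- elig[runif(length(elig)) < config$standard_cug_fraction]
      }
      sid <- paste(fid, sp, sep = "_")
      msa[s] <- paste(row, collapse = "")
      names(msa)[s] <- sid
      if (length(ann_cols))
        ann[[sid]] <- data.frame(seq_id = sid, column = ann_cols,
                                 stringsAsFactors = FALSE)
      seq_rows[[sid]] <- data.frame(seq_id = sid, family = fid, species = sp,
                                    complete = !incomplete[[sp]],
                                    stringsAsFactors = FALSE)
    }
    cug <- if (length(ann)) do.call(rbind, c(ann, make.row.names = FALSE))
           else data.frame(seq_id = character(), column = integer(),
                           stringsAsFactors = FALSE)
    fam_species <- setNames(species, paste(fid, species, sep = "_"))
    fam_complete <- setNames(!incomplete[species],
                             paste(fid, species, sep = "_"))
    families[[fid]] <- reference_family(fid, msa, cug, fam_species,
                                        fam_complete, decoding)
    truth[[fid]] <- list(consensus = paste(consensus, collapse = ""),
                         ser_cols = ser_cols, leu_cols = leu_cols)
  }
  trna <- simulate_trna_refs(config, seed = seed + 1L)
  structure(list(
    families = families,
    sequences = do.call(rbind, c(seq_rows, make.row.names = FALSE)),
    species = data.frame(species = species, decoding = unname(decoding),
                         stringsAsFactors = FALSE),
    trna = trna$refs,
    ground_truth = list(seed = seed, families = truth,
                        trna = trna$truth)),
    class = "reference_bundle")
}

#' Simulate a query genome under a chosen decoding
#'
#' Draws one gene per family from the bundle: a complete reference row of
#' the matching clade is copied, mutated to `query_identity` with a small
#' indel rate, and back-translated with uniform synonymous codon choice --
#' except at the family's designated CUG columns, where the class residue
#' is encoded by CTG with probability `purity`. CTG is never emitted
#' elsewhere, so the planted positions are exactly the genome's CUG sites
#' and every site's ground-truth verdict equals `decoding`. Genes are
#' packed onto contigs separated by random intergenic spacers of at least
#' twice the flank length.
#'
#' @param bundle a [simulate_reference_bundle()] result.
#' @param decoding `"standard"` or `"aycu"`: the code the simulated genome
#'   uses.
#' @param config the [sim_config()] used for the bundle.
#' @param seed integer seed.
#' @return list with `contigs` (named character vector) and `truth`: the
#'   decoding plus, per gene, its family, donor row, contig, strand,
#'   interval, final protein, and planted CUG sites (`residue`, `column`).
#' @export
simulate_query_genome <- function(bundle, decoding = c("aycu", "standard"),
                                  config = sim_config(), seed = 1) {
  decoding <- match.arg(decoding)
  set.seed(seed)
  code <- genetic_code(if (decoding == "aycu") "aycu" else "standard")
  target_aa <- if (decoding == "aycu") "S" else "L"
  genes <- list()
  for (fid in names(bundle$families)) {
    fam <- bundle$families[[fid]]
    gt <- bundle$ground_truth$families[[fid]]
    planted_cols <- if (decoding == "aycu") gt$ser_cols else gt$leu_cols
    donors <- names(fam$msa)[fam$complete & fam$decoding == decoding]
    if (!length(donors)) donors <- names(fam$msa)[fam$complete]
    donor <- sample(donors, 1L)
    row <- chars(fam$msa[[donor]])
    res_cols <- which(row != "-")
    aa <- row[res_cols]
    cols <- res_cols
    # substitutions away from CUG columns
    for (i in seq_along(aa)) {
      if (cols[i] %in% planted_cols) next
      if (runif(1) > config$query_identity) aa[i] <- other_residue(aa[i])
    }
    # 1-residue indels, never touching CUG columns
    keep <- runif(length(aa)) >= config$query_indel_rate / 2 |
      cols %in% planted_cols
    aa <- aa[keep]; cols <- cols[keep]
    ins_after <- which(runif(length(aa)) < config$query_indel_rate / 2)
    if (length(ins_after)) {
      for (i in rev(ins_after)) {
        aa <- append(aa, sample(AA20, 1L), after = i)
        cols <- append(cols, NA_integer_, after = i)
      }
    }
    # back-translate
    codons <- character(length(aa))
    site_res <- integer(0); site_col <- integer(0)
    for (i in seq_along(aa)) {
      planted <- !is.na(cols[i]) && cols[i] %in% planted_cols &&
        aa[i] == target_aa && runif(1) < config$purity
      if (planted) {
        codons[i] <- "CTG"
        site_res <- c(site_res, i); site_col <- c(site_col, cols[i])
      } else {
        codons[i] <- sample(codons_for(aa[i], code, exclude = "CTG"), 1L)
      }
    }
    genes[[fid]] <- list(family = fid, donor = donor,
                         protein = paste(aa, collapse = ""),
                         dna = paste(codons, collapse = ""),
                         columns = cols,
                         sites = data.frame(residue = site_res,
                                            column = site_col,
                                            stringsAsFactors = FALSE))
  }
  # pack onto contigs
  spacer_len <- function() 2L * config$flank + sample(100:300, 1L)
  n_contig <- ceiling(length(genes) / config$genes_per_contig)
  contigs <- character(n_contig)
  names(contigs) <- sprintf("contig%02d", seq_len(n_contig))
  gi <- 0L
  for (ci in seq_len(n_contig)) {
    parts <- random_dna(spacer_len())
    while (gi < length(genes) &&
           (gi %% config$genes_per_contig) < config$genes_per_contig) {
      gi <- gi + 1L
      g <- genes[[gi]]
      strand <- if (identical(config$minus_strand, TRUE)) "-"
                else if (identical(config$minus_strand, "alternate") && gi %% 2L == 0L) "-"
                else "+"
      placed <- if (strand == "-") reverse_complement(g$dna) else g$dna
      start <- nchar(parts) + 1L
      parts <- paste0(parts, placed, random_dna(spacer_len()))
      genes[[gi]]$contig <- names(contigs)[ci]
      genes[[gi]]$strand <- strand
      genes[[gi]]$start <- start
      genes[[gi]]$end <- start + nchar(placed) - 1L
      if (gi %% config$genes_per_contig == 0L) break
    }
    contigs[ci] <- parts
  }
  list(contigs = contigs,
       truth = list(decoding = decoding, seed = seed, genes = genes))
}

#' Simulate labelled tRNA reference sets
#'
#' Builds leucine-type and serine-type tRNA-CAG reference sets from two
#' class consensus sequences that differ at a `trna_divergence` fraction of
#' their positions (anticodon excluded), plus a third set with non-CAG
#' anticodons. Each reference is an independently mutated copy of its class
#' consensus at rate `trna_noise`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `refs` (a `trna_reference_set`: `leu_cag`, `ser_cag`,
#'   `other` named character vectors) and `truth` (data frame `id`,
#'   `label`).
#' @export
simulate_trna_refs <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  L <- config$trna_length
  ac <- 34:36  # anticodon position
  bases <- c("A", "C", "G", "T")
  mutate <- function(x, rate, protect = ac) {
    for (i in seq_along(x)) {
      if (i %in% protect) next
      if (runif(1) < rate) x[i] <- sample(setdiff(bases, x[i]), 1L)
    }
    x
  }
  leu_cons <- sample(bases, L, replace = TRUE)
  leu_cons[ac] <- c("C", "A", "G")
  ser_cons <- mutate(leu_cons, config$trna_divergence)
  other_cons <- mutate(leu_cons, config$trna_divergence)
  make_set <- function(cons, n, prefix, anticodon = NULL) {
    out <- character(n)
    for (i in seq_len(n)) {
      x <- mutate(cons, config$trna_noise)
      if (!is.null(anticodon)) x[ac] <- anticodon()
      out[i] <- paste(x, collapse = "")
    }
    setNames(out, sprintf("%s_%02d", prefix, seq_len(n)))
  }
  non_cag <- function() {
    repeat {
      a <- sample(bases, 3L, replace = TRUE)
      if (!identical(a, c("C", "A", "G"))) return(a)
    }
  }
  refs <- structure(list(
    leu_cag = make_set(leu_cons, config$n_leu, "leu"),
    ser_cag = make_set(ser_cons, config$n_ser, "ser"),
    other = make_set(other_cons, config$n_other, "oth", anticodon = non_cag)),
    class = "trna_reference_set")
  truth <- data.frame(
    id = c(names(refs$leu_cag), names(refs$ser_cag), names(refs$other)),
    label = rep(c("leu", "ser", "other"),
                c(config$n_leu, config$n_ser, config$n_other)),
    stringsAsFactors = FALSE)
  list(refs = refs, truth = truth)
}
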