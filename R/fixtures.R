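# Codon machinery for the synthetic generator. Coding-like codon usage is
# emulated by giving each amino acid one preferred codon (its
# alphabetically first) and weighting it `codon_bias`-fold over the
# synonymous alternatives; this is a synthetic usage pattern, not a real
# organism's codon table.
sense_codons <- function() {
  all <- all_kmers(3L)
  setdiff(all, STOP_CODONS)
}

codon_weights <- function(codon_bias) {
  codons <- sense_codons()
  aa <- Biostrings::GENETIC_CODE[codons]
  preferred <- vapply(split(codons, aa), min, character(1))
  w <- ifelse(codons %in% preferred, codon_bias, 1)
  setNames(w / sum(w), codons)
}

codon_gc <- function(codons) {
  vapply(strsplit(codons, ""), function(ch) sum(ch %in% c("G", "C")), numeric(1))
}

random_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# cap open runs between stops at `limit` codons in every frame by salting
# random stop codons, so spurious ORFs stay short
salt_stops <- function(sequence, limit = 50L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  for (f in 0:2) {
    n_codons <- (L - f) %/% 3L
    if (n_codons < 1L) next
    run <- 0L
    for (ci in seq_len(n_codons)) {
      s <- f + 3L * (ci - 1L) + 1L
      codon <- paste(chars[s:(s + 2L)], collapse = "")
      if (codon %in% STOP_CODONS) {
        run <- 0L
      } else {
        run <- run + 1L
        if (run >= limit) {
          chars[s:(s + 2L)] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
          run <- 0L
        }
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate a labelled synthetic transcript set
#'
#' Produces mRNA-like and lncRNA-like transcripts so the whole pipeline —
#' probability tables, training, evaluation — runs without downloads.
#' mRNA-like records embed an `ATG`...stop open reading frame covering at
#' least `orf_fraction` of the transcript, with skewed synonymous-codon
#' usage (one preferred codon per amino acid, `codon_bias`-fold weight);
#' untranslated flanks are tuned so the overall GC content targets
#' `gc_mrna` on average. lncRNA-like records are near-uniform sequence at
#' `gc_lncrna` GC with stop codons salted into every reading frame so
#' spurious ORFs stay short. Structures come from [fallback_fold()] when
#' `with_structure = TRUE`. Everything is reproducible from `seed`.
#'
#' These fixtures are explicitly synthetic: they emulate the coarse
#' signals that separate real mRNAs from lncRNAs (long biased ORFs,
#' composition) but none of the biology of real corpora, and benchmark
#' numbers on them say nothing about performance on real GENCODE/RefSeq
#' data.
#'
#' @param n_mrna,n_lncrna Number of records per class.
#' @param length_range Transcript length range in nt (inclusive).
#' @param orf_fraction Minimum fraction of an mRNA covered by its embedded
#'   ORF (must be in (0, 1]).
#' @param codon_bias Weight of each amino acid's preferred codon relative
#'   to its synonyms (1 = no bias).
#' @param gc_mrna,gc_lncrna Class GC-content targets.
#' @param with_structure Fold every record with [fallback_fold()]?
#' @param seed Integer seed.
#' @return A transcript tibble with `label` and, for mRNAs, CDS
#'   coordinates of the embedded ORF.
#' @export
generate_transcripts <- function(n_mrna = 500L, n_lncrna = 500L,
                                 length_range = c(200L, 600L),
                                 orf_fraction = 0.5, codon_bias = 8,
                                 gc_mrna = 0.52, gc_lncrna = 0.45,
                                 with_structure = TRUE, seed = 1L) {
  stopifnot(orf_fraction > 0, orf_fraction <= 1,
            length_range[1] >= 200L, length_range[2] <= 20000L)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  cw <- codon_weights(codon_bias)
  gc_per_codon <- sum(cw * codon_gc(names(cw)))  # expected GC bases per codon

  make_mrna <- function(i) {
    L <- sample(length_range[1]:length_range[2], 1L)
    n_codons <- ceiling(orf_fraction * L / 3)
    orf_len <- 3L * n_codons
    if (orf_len > L) orf_len <- 3L * (L %/% 3L)
    n_inner <- orf_len %/% 3L - 2L
    stop_codon <- sample(STOP_CODONS, 1L)
    orf <- paste0(START_CODON,
                  paste(sample(names(cw), max(0L, n_inner), replace = TRUE, prob = cw),
                        collapse = ""),
                  stop_codon)
    utr_len <- L - orf_len
    orf_gc_bases <- 1 + sum(codon_gc(stop_codon)) + max(0L, n_inner) * gc_per_codon
    utr_gc <- if (utr_len > 0) {
      min(0.8, max(0.2, (gc_mrna * L - orf_gc_bases) / utr_len))
    } else 0.5
    utr5_len <- if (utr_len > 0) sample(0:utr_len, 1L) else 0L
    utr3_len <- utr_len - utr5_len
    seq <- paste0(
      if (utr5_len > 0) random_bases(utr5_len, utr_gc) else "",
      orf,
      if (utr3_len > 0) random_bases(utr3_len, utr_gc) else ""
    )
    list(sequence = seq, cds_start = utr5_len, cds_end = utr5_len + orf_len)
  }

  make_lncrna <- function(i) {
    L <- sample(length_range[1]:length_range[2], 1L)
    salt_stops(random_bases(L, gc_lncrna))
  }

  mrnas <- lapply(seq_len(n_mrna), make_mrna)
  lncs <- vapply(seq_len(n_lncrna), make_lncrna, character(1))

  records <- dplyr::bind_rows(
    new_transcripts(
      id = sprintf("mrna_%04d", seq_len(n_mrna)),
      sequence = vapply(mrnas, `[[`, character(1), "sequence"),
      label = "mRNA",
      cds_start = vapply(mrnas, `[[`, numeric(1), "cds_start"),
      cds_end = vapply(mrnas, `[[`, numeric(1), "cds_end")
    ),
    new_transcripts(
      id = sprintf("lnc_%04d", seq_len(n_lncrna)),
      sequence = lncs,
      label = "lncRNA"
    )
  )
  if (with_structure) records <- fold_transcripts(records)
  records
}

#' Write a fixture set to disk
#'
#' Writes `transcripts.fa` (FASTA), `structures.tsv` (id/structure/mfe,
#' for records that have one) and `labels.tsv` (id/label/cds_start/cds_end)
#' into a directory.
#'
#' @param records A transcript tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_fixture_files <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "transcripts.fa")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(records$sequence, records$id)), fa
  )
  st <- file.path(dir, "structures.tsv")
  has_st <- !is.na(records$structure)
  readr::write_tsv(
    tibble(id = records$id[has_st], structure = records$structure[has_st],
           mfe = records$mfe[has_st]),
    st
  )
  lab <- file.path(dir, "labels.tsv")
  readr::write_tsv(
    tibble(id = records$id, label = records$label,
           cds_start = records$cds_start, cds_end = records$cds_end),
    lab
  )
  invisible(c(fasta = fa, structures = st, labels = lab))
}

#' Attach labels (and CDS annotations) from a TSV file
#'
#' The file needs columns `id` and `label`, and optionally `cds_start`/
#' `cds_end` (0-based half-open, for mRNA training records).
#'
#' @param records A transcript tibble.
#' @param path Path to the label TSV.
#' @return The tibble with `label` (and CDS columns) filled in.
#' @export
attach_labels <- function(records, path) {
  lab <- readr::read_tsv(path, col_types = readr::cols())
  stopifnot(all(c("id", "label") %in% names(lab)))
  idx <- match(records$id, lab$id)
  records$label <- as.character(lab$label[idx])
  if ("cds_start" %in% names(lab)) {
    records$cds_start <- as.integer(lab$cds_start[idx])
    records$cds_end <- as.integer(lab$cds_end[idx])
  }
  records
}
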