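#' Read transcript sequences from a FASTA file
#'
#' Reads one record per FASTA entry into a transcript tibble, the container
#' used throughout the package. Sequences are normalised to the canonical
#' uppercase DNA alphabet: lowercase is upcased and `U` becomes `T`, so RNA
#' and DNA FASTA files are interchangeable. No symbol validation happens
#' here — records with characters outside `{A,C,G,T}` are kept verbatim and
#' flagged later by [filter_transcripts()], so the reader never silently
#' drops input.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `id` (first
#'   whitespace-delimited header token), `sequence`, `length`, plus empty
#'   `structure`, `mfe`, `label`, `cds_start`, `cds_end` columns filled by
#'   later steps. Input order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "acgu", ">t2", "TTTT"), fa)
#' read_transcripts(fa)
#' @export
read_transcripts <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate transcript id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  new_transcripts(ids, unname(seqs))
}

#' Construct a transcript tibble from id and sequence vectors
#'
#' @param id Character vector of unique transcript ids.
#' @param sequence Character vector of sequences (normalised as in
#'   [read_transcripts()]).
#' @param label Optional class labels, `"lncRNA"` or `"mRNA"`.
#' @param cds_start,cds_end Optional 0-based half-open CDS coordinates on the
#'   transcript (mRNA training records only).
#' @return A transcript tibble.
#' @export
new_transcripts <- function(id, sequence, label = NA_character_,
                            cds_start = NA_integer_, cds_end = NA_integer_) {
  sequence <- chartr("U", "T", toupper(sequence))
  tibble(
    id = as.character(id),
    sequence = sequence,
    length = nchar(sequence),
    structure = NA_character_,
    mfe = NA_real_,
    label = as.character(label),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end)
  )
}

#' Filter transcripts by length and alphabet
#'
#' Applies the corpus filtration rule used for training and prediction
#' alike: transcripts shorter than `min_len` or longer than `max_len`
#' nucleotides are removed, as are transcripts containing symbols outside
#' `{A,C,G,T}` (ambiguity codes such as `N` or `S`). Both length bounds are
#' inclusive. Filtering is total: every input row ends up either kept or
#' rejected with a reason code.
#'
#' @param records A transcript tibble.
#' @param min_len,max_len Inclusive length bounds in nucleotides.
#' @return The kept rows, with the rejected rows (columns `id`, `length`,
#'   `reason` with codes `too_short`, `too_long`, `invalid_symbol`) attached
#'   as attribute `"rejected"`; retrieve them with [rejected_transcripts()].
#' @seealso [rejected_transcripts()]
#' @export
filter_transcripts <- function(records, min_len = 200L, max_len = 20000L) {
  stopifnot(is.data.frame(records), min_len <= max_len)
  len <- nchar(records$sequence)
  bad_sym <- grepl("[^ACGT]", records$sequence)
  reason <- dplyr::case_when(
    bad_sym ~ "invalid_symbol",
    len < min_len ~ "too_short",
    len > max_len ~ "too_long",
    TRUE ~ NA_character_
  )
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- tibble(
    id = records$id[!is.na(reason)],
    length = len[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  attr(kept, "rejected") <- rejected
  kept
}

#' Rejected rows from the last filtering step
#'
#' @param records A transcript tibble returned by [filter_transcripts()].
#' @return A tibble of rejected records with reason codes (empty if none).
#' @export
rejected_transcripts <- function(records) {
  rej <- attr(records, "rejected")
  if (is.null(rej)) {
    return(tibble(id = character(), length = integer(), reason = character()))
  }
  rej
}

# Parse one structure file into a tibble id/structure/mfe.
# Two dialects: RNAfold-style text (">id" header, sequence line, dot-bracket
# line ending in "( MFE )") or a header-less/headed 3-column TSV.
read_structure_file <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(id = character(), structure = character(), mfe = double()))
  }
  if (startsWith(lines[[1]], ">")) {
    if (length(lines) %% 3L != 0L) {
      stop("RNAfold-style structure file must consist of header/sequence/structure triplets",
           call. = FALSE)
    }
    idx <- seq(1L, length(lines), by = 3L)
    ids <- sub("^>", "", lines[idx])
    ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
    struct_lines <- lines[idx + 2L]
    m <- regmatches(struct_lines,
                    regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", struct_lines))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad)) {
      stop("cannot parse dot-bracket/MFE line for record(s): ",
           paste(ids[bad], collapse = ", "), call. = FALSE)
    }
    tibble(
      id = ids,
      structure = vapply(m, `[`, character(1), 2L),
      mfe = as.numeric(vapply(m, `[`, character(1), 3L))
    )
  } else {
    tab <- utils::read.table(path, sep = "\t", header = grepl("structure", lines[[1]], fixed = TRUE),
                             stringsAsFactors = FALSE,
                             col.names = c("id", "structure", "mfe"))
    tibble(id = as.character(tab$id), structure = tab$structure, mfe = as.numeric(tab$mfe))
  }
}

#' Attach predicted secondary structures to transcripts
#'
#' Joins dot-bracket structures (with their minimum free energies, kcal/mol)
#' onto a transcript tibble. The structure file may be RNAfold-style text
#' (header line, sequence line, dot-bracket line ending in `( MFE )`) or a
#' three-column TSV `id`/`structure`/`mfe`. Every matched structure is
#' validated: its length must equal the sequence length and its parentheses
#' must be balanced. Records without a matching structure are left
#' structure-free and reported with a message.
#'
#' @param records A transcript tibble.
#' @param path Path to the structure file.
#' @return `records` with `structure` and `mfe` filled in where matched.
#' @export
attach_structures <- function(records, path) {
  st <- if (is.data.frame(path)) {
    path
  } else {
    read_structure_file(path)
  }
  idx <- match(records$id, st$id)
  hit <- !is.na(idx)
  if (any(hit)) {
    struct <- st$structure[idx[hit]]
    seqs <- records$sequence[hit]
    mismatch <- nchar(struct) != nchar(seqs)
    if (any(mismatch)) {
      stop("structure length differs from sequence length for record(s): ",
           paste(records$id[hit][mismatch], collapse = ", "), call. = FALSE)
    }
    for (s in seq_along(struct)) {
      check_balanced(struct[[s]], records$id[hit][[s]])
    }
    records$structure[hit] <- struct
    records$mfe[hit] <- st$mfe[idx[hit]]
  }
  if (any(!hit)) {
    message(sum(!hit), " record(s) without a matching structure: ",
            paste(utils::head(records$id[!hit], 5L), collapse = ", "),
            if (sum(!hit) > 5L) ", ..." else "")
  }
  records
}

# error (naming the record) unless the dot-bracket string is balanced
check_balanced <- function(structure, id = "<structure>") {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c(".", "(", ")"))) {
    stop("invalid structure symbol in record ", id, call. = FALSE)
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    pos <- if (any(depth < 0)) which(depth < 0)[1] else length(chars)
    stop("unbalanced dot-bracket structure in record ", id, " at position ", pos,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a prediction table
#'
#' Writes a tab-separated prediction file with columns `id`, `length`,
#' `predicted_label`, `lncRNA_probability`, one row per record in input
#' order. Probabilities at or above the 0.5 threshold are labelled
#' `lncRNA` (ties go to the positive class).
#'
#' @param records A transcript tibble.
#' @param probabilities Numeric vector of lncRNA probabilities, one per record.
#' @param path Output file path.
#' @param threshold Decision threshold on the lncRNA probability.
#' @return Invisibly, the written tibble.
#' @export
write_predictions <- function(records, probabilities, path, threshold = 0.5) {
  if (nrow(records) != length(probabilities)) {
    stop("need exactly one probability per record (", nrow(records), " records, ",
         length(probabilities), " probabilities)", call. = FALSE)
  }
  out <- tibble(
    id = records$id,
    length = nchar(records$sequence),
    predicted_label = ifelse(probabilities >= threshold, "lncRNA", "mRNA"),
    lncRNA_probability = probabilities
  )
  readr::write_tsv(out, path)
  invisible(out)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with the four prediction columns.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    length = readr::col_integer(),
    predicted_label = readr::col_character(),
    lncRNA_probability = readr::col_double()
  ))
}
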