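STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODON <- "ATG"

new_orf <- function(type, frame, start, end, sequence) {
  list(type = type, frame = frame, start = start, end = end,
       length = end - start, sequence = sequence)
}

#' Locate the four ORF types of a transcript
#'
#' Scans the three forward reading frames and segments each frame's codons
#' at in-frame stop codons (`TAA`, `TAG`, `TGA`). Four open-reading-frame
#' types are extracted:
#'
#' * **T0** — the conventional ORF: first `ATG` within a stop-terminated
#'   segment through that stop (stop codon included).
#' * **T1** — start codon only: first `ATG` of the trailing (stop-free)
#'   segment through the frame's last complete codon.
#' * **T2** — stop codon only: a stop-terminated segment from its first
#'   (non-stop) codon through its stop.
#' * **T3** — the longer of the best T1 and best T2.
#'
#' For each type the longest candidate over all three frames is kept, ties
#' broken by lower frame then smaller start; a T1/T2 length tie for T3 is
#' resolved in favour of T1. These extra ORF types exist because the longest
#' conventional ORF of an mRNA does not always coincide with its annotated
#' CDS; T1--T3 capture coding signal that T0 misses.
#'
#' @param sequence A single DNA string over `{A,C,G,T}` (any length).
#' @return An object of class `orf_set`: list with elements `t0`, `t1`,
#'   `t2`, `t3` (each an ORF record with `frame`, 0-based half-open
#'   `start`/`end`, `length`, `sequence`, or `NULL` when absent) and
#'   `all_t0`, the list of every T0 candidate across frames.
#' @examples
#' find_typed_orfs("ATGAAATAG")$t0$length  # 9
#' @export
find_typed_orfs <- function(sequence) {
  L <- nchar(sequence)
  best <- list(t0 = NULL, t1 = NULL, t2 = NULL)
  all_t0 <- list()
  if (L >= 3L) {
    for (f in 0:2) {
      n_codons <- (L - f) %/% 3L
      if (n_codons < 1L) next
      starts <- f + 3L * (seq_len(n_codons) - 1L) + 1L
      codons <- substring(sequence, starts, starts + 2L)
      stop_idx <- which(codons %in% STOP_CODONS)
      atg_idx <- which(codons == START_CODON)

      # stop-terminated segments: (prev stop, this stop]
      seg_begin <- c(1L, head(stop_idx, -1L) + 1L)
      for (s in seq_along(stop_idx)) {
        b <- seg_begin[s]; e <- stop_idx[s]
        # T2 needs a non-stop first codon, i.e. at least one codon before the stop
        if (e > b) {
          orf <- new_orf("T2", f, starts[b] - 1L, starts[e] + 2L,
                         substr(sequence, starts[b], starts[e] + 2L))
          best$t2 <- better_orf(best$t2, orf)
        }
        # T0: first ATG inside the segment (before or at the stop's predecessor)
        a <- atg_idx[atg_idx >= b & atg_idx < e]
        if (length(a) > 0L) {
          orf <- new_orf("T0", f, starts[a[1]] - 1L, starts[e] + 2L,
                         substr(sequence, starts[a[1]], starts[e] + 2L))
          all_t0 <- c(all_t0, list(orf))
          best$t0 <- better_orf(best$t0, orf)
        }
      }

      # trailing segment without a terminating stop -> T1
      tb <- if (length(stop_idx)) stop_idx[length(stop_idx)] + 1L else 1L
      if (tb <= n_codons) {
        a <- atg_idx[atg_idx >= tb]
        if (length(a) > 0L) {
          orf <- new_orf("T1", f, starts[a[1]] - 1L, starts[n_codons] + 2L,
                         substr(sequence, starts[a[1]], starts[n_codons] + 2L))
          best$t1 <- better_orf(best$t1, orf)
        }
      }
    }
  }
  t3 <- NULL
  if (!is.null(best$t1) || !is.null(best$t2)) {
    l1 <- if (is.null(best$t1)) -1L else best$t1$length
    l2 <- if (is.null(best$t2)) -1L else best$t2$length
    t3 <- if (l1 >= l2) best$t1 else best$t2
    t3$type <- "T3"
  }
  structure(list(t0 = best$t0, t1 = best$t1, t2 = best$t2, t3 = t3,
                 all_t0 = all_t0),
            class = "orf_set")
}

# longest wins; ties by lower frame then smaller start
better_orf <- function(current, candidate) {
  if (is.null(current)) return(candidate)
  if (candidate$length > current$length) return(candidate)
  if (candidate$length == current$length &&
      (candidate$frame < current$frame ||
       (candidate$frame == current$frame && candidate$start < current$start))) {
    return(candidate)
  }
  current
}

#' @export
print.orf_set <- function(x, ...) {
  for (t in c("t0", "t1", "t2", "t3")) {
    o <- x[[t]]
    if (is.null(o)) {
      cat(toupper(t), ": absent\n", sep = "")
    } else {
      cat(sprintf("%s: frame %d, [%d, %d), %d nt\n",
                  toupper(t), o$frame, o$start, o$end, o$length))
    }
  }
  cat(length(x$all_t0), "T0 candidate(s) in total\n")
  invisible(x)
}

#' ORF length and coverage features
#'
#' Derives the ten ORF-geometry features of a transcript: the max ORF length
#' of each type, its coverage (length divided by transcript length), and the
#' mean length and mean coverage over *all* T0 candidates across frames. An
#' absent ORF contributes 0 so feature vectors stay total.
#'
#' @param orfs An `orf_set` from [find_typed_orfs()].
#' @param transcript_length Transcript length in nucleotides (>= 1).
#' @return A named numeric vector of 10 features.
#' @export
orf_length_coverage_features <- function(orfs, transcript_length) {
  stopifnot(transcript_length >= 1)
  len <- function(o) if (is.null(o)) 0 else o$length
  lens <- c(len(orfs$t0), len(orfs$t1), len(orfs$t2), len(orfs$t3))
  avg_len <- if (length(orfs$all_t0)) {
    mean(vapply(orfs$all_t0, `[[`, numeric(1), "length"))
  } else 0
  c(
    orf_t0_length = lens[1], orf_t1_length = lens[2],
    orf_t2_length = lens[3], orf_t3_length = lens[4],
    orf_t0_coverage = lens[1] / transcript_length,
    orf_t1_coverage = lens[2] / transcript_length,
    orf_t2_coverage = lens[3] / transcript_length,
    orf_t3_coverage = lens[4] / transcript_length,
    orf_avg_length = avg_len,
    orf_avg_coverage = avg_len / transcript_length
  )
}
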