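#' GC content of a sequence
#'
#' Fraction of `G` and `C` bases: `(N(G) + N(C)) / L_t`. Coding sequence
#' tends to be GC-richer than non-coding sequence, which makes this simple
#' quantity surprisingly informative for the classifier.
#'
#' @param sequence A non-empty DNA string.
#' @return A fraction in `[0, 1]`.
#' @examples
#' gc_content("ACGT")  # 0.5
#' @export
gc_content <- function(sequence) {
  L <- nchar(sequence)
  if (L < 1L) stop("cannot compute GC content of an empty sequence", call. = FALSE)
  counts <- base_counts(sequence)
  (counts[["G"]] + counts[["C"]]) / L
}

base_counts <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), numeric(1))
}

#' Fickett TESTCODE score
#'
#' Computes the classical coding/non-coding discriminant of Fickett (1982):
#' for each base, a *position* value (max over the three codon-phase counts
#' divided by the min plus one) and a *content* value (overall base
#' frequency) are mapped through the published lookup tables to
#' probabilities, and the eight probabilities are combined as a weighted sum
#' `sum(p_i * w_i)`. Position phases are taken over the whole transcript
#' starting at its first base.
#'
#' @param sequence A DNA string of length >= 3.
#' @return The Fickett score (dimensionless).
#' @export
fickett_score <- function(sequence) {
  L <- nchar(sequence)
  stopifnot(L >= 3L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  phase <- (seq_len(L) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    ph <- vapply(0:2, function(p) sum(chars == b & phase == p), numeric(1))
    pos_val <- max(ph) / (min(ph) + 1)
    cont_val <- sum(chars == b) / L
    pos_bin <- which(pos_val >= FICKETT_POSITION_PARA)[1]
    cont_bin <- which(cont_val >= FICKETT_CONTENT_PARA)[1]
    score <- score +
      FICKETT_POSITION_PROB[b, pos_bin] * FICKETT_POSITION_WEIGHT[[b]] +
      FICKETT_CONTENT_PROB[b, cont_bin] * FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}

#' Relative codon bias of an ORF
#'
#' Measures how far an ORF's codon usage departs from independence of its
#' three codon positions. For codon `(x, y, z)` the deviation is
#' `d_xyz = (f(x,y,z) - f1(x) f2(y) f3(z)) / (f1(x) f2(y) f3(z))` with
#' `f` the codon frequency and `f1..f3` the positional base frequencies,
#' all within the same ORF. The score is the geometric mean of `(1 + d)`
#' over the ORF's codon instances, minus one:
#' `RCB = (prod_i (1 + d_i))^(1/L_codon) - 1`. A uniform or
#' position-independent ORF scores 0; strong codon preference scores
#' higher. Depends only on codon counts, not their order.
#'
#' @param orf_sequence ORF sequence, length divisible by 3 (or `NULL`/empty
#'   for an absent ORF, which scores 0).
#' @return The RCB value.
#' @export
relative_codon_bias <- function(orf_sequence) {
  if (is.null(orf_sequence) || !nzchar(orf_sequence)) return(0)
  L <- nchar(orf_sequence)
  stopifnot(L >= 3L, L %% 3L == 0L)
  n <- L %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(orf_sequence, starts, starts + 2L)
  pos_freq <- lapply(1:3, function(p) {
    tab <- table(factor(substr(codons, p, p), levels = c("A", "C", "G", "T")))
    as.numeric(tab) / n
  })
  codon_tab <- table(codons)
  f_codon <- as.numeric(codon_tab[codons]) / n
  base_idx <- function(p) match(substr(codons, p, p), c("A", "C", "G", "T"))
  f_indep <- pos_freq[[1]][base_idx(1)] * pos_freq[[2]][base_idx(2)] *
    pos_freq[[3]][base_idx(3)]
  # every observed codon has nonzero positional frequencies, so the ratio
  # f/f_indep = 1 + d is strictly positive and logs are safe
  exp(mean(log(f_codon / f_indep))) - 1
}

#' Build a class-conditional hexamer probability table
#'
#' Counts 6-mers in coding and non-coding training sequences and normalises
#' each class to probabilities. Coding sequences must be CDS (phase 0) and
#' are scanned with a codon-sized step of 3 so every window spans two
#' in-frame codons; non-coding (lncRNA) sequences are scanned with step 1
#' since they have no reading frame. The dense key space is all
#' `4^6 = 4096` hexamers; unobserved hexamers have probability 0.
#'
#' @param coding_seqs Character vector of CDS sequences.
#' @param noncoding_seqs Character vector of lncRNA sequences.
#' @return A tibble with columns `hexamer`, `p_coding`, `p_noncoding`
#'   (4096 rows), carrying counts and sequence totals as attributes.
#' @export
build_hexamer_table <- function(coding_seqs, noncoding_seqs) {
  stopifnot(length(coding_seqs) > 0L, length(noncoding_seqs) > 0L)
  keys <- all_kmers(6L)
  cod <- count_kmers(coding_seqs, keys, k = 6L, step = 3L)
  non <- count_kmers(noncoding_seqs, keys, k = 6L, step = 1L)
  if (sum(cod) == 0) stop("no hexamers observed in the coding set", call. = FALSE)
  if (sum(non) == 0) stop("no hexamers observed in the non-coding set", call. = FALSE)
  out <- tibble(
    hexamer = keys,
    p_coding = cod / sum(cod),
    p_noncoding = non / sum(non)
  )
  attr(out, "n_coding_windows") <- sum(cod)
  attr(out, "n_noncoding_windows") <- sum(non)
  out
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  out <- bases
  for (i in seq_len(k - 1L)) out <- as.vector(outer(out, bases, paste0))
  sort(out)
}

count_kmers <- function(seqs, keys, k, step) {
  counts <- numeric(length(keys))
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    starts <- seq(1L, L - k + 1L, by = step)
    idx <- match(substring(s, starts, starts + k - 1L), keys)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tab <- tabulate(idx, nbins = length(keys))
      counts <- counts + tab
    }
  }
  counts
}

# mean log-likelihood ratio over tokens, with the bounded zero-count
# convention: both probabilities zero -> 0; numerator zero -> -1;
# denominator zero -> +1.
log_ratio_mean <- function(p_num, p_den) {
  contrib <- ifelse(
    p_num == 0 & p_den == 0, 0,
    ifelse(p_num == 0, -1,
           ifelse(p_den == 0, 1, log(p_num / p_den)))
  )
  mean(contrib)
}

#' Hexamer score of a transcript
#'
#' Mean log-likelihood ratio `log(P(X)_coding / P(X)_noncoding)` over the
#' transcript's hexamers, computed in each of the three reading frames
#' (windows advance by one codon, step 3) and maximised over frames. A
#' hexamer unobserved in one class contributes a bounded pseudo-log-ratio
#' (+1/-1); unobserved in both contributes 0. Transcripts shorter than 6 nt
#' score 0.
#'
#' @param sequence A DNA string.
#' @param table A hexamer table from [build_hexamer_table()].
#' @return The frame-maximised hexamer score.
#' @export
hexamer_score_transcript <- function(sequence, table) {
  L <- nchar(sequence)
  if (L < 6L) return(0)
  best <- -Inf
  for (f in 0:2) {
    if (L - f < 6L) next
    starts <- seq(f + 1L, L - 5L, by = 3L)
    sc <- hexamer_frame_score(sequence, starts, table)
    if (!is.na(sc) && sc > best) best <- sc
  }
  if (is.infinite(best)) 0 else best
}

hexamer_frame_score <- function(sequence, starts, table) {
  idx <- match(substring(sequence, starts, starts + 5L), table$hexamer)
  if (anyNA(idx)) {
    # tokens containing non-ACGT symbols are outside the table; drop them
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0L) return(NA_real_)
  log_ratio_mean(table$p_coding[idx], table$p_noncoding[idx])
}

#' Hexamer scores of the four max ORFs
#'
#' Applies the hexamer log-likelihood score to each max ORF's own sequence
#' in its single reading frame (windows at step 3 from the ORF start, no
#' frame maximisation). Absent ORFs, and ORFs shorter than 6 nt, score 0.
#'
#' @param orfs An `orf_set` from [find_typed_orfs()].
#' @param table A hexamer table from [build_hexamer_table()].
#' @return Named numeric vector `hexamer_orf_t0` .. `hexamer_orf_t3`.
#' @export
hexamer_score_orf <- function(orfs, table) {
  one <- function(o) {
    if (is.null(o) || o$length < 6L) return(0)
    starts <- seq(1L, o$length - 5L, by = 3L)
    sc <- hexamer_frame_score(o$sequence, starts, table)
    if (is.na(sc)) 0 else sc
  }
  c(
    hexamer_orf_t0 = one(orfs$t0), hexamer_orf_t1 = one(orfs$t1),
    hexamer_orf_t2 = one(orfs$t2), hexamer_orf_t3 = one(orfs$t3)
  )
}
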