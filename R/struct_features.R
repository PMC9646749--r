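#' Parse a dot-bracket string into a pair table
#'
#' Stack-matches nested parentheses. Pseudoknots are not representable in
#' plain dot-bracket and therefore cannot occur.
#'
#' @param structure A balanced string over `{., (, )}`.
#' @return An integer vector `pair` of the same length where `pair[i]` is
#'   the 1-based index of the partner of position `i`, or `NA` when
#'   unpaired. The table is an involution: `pair[pair[i]] == i`.
#' @examples
#' parse_dotbracket("(.)")  # 3 NA 1
#' @export
parse_dotbracket <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pair <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[[i]]
    if (ch == "(") {
      stack <- c(stack, i)
    } else if (ch == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced dot-bracket: unmatched ')' at position ", i, call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j
      pair[j] <- i
    } else if (ch != ".") {
      stop("invalid structure symbol '", ch, "' at position ", i, call. = FALSE)
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced dot-bracket: unmatched '(' at position ", stack[1], call. = FALSE)
  }
  pair
}

#' Fraction of paired nucleotides
#'
#' `N(paired bases) / L_t`; equivalently `2 * (number of pairs) / L_t`.
#'
#' @param pair A pair table from [parse_dotbracket()].
#' @return A fraction in `[0, 1]`.
#' @export
paired_ratio <- function(pair) {
  stopifnot(length(pair) >= 1L)
  sum(!is.na(pair)) / length(pair)
}

#' GC content of paired nucleotides
#'
#' `(N(paired G) + N(paired C)) / N(paired bases)`. G-C pairs are stronger
#' than A-T pairs, so a high value suggests a more durable structure. A
#' structure with no pairs returns 0.
#'
#' @param sequence The transcript sequence.
#' @param pair Its pair table.
#' @return A fraction in `[0, 1]`.
#' @export
gc_content_paired <- function(sequence, pair) {
  paired <- which(!is.na(pair))
  if (length(paired) == 0L) return(0)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(chars[paired] %in% c("G", "C")) / length(paired)
}

#' Decompose a secondary structure into loops
#'
#' Classifies the loop closed by every base pair `(i, j)` by the helices it
#' directly encloses: none makes a hairpin; exactly one with unpaired bases
#' on both sides an interior loop, on exactly one side a bulge, on neither a
#' stack (stacks are not counted as loops); two or more enclosed helices
#' make a multibranch loop. The exterior (unenclosed) region is not a loop.
#'
#' @param pair A pair table from [parse_dotbracket()].
#' @return A list with counts `n_hairpin`, `n_interior`, `n_bulge`,
#'   `n_multi` and a tibble `loops` recording each closing pair and its
#'   classification (stacks included for audit, flagged `counted = FALSE`).
#' @examples
#' decompose_loops(parse_dotbracket("((((....))))"))$n_hairpin  # 1
#' @export
decompose_loops <- function(pair) {
  open_idx <- which(!is.na(pair) & pair > seq_along(pair))
  loop_type <- character(length(open_idx))
  counts <- c(hairpin = 0L, interior = 0L, bulge = 0L, multi = 0L)
  for (li in seq_along(open_idx)) {
    i <- open_idx[[li]]
    j <- pair[[i]]
    children <- list()
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (is.na(pair[[k]])) {
        unpaired <- unpaired + 1L
        k <- k + 1L
      } else {
        children <- c(children, list(c(k, pair[[k]])))
        k <- pair[[k]] + 1L
      }
    }
    type <-
      if (length(children) == 0L) {
        "hairpin"
      } else if (length(children) >= 2L) {
        "multi"
      } else {
        child <- children[[1]]
        left <- child[1] - i - 1L
        right <- j - child[2] - 1L
        if (left > 0L && right > 0L) "interior"
        else if (left + right > 0L) "bulge"
        else "stack"
      }
    if (type != "stack") counts[[type]] <- counts[[type]] + 1L
    loop_type[[li]] <- type
  }
  list(
    n_hairpin = counts[["hairpin"]], n_interior = counts[["interior"]],
    n_bulge = counts[["bulge"]], n_multi = counts[["multi"]],
    loops = tibble(i = open_idx, j = pair[open_idx], type = loop_type,
                   counted = loop_type != "stack")
  )
}

#' Dense SASS k-mer key-space size
#'
#' A SASS token joins `k` sequence characters (4 possibilities each) with
#' the `k` aligned dot-bracket characters (3 possibilities each), so the
#' dense key space has `4^k * 3^k` tokens: 12, 144, 1728, 20736, 248832
#' for `k = 1..5`.
#'
#' @param k Token width, 1 to 5.
#' @return The dense key-space size.
#' @export
sass_dense_size <- function(k) {
  stopifnot(k >= 1L, k <= 5L)
  as.integer(4^k * 3^k)
}

#' Tokenise a sequence/structure pair into SASS k-mers
#'
#' Slides a window of width `k` and height 2 over the two-row array formed
#' by the primary sequence (top) and the dot-bracket structure (bottom),
#' with step 1. Each token is the `k` sequence characters concatenated with
#' the `k` aligned structure characters, e.g. window `GG` over `.(` gives
#' token `"GG.("`.
#'
#' @param sequence DNA string.
#' @param structure Dot-bracket string of the same length.
#' @param k Token width.
#' @return Character vector of `L_t - k + 1` tokens.
#' @examples
#' sass_tokenize("GGG", "..(", 1)  # "G." "G." "G("
#' @export
sass_tokenize <- function(sequence, structure, k) {
  L <- nchar(sequence)
  if (nchar(structure) != L) {
    stop("sequence and structure lengths differ (", L, " vs ",
         nchar(structure), ")", call. = FALSE)
  }
  stopifnot(k >= 1L, L >= k)
  starts <- seq_len(L - k + 1L)
  paste0(substring(sequence, starts, starts + k - 1L),
         substring(structure, starts, starts + k - 1L))
}

#' Build class-conditional SASS k-mer tables
#'
#' Counts SASS tokens over full transcripts for the mRNA and lncRNA classes
#' and normalises each class to probabilities, for every `k` in 1..5.
#' Tables are stored sparsely (observed tokens only); the dense key-space
#' size is available from [sass_dense_size()].
#'
#' @param mrna,lncrna Transcript tibbles whose rows all carry structures.
#' @param k_values Token widths to build (default 1:5).
#' @return A named list `k1`..`k5` of tibbles with columns `token`,
#'   `p_mrna`, `p_lncrna`.
#' @export
build_sass_tables <- function(mrna, lncrna, k_values = 1:5) {
  check_has_structure <- function(df, what) {
    if (nrow(df) == 0L) stop("empty ", what, " class for SASS tables", call. = FALSE)
    if (anyNA(df$structure)) {
      stop(what, " record(s) without structure: ",
           paste(head(df$id[is.na(df$structure)], 5L), collapse = ", "), call. = FALSE)
    }
  }
  check_has_structure(mrna, "mRNA")
  check_has_structure(lncrna, "lncRNA")
  out <- lapply(k_values, function(k) {
    cm <- sass_count(mrna, k)
    cl <- sass_count(lncrna, k)
    tokens <- union(names(cm), names(cl))
    tibble(
      token = tokens,
      p_mrna = unname(cm[tokens] / sum(cm)) %|0|% 0,
      p_lncrna = unname(cl[tokens] / sum(cl)) %|0|% 0
    )
  })
  names(out) <- paste0("k", k_values)
  out
}

# replace NAs produced by name-based lookup misses with zero
`%|0|%` <- function(x, zero) {
  x[is.na(x)] <- zero
  x
}

sass_count <- function(records, k) {
  tok <- unlist(lapply(seq_len(nrow(records)), function(i) {
    if (nchar(records$sequence[[i]]) < k) return(character(0))
    sass_tokenize(records$sequence[[i]], records$structure[[i]], k)
  }))
  table_to_named(tok)
}

table_to_named <- function(x) {
  tab <- table(x)
  setNames(as.numeric(tab), names(tab))
}

#' SASS k-mer score of a transcript
#'
#' Mean log-likelihood ratio `log(P(X)_mRNA / P(X)_lncRNA)` over the
#' transcript's SASS tokens, with the same bounded zero-count convention as
#' the hexamer score. A transcript without a structure scores 0 with a
#' warning (this supports the structure-free mode of the classifier).
#'
#' @param sequence DNA string.
#' @param structure Dot-bracket string (or `NA` for none).
#' @param k Token width.
#' @param table The matching SASS table from [build_sass_tables()].
#' @return The SASS k-mer score.
#' @export
sass_score <- function(sequence, structure, k, table) {
  if (is.na(structure) || is.null(structure)) {
    warning("transcript without structure: SASS ", k, "-mer score set to 0")
    return(0)
  }
  if (nchar(sequence) < k) return(0)
  tok <- sass_tokenize(sequence, structure, k)
  idx <- match(tok, table$token)
  p_m <- ifelse(is.na(idx), 0, table$p_mrna[idx])
  p_l <- ifelse(is.na(idx), 0, table$p_lncrna[idx])
  log_ratio_mean(p_m, p_l)
}

#' Fold a sequence by base-pair maximisation (fixtures only)
#'
#' A deterministic Nussinov-style dynamic program that maximises the number
#' of canonical pairs (`AT`, `GC` and the `GT` wobble) subject to a minimum
#' hairpin gap of `min_hairpin` unpaired bases. Traceback prefers pairing
#' and takes the leftmost partner, so the output is reproducible. The
#' returned `mfe` is a *pseudo*-energy, minus the pair count — this folder
#' exists so the pipeline and its tests run self-contained, and its output
#' is explicitly **not** equivalent to a thermodynamic folder such as
#' RNAfold; model bundles record which structure source was used.
#'
#' @param sequence DNA string of length <= 2000 (the cubic DP is the guard;
#'   use RNAfold for longer transcripts).
#' @param min_hairpin Minimum number of unpaired bases in a hairpin loop.
#' @return A list with `structure` (dot-bracket) and `mfe` (pseudo-energy,
#'   `-pairs`).
#' @examples
#' fallback_fold("GGGAAACCC")$structure  # "(((...)))"
#' @export
fallback_fold <- function(sequence, min_hairpin = 3L) {
  L <- nchar(sequence)
  if (L > 2000L) {
    stop("sequence of ", L, " nt is too long for the fixture folder; ",
         "predict its structure with RNAfold and attach_structures() instead",
         call. = FALSE)
  }
  res <- .nussinov_fold(sequence, as.integer(min_hairpin))
  list(structure = res$structure, mfe = -as.numeric(res$pairs))
}

#' Fold every structure-free transcript in a tibble
#'
#' Applies [fallback_fold()] to each record lacking a structure and fills
#' the `structure` and `mfe` columns. Records that already carry a
#' structure are left untouched.
#'
#' @param records A transcript tibble.
#' @param min_hairpin Passed to [fallback_fold()].
#' @return The tibble with structures attached.
#' @export
fold_transcripts <- function(records, min_hairpin = 3L) {
  todo <- which(is.na(records$structure))
  for (i in todo) {
    f <- fallback_fold(records$sequence[[i]], min_hairpin)
    records$structure[[i]] <- f$structure
    records$mfe[[i]] <- f$mfe
  }
  records
}
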