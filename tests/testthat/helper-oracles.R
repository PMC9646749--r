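# Independent reference implementations used as oracles. These deliberately
# take different routes than the package code (explicit loops, brute-force
# enumeration) so agreement is informative.

STOPS <- c("TAA", "TAG", "TGA")

frame_codons <- function(sequence, f) {
  L <- nchar(sequence)
  n <- (L - f) %/% 3
  if (n < 1) return(character(0))
  vapply(seq_len(n), function(ci) substr(sequence, f + 3 * (ci - 1) + 1,
                                         f + 3 * (ci - 1) + 3), character(1))
}

# brute-force typed-ORF finder: enumerates candidate (start, end) codon pairs
# per type and keeps the longest (lower frame, then smaller start on ties)
oracle_orfs <- function(sequence) {
  best <- list(t0 = NULL, t1 = NULL, t2 = NULL)
  all_t0 <- list()
  keep <- function(cur, cand) {
    if (is.null(cand)) return(cur)
    if (is.null(cur) || cand$length > cur$length) return(cand)
    if (cand$length == cur$length &&
        (cand$frame < cur$frame ||
         (cand$frame == cur$frame && cand$start < cur$start))) return(cand)
    cur
  }
  for (f in 0:2) {
    codons <- frame_codons(sequence, f)
    n <- length(codons)
    if (n == 0) next
    is_stop <- codons %in% STOPS
    # T2: for every stop, candidate from the codon after the previous stop
    prev_stop <- 0
    for (e in seq_len(n)) {
      if (!is_stop[e]) next
      b <- prev_stop + 1
      if (e > b) {
        cand <- list(frame = f, start = f + 3 * (b - 1),
                     end = f + 3 * e, length = 3 * (e - b + 1))
        cand$sequence <- substr(sequence, cand$start + 1, cand$end)
        best$t2 <- keep(best$t2, cand)
      }
      # T0: smallest ATG index in (prev_stop, e)
      a_candidates <- which(codons == "ATG")
      a_candidates <- a_candidates[a_candidates > prev_stop & a_candidates < e]
      if (length(a_candidates)) {
        a <- min(a_candidates)
        cand <- list(frame = f, start = f + 3 * (a - 1),
                     end = f + 3 * e, length = 3 * (e - a + 1))
        cand$sequence <- substr(sequence, cand$start + 1, cand$end)
        all_t0 <- c(all_t0, list(cand))
        best$t0 <- keep(best$t0, cand)
      }
      prev_stop <- e
    }
    # T1: earliest ATG with no stop anywhere after it in this frame
    atg <- which(codons == "ATG")
    atg <- atg[vapply(atg, function(a) !any(is_stop[a:n]), logical(1))]
    if (length(atg)) {
      a <- min(atg)
      cand <- list(frame = f, start = f + 3 * (a - 1),
                   end = f + 3 * n, length = 3 * (n - a + 1))
      cand$sequence <- substr(sequence, cand$start + 1, cand$end)
      best$t1 <- keep(best$t1, cand)
    }
  }
  l1 <- if (is.null(best$t1)) -1 else best$t1$length
  l2 <- if (is.null(best$t2)) -1 else best$t2$length
  t3 <- if (l1 < 0 && l2 < 0) NULL else if (l1 >= l2) best$t1 else best$t2
  list(t0 = best$t0, t1 = best$t1, t2 = best$t2, t3 = t3, all_t0 = all_t0)
}

# loop classification via brute-force parent assignment: each pair's parent
# is the innermost enclosing pair, found by O(P^2) containment search
oracle_loops <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") {
      pairs <- c(pairs, list(c(stack[length(stack)], i)))
      stack <- stack[-length(stack)]
    }
  }
  P <- length(pairs)
  counts <- c(H = 0, I = 0, B = 0, M = 0)
  if (P == 0) return(counts)
  pi_ <- vapply(pairs, `[`, numeric(1), 1)
  pj_ <- vapply(pairs, `[`, numeric(1), 2)
  parent <- vapply(seq_len(P), function(p) {
    enclosing <- which(pi_ < pi_[p] & pj_ > pj_[p])
    if (!length(enclosing)) return(NA_integer_)
    enclosing[which.max(pi_[enclosing])]  # innermost = largest opening index
  }, integer(1))
  paired_pos <- c(pi_, pj_)
  for (p in seq_len(P)) {
    children <- which(!is.na(parent) & parent == p)
    if (length(children) == 0) {
      counts[["H"]] <- counts[["H"]] + 1
    } else if (length(children) >= 2) {
      counts[["M"]] <- counts[["M"]] + 1
    } else {
      ch <- children[[1]]
      left_range <- if (pi_[ch] - pi_[p] > 1) seq(pi_[p] + 1, pi_[ch] - 1) else integer(0)
      right_range <- if (pj_[p] - pj_[ch] > 1) seq(pj_[ch] + 1, pj_[p] - 1) else integer(0)
      left <- sum(!left_range %in% paired_pos)
      right <- sum(!right_range %in% paired_pos)
      if (left > 0 && right > 0) counts[["I"]] <- counts[["I"]] + 1
      else if (left + right > 0) counts[["B"]] <- counts[["B"]] + 1
      # else: stacked pair, not a loop
    }
  }
  counts
}

# direct-formula mean log-ratio with the bounded zero conventions
oracle_log_ratio <- function(p_num, p_den) {
  total <- 0
  for (i in seq_along(p_num)) {
    total <- total + if (p_num[i] == 0 && p_den[i] == 0) 0
    else if (p_num[i] == 0) -1
    else if (p_den[i] == 0) 1
    else log(p_num[i] / p_den[i])
  }
  total / length(p_num)
}

oracle_hexamer_transcript <- function(sequence, table) {
  L <- nchar(sequence)
  if (L < 6) return(0)
  lut_c <- setNames(table$p_coding, table$hexamer)
  lut_n <- setNames(table$p_noncoding, table$hexamer)
  frame_scores <- c()
  for (f in 0:2) {
    starts <- seq(f + 1, L - 5, by = 3)
    if (length(starts) == 0 || f + 6 > L) next
    toks <- substring(sequence, starts, starts + 5)
    ok <- toks %in% names(lut_c)
    if (!any(ok)) next
    frame_scores <- c(frame_scores, oracle_log_ratio(lut_c[toks[ok]], lut_n[toks[ok]]))
  }
  if (!length(frame_scores)) 0 else max(frame_scores)
}

oracle_sass <- function(sequence, structure, k, table) {
  L <- nchar(sequence)
  if (L < k) return(0)
  toks <- vapply(seq_len(L - k + 1), function(i) {
    paste0(substr(sequence, i, i + k - 1), substr(structure, i, i + k - 1))
  }, character(1))
  idx <- match(toks, table$token)
  p_m <- ifelse(is.na(idx), 0, table$p_mrna[idx])
  p_l <- ifelse(is.na(idx), 0, table$p_lncrna[idx])
  oracle_log_ratio(p_m, p_l)
}

# direct evaluation of the RCB formula: all 64 d values, then the product
oracle_rcb <- function(orf) {
  n <- nchar(orf) / 3
  codons <- frame_codons(orf, 0)
  bases <- c("A", "C", "G", "T")
  f_pos <- lapply(1:3, function(p) {
    sapply(bases, function(b) sum(substr(codons, p, p) == b) / n)
  })
  d <- array(0, dim = c(4, 4, 4), dimnames = list(bases, bases, bases))
  for (x in bases) for (y in bases) for (z in bases) {
    f_xyz <- sum(codons == paste0(x, y, z)) / n
    denom <- f_pos[[1]][x] * f_pos[[2]][y] * f_pos[[3]][z]
    d[x, y, z] <- if (denom == 0) 0 else (f_xyz - denom) / denom
  }
  prod_term <- 1
  for (cdn in codons) {
    ch <- strsplit(cdn, "")[[1]]
    prod_term <- prod_term * (1 + d[ch[1], ch[2], ch[3]])
  }
  prod_term^(1 / n) - 1
}

# independent loop-based Fickett reimplementation against the same tables
oracle_fickett <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- c(0, 0, 0)
    for (i in seq_len(L)) if (chars[i] == b) {
      cnt[(i - 1) %% 3 + 1] <- cnt[(i - 1) %% 3 + 1] + 1
    }
    pos_val <- max(cnt) / (min(cnt) + 1)
    pos_bin <- 10
    for (bin in 1:10) {
      if (pos_val >= lncsieve:::FICKETT_POSITION_PARA[bin]) { pos_bin <- bin; break }
    }
    cont_val <- sum(chars == b) / L
    cont_bin <- 10
    for (bin in 1:10) {
      if (cont_val >= lncsieve:::FICKETT_CONTENT_PARA[bin]) { cont_bin <- bin; break }
    }
    total <- total +
      lncsieve:::FICKETT_POSITION_PROB[b, pos_bin] * lncsieve:::FICKETT_POSITION_WEIGHT[[b]] +
      lncsieve:::FICKETT_CONTENT_PROB[b, cont_bin] * lncsieve:::FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(total)
}

# rank-statistic AUC (Mann-Whitney)
oracle_auc <- function(truth, scores) {
  pos <- truth == "lncRNA"
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

# exhaustive maximum nested pairing for tiny sequences: enumerate every
# nested pairing recursively and return the best pair count
oracle_max_pairs <- function(sequence, min_hairpin = 3) {
  chars <- strsplit(sequence, "")[[1]]
  can <- function(a, b) {
    paste0(chars[a], chars[b]) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  explore <- function(i, j) {
    if (j - i < min_hairpin + 1) return(0)
    best <- explore(i + 1, j)  # i unpaired
    for (k in (i + min_hairpin + 1):j) {
      if (can(i, k)) {
        best <- max(best, 1 + explore(i + 1, k - 1) + explore(k + 1, j))
      }
    }
    best
  }
  explore(1, length(chars))
}

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")
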