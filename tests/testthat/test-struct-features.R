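test_that("dot-bracket parsing builds an involution pair table", {
  expect_equal(parse_dotbracket("(())"), c(4L, 3L, 2L, 1L))
  expect_equal(parse_dotbracket("...."), rep(NA_integer_, 4))
  expect_equal(parse_dotbracket("(.)"), c(3L, NA, 1L))
  expect_error(parse_dotbracket("((."), "unbalanced.*position 1")
  expect_error(parse_dotbracket(").("), "position 1")
  p <- parse_dotbracket("((..((...))..))")
  paired <- which(!is.na(p))
  expect_equal(p[p[paired]], paired)
})

test_that("paired ratio and paired GC match direct counts", {
  expect_equal(paired_ratio(parse_dotbracket("(((...)))")), 6 / 9)
  expect_equal(paired_ratio(parse_dotbracket(".....")), 0)
  expect_equal(paired_ratio(parse_dotbracket("()")), 1)
  expect_equal(gc_content_paired("GC", parse_dotbracket("()")), 1)
  expect_equal(gc_content_paired("AT", parse_dotbracket("()")), 0)
  expect_equal(gc_content_paired("GC", parse_dotbracket("..")), 0)
  set.seed(408)
  for (i in 1:30) {
    s <- random_dna(80)
    st <- fallback_fold(s)$structure
    pair <- parse_dotbracket(st)
    chars <- strsplit(s, "")[[1]]
    paired <- which(!is.na(pair))
    want <- if (length(paired)) sum(chars[paired] %in% c("G", "C")) / length(paired) else 0
    expect_equal(gc_content_paired(s, pair), want)
    expect_equal(paired_ratio(pair), 2 * sum(!is.na(pair)) / 2 / length(pair))
  }
})

test_that("loop decomposition classifies the canonical structures", {
  d <- decompose_loops(parse_dotbracket("((((....))))"))
  expect_equal(c(d$n_hairpin, d$n_interior, d$n_bulge, d$n_multi), c(1, 0, 0, 0))
  d <- decompose_loops(parse_dotbracket("((..((....))))"))
  expect_equal(c(d$n_hairpin, d$n_interior, d$n_bulge, d$n_multi), c(1, 0, 1, 0))
  d <- decompose_loops(parse_dotbracket("((((...))((...))))"))
  expect_equal(d$n_hairpin, 2)
  expect_equal(d$n_multi, 1)
  d <- decompose_loops(parse_dotbracket("((.((....)).))"))
  expect_equal(d$n_interior, 1)
})

test_that("loop decomposition agrees with the recursive-parent oracle on folds", {
  set.seed(409)
  for (i in 1:120) {
    st <- fallback_fold(random_dna(sample(40:150, 1)))$structure
    d <- decompose_loops(parse_dotbracket(st))
    want <- oracle_loops(st)
    expect_equal(c(d$n_hairpin, d$n_interior, d$n_bulge, d$n_multi),
                 unname(want), label = st)
    if (grepl("\\(", st)) expect_gte(d$n_hairpin, 1)
  }
})

test_that("SASS tokenisation reproduces the worked two-row example", {
  expect_equal(sass_tokenize("GGG", "..(", 1), c("G.", "G.", "G("))
  expect_equal(sass_tokenize("GGG", "..(", 2), c("GG..", "GG.("))
  set.seed(410)
  s <- random_dna(60)
  st <- fallback_fold(s)$structure
  for (k in 1:5) expect_length(sass_tokenize(s, st, k), 60 - k + 1)
  expect_error(sass_tokenize("AC", "...", 1), "lengths differ")
})

test_that("SASS tables have the right key spaces and normalisation", {
  expect_equal(vapply(1:5, sass_dense_size, integer(1)),
               c(12L, 144L, 1728L, 20736L, 248832L))
  one_m <- new_transcripts("m", "GG"); one_m$structure <- "(("
  one_l <- new_transcripts("l", "AT"); one_l$structure <- ".."
  tabs <- build_sass_tables(one_m, one_l, k_values = 1)
  expect_equal(tabs$k1$p_mrna[tabs$k1$token == "G("], 1)
  expect_equal(sum(tabs$k1$p_mrna), 1)
  expect_equal(sum(tabs$k1$p_lncrna), 1)
  big <- shared_tables()$sass
  for (k in 1:5) {
    expect_lte(nrow(big[[k]]), sass_dense_size(k))
    expect_equal(sum(big[[k]]$p_mrna), 1, tolerance = 1e-9)
    expect_equal(sum(big[[k]]$p_lncrna), 1, tolerance = 1e-9)
  }
})

test_that("SASS scores match the direct token oracle and swap antisymmetry", {
  tabs <- shared_tables()$sass
  set.seed(411)
  for (i in 1:15) {
    s <- random_dna(90)
    st <- fallback_fold(s)$structure
    for (k in c(1, 3, 5)) {
      tab <- tabs[[paste0("k", k)]]
      got <- sass_score(s, st, k, tab)
      expect_equal(got, oracle_sass(s, st, k, tab), tolerance = 1e-12)
      swapped <- tibble::tibble(token = tab$token, p_mrna = tab$p_lncrna,
                                p_lncrna = tab$p_mrna)
      expect_equal(sass_score(s, st, k, swapped), -got, tolerance = 1e-12)
    }
  }
  flat <- tibble::tibble(token = c("A.", "C.", "G.", "T."),
                         p_mrna = rep(0.25, 4), p_lncrna = rep(0.25, 4))
  expect_equal(sass_score("ACGT", "....", 1, flat), 0)
  single <- tibble::tibble(token = "A.", p_mrna = exp(1) / 3, p_lncrna = 1 / 3)
  expect_equal(sass_score("A", ".", 1, single), 1, tolerance = 1e-12)
  expect_warning(got0 <- sass_score("ACGT", NA, 1, flat), "without structure")
  expect_equal(got0, 0)
})

test_that("the fixture folder maximises pairings deterministically", {
  f <- fallback_fold("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$mfe, -3)
  expect_equal(fallback_fold("AAAA")$structure, "....")
  set.seed(412)
  for (i in 1:25) {
    s <- random_dna(sample(10:16, 1))
    f <- fallback_fold(s)
    expect_equal(-f$mfe, oracle_max_pairs(s), label = s)
    # output is well-formed: balanced with hairpin gaps >= 3
    pair <- parse_dotbracket(f$structure)
    open <- which(!is.na(pair) & pair > seq_along(pair))
    for (o in open) {
      inner <- if (pair[o] - o > 1) seq(o + 1, pair[o] - 1) else integer(0)
      if (all(is.na(pair[inner]))) expect_gte(length(inner), 3)
    }
    expect_identical(fallback_fold(s)$structure, f$structure)
  }
  expect_error(fallback_fold(strrep("A", 2001)), "RNAfold")
})

test_that("fold_transcripts fills only missing structures", {
  rec <- new_transcripts(c("a", "b"), c("GGGAAACCC", "GGGTTTCCC"))
  rec$structure[1] <- "........."
  rec$mfe[1] <- -1.5
  out <- fold_transcripts(rec)
  expect_equal(out$structure[1], ".........")
  expect_equal(out$mfe[1], -1.5)
  expect_equal(out$structure[2], "(((...)))")
  expect_equal(out$mfe[2], -3)
})
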