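test_that("GC content matches direct counting", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AATT"), 0.0)
  expect_error(gc_content(""), "empty")
})

test_that("Fickett score matches hand lookup and an independent reimplementation", {
  # one base per codon phase: every position value is 1/2, every content 1/4
  expect_equal(fickett_score("ACGTACGTACGT"), 0.4606, tolerance = 1e-9)
  set.seed(403)
  for (i in 1:40) {
    s <- random_dna(300)
    expect_equal(fickett_score(s), oracle_fickett(s), tolerance = 1e-12)
  }
})

test_that("relative codon bias is zero under positional independence", {
  expect_equal(relative_codon_bias("ATGATGATG"), 0)
  # codon distribution equal to the product of positional distributions
  codons <- as.vector(outer(outer(c("A", "G"), c("C", "T"), paste0), c("G", "A"), paste0))
  expect_equal(relative_codon_bias(paste(codons, collapse = "")), 0, tolerance = 1e-12)
  expect_equal(relative_codon_bias(NULL), 0)
})

test_that("relative codon bias equals the direct-formula oracle and is order-invariant", {
  set.seed(404)
  for (i in 1:30) {
    orf <- random_dna(150)
    expect_equal(relative_codon_bias(orf), oracle_rcb(orf), tolerance = 1e-10)
    codons <- substring(orf, seq(1, 148, 3), seq(3, 150, 3))
    shuffled <- paste(sample(codons), collapse = "")
    expect_equal(relative_codon_bias(shuffled), relative_codon_bias(orf),
                 tolerance = 1e-10)
  }
})

test_that("hexamer table counts follow the two window rules", {
  tab <- build_hexamer_table("ATGAAATTTTAG", "ACGTACGTA")
  expect_equal(nrow(tab), 4096L)
  expect_equal(attr(tab, "n_coding_windows"), 3)    # step 3 over a 12 nt CDS
  expect_equal(attr(tab, "n_noncoding_windows"), 4) # step 1 over 9 nt
  expect_equal(sum(tab$p_coding), 1, tolerance = 1e-9)
  expect_equal(sum(tab$p_noncoding), 1, tolerance = 1e-9)
  expect_error(build_hexamer_table("ACGT", "ACGTACGTA"), "no hexamers")
})

test_that("hexamer score honours the log-ratio formula and frame maximisation", {
  keys <- lncsieve:::all_kmers(6)
  flat <- tibble::tibble(hexamer = keys, p_coding = 1 / 4096, p_noncoding = 1 / 4096)
  expect_equal(hexamer_score_transcript("ATGAAATTTTAGACGT", flat), 0)

  # one hexamer with ratio e, all others ratio 1: score = count / m per frame
  boosted <- flat
  target <- "ATGAAA"
  boosted$p_coding[boosted$hexamer == target] <- exp(1) / 4096
  s <- strrep("ATGAAA", 3)
  got <- hexamer_score_transcript(s, boosted)
  expect_equal(got, oracle_hexamer_transcript(s, boosted), tolerance = 1e-12)

  set.seed(405)
  ratio_tab <- flat
  ratio_tab$p_coding <- as.vector(stats::rmultinom(1, 5000, rep(1, 4096))) / 5000
  ratio_tab$p_noncoding <- as.vector(stats::rmultinom(1, 5000, rep(1, 4096))) / 5000
  for (i in 1:25) {
    sq <- random_dna(sample(50:300, 1))
    expect_equal(hexamer_score_transcript(sq, ratio_tab),
                 oracle_hexamer_transcript(sq, ratio_tab), tolerance = 1e-12)
  }
})

test_that("single-hexamer ratio-e table gives score count/m", {
  keys <- lncsieve:::all_kmers(6)
  tab <- tibble::tibble(hexamer = keys, p_coding = 1 / 4096, p_noncoding = 1 / 4096)
  tab$p_coding[tab$hexamer == "AAAAAA"] <- exp(1) / 4096
  # frame 0 of a poly-A 12-mer: tokens AAAAAA, AAAAAA and both hit -> score 1
  expect_equal(hexamer_score_transcript("AAAAAAAAAAAA", tab), 1, tolerance = 1e-12)
})

test_that("hexamer score is antisymmetric under class swap per frame", {
  set.seed(406)
  keys <- lncsieve:::all_kmers(6)
  tab <- tibble::tibble(
    hexamer = keys,
    p_coding = as.vector(stats::rmultinom(1, 3000, rep(1, 4096))) / 3000,
    p_noncoding = as.vector(stats::rmultinom(1, 3000, rep(1, 4096))) / 3000
  )
  swapped <- tibble::tibble(hexamer = keys, p_coding = tab$p_noncoding,
                            p_noncoding = tab$p_coding)
  for (i in 1:10) {
    orf <- find_typed_orfs(random_dna(120))
    # ORF scores are single-frame, so swapping classes flips every sign
    expect_equal(hexamer_score_orf(orf, tab),
                 -hexamer_score_orf(orf, swapped), tolerance = 1e-12)
  }
})

test_that("ORF hexamer scores use the ORF's own frame and zero-fill absences", {
  tabs <- shared_tables()
  no_orf <- find_typed_orfs("ACACAC")
  expect_equal(unname(hexamer_score_orf(no_orf, tabs$hexamer)), rep(0, 4))
  set.seed(407)
  for (i in 1:10) {
    o <- find_typed_orfs(random_dna(200))
    got <- hexamer_score_orf(o, tabs$hexamer)
    for (t in c("t0", "t1", "t2", "t3")) {
      want <- if (is.null(o[[t]]) || o[[t]]$length < 6) 0 else {
        starts <- seq(1, o[[t]]$length - 5, by = 3)
        toks <- substring(o[[t]]$sequence, starts, starts + 5)
        idx <- match(toks, tabs$hexamer$hexamer)
        oracle_log_ratio(tabs$hexamer$p_coding[idx], tabs$hexamer$p_noncoding[idx])
      }
      expect_equal(unname(got[paste0("hexamer_orf_", t)]), want, tolerance = 1e-12)
    }
  }
})
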