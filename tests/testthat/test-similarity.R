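test_that("align_res lays REs out in a fixed frame with gap-free half-sites", {
  pat <- compile_pattern()
  spacers <- c(14L, 2L, 0L, 11L, 13L, 12L, 0L, 1L, 2L, 6L)
  set.seed(55)
  res <- vapply(spacers, function(s) sample_from_pattern(pat, s),
                character(1))
  aln <- align_res(res, spacers)
  expect_equal(aln$frame_width, 34L)  # 20 + max spacer 14
  expect_equal(nrow(aln$rows), 10L)
  # half-site blocks gap-free; per-row non-gap count = 20 + spacer
  expect_false(any(aln$rows[, 1:10] == "-"))
  expect_false(any(aln$rows[, 25:34] == "-"))
  expect_equal(rowSums(aln$rows != "-"), 20L + spacers)

  # three spacer-0 REs: no gap columns at all
  aln0 <- align_res(res[spacers == 0])
  expect_equal(aln0$frame_width, 20L)
  expect_false(any(aln0$rows == "-"))

  # one RE aligns to itself
  aln1 <- align_res(res[1], spacers[1])
  expect_equal(paste(aln1$rows[1, ], collapse = ""), res[1])

  expect_error(align_res("ACGT", 2), "length")
  expect_error(align_res(strrep("A", 40), 20), "range")
})

test_that("half-site PWMs come from the outer columns only, with the CWWG core", {
  pat <- compile_pattern()
  # identical rows give single-letter columns
  aln <- align_res(rep("AAACATGTTTGGGCTTGCCC", 3))
  pair <- build_halfsite_pwms(aln, pseudocount = 0)
  expect_equal(max(pair$left$freqs["A", 1]), 1)
  expect_equal(unname(pair$right$counts["G", 1]), 3)

  # PWMs built from pattern samples keep the invariant C4 / G7 core
  set.seed(56)
  spacers <- c(14L, 2L, 0L, 11L, 13L, 12L, 0L, 1L, 2L, 6L)
  res <- vapply(spacers, function(s) sample_from_pattern(pat, s),
                character(1))
  pair <- build_halfsite_pwms(align_res(res, spacers))
  expect_equal(rownames(pair$left$freqs)[which.max(pair$left$freqs[, 4])],
               "C")
  expect_equal(rownames(pair$left$freqs)[which.max(pair$left$freqs[, 7])],
               "G")
  expect_equal(rownames(pair$right$freqs)[which.max(pair$right$freqs[, 4])],
               "C")
  # gap columns never contribute: counts per column always sum to n rows
  expect_true(all(colSums(pair$left$counts) == 10))
  expect_true(all(colSums(pair$right$counts) == 10))
})

test_that("PWMs rebuilt from sampled sites recover the generator frequencies", {
  pat <- compile_pattern()
  set.seed(60)
  gen_sites <- vapply(1:15, function(i) sample_from_pattern(pat, 0L),
                      character(1))
  gen_pair <- build_halfsite_pwms(align_res(gen_sites), pseudocount = 0.25)
  sample_n <- function(n) {
    vapply(seq_len(n), function(i) sample_from_pwms(gen_pair, 0L),
           character(1))
  }
  set.seed(61)
  rebuilt500 <- build_pwm(substr(sample_n(500), 1, 10), pseudocount = 0)
  # every column frequency within 3 sigma multinomial bounds at N = 500
  for (j in 1:10) {
    for (b in c("A", "C", "G", "T")) {
      p <- gen_pair$left$freqs[b, j]
      expect_lt(abs(rebuilt500$freqs[b, j] - p),
                3 * sqrt(p * (1 - p) / 500) + 1e-12)
    }
  }
  # contraction: error shrinks from N=50 to N=500
  set.seed(62)
  rebuilt50 <- build_pwm(substr(sample_n(50), 1, 10), pseudocount = 0)
  err <- function(m) max(abs(m$freqs - gen_pair$left$freqs))
  expect_lt(err(rebuilt500), err(rebuilt50))
})

test_that("candidate ranking orders by E-value and applies both gates", {
  pat <- compile_pattern()
  set.seed(63)
  seeds <- vapply(c(0L, 2L, 5L, 0L, 1L), function(s)
    sample_from_pattern(pat, s), character(1))
  pair <- build_halfsite_pwms(align_res(seeds))
  consensus <- paste0(
    paste(rownames(pair$left$freqs)[apply(pair$left$freqs, 2, which.max)],
          collapse = ""),
    paste(rownames(pair$right$freqs)[apply(pair$right$freqs, 2, which.max)],
          collapse = ""))
  set.seed(64)
  cand <- c(best = consensus,
            setNames(replicate(51, random_dna(22)), sprintf("bg%02d", 1:51)))
  r <- rank_candidates(cand, pair)
  expect_equal(r$table$id[1], "best")  # consensus ranks first
  expect_true(all(diff(r$table$evalue) >= 0))
  expect_true(r$table$in_consensus[1])
  expect_true(all(r$table$evalue == r$table$pvalue * 52))
  # consensus set is the intersection, ordered by MAST rank
  cons <- consensus_candidates(r)
  expect_setequal(cons, intersect(r$table$id[r$table$in_mast],
                                  r$table$id[r$table$in_scan]))
  expect_equal(cons, r$table$id[r$table$in_consensus])

  # a background-composition candidate scoring ~0 bits has p ~ 1, E ~ n > 10
  flat <- build_pwm(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG",
                      "TTTTTTTTTT"), pseudocount = 0)
  flat_pair <- pwm_pair(flat, flat, 0, 15)
  r0 <- rank_candidates(cand, flat_pair)
  expect_true(all(r0$table$pvalue == 1))  # every word scores exactly 0
  expect_false(any(r0$table$in_mast))     # E = 52 > 10 for all

  # E-values scale with pool size; p-values and order do not
  r2 <- rank_candidates(c(cand, setNames(cand, paste0(names(cand), "_dup"))),
                        pair)
  half <- r2$table[!grepl("_dup$", r2$table$id), ]
  expect_equal(half$pvalue[match(r$table$id, half$id)], r$table$pvalue)
  expect_equal(half$evalue[match(r$table$id, half$id)], 2 * r$table$evalue)
})

test_that("matrix-scan-like gate shrinks with alpha and empties at alpha 0", {
  pat <- compile_pattern()
  set.seed(65)
  seeds <- vapply(1:6, function(i) sample_from_pattern(pat, 0L),
                  character(1))
  pair <- build_halfsite_pwms(align_res(seeds))
  cand <- c(setNames(vapply(1:10, function(i) sample_from_pattern(pat, 0L),
                            character(1)), sprintf("re%02d", 1:10)),
            setNames(replicate(30, random_dna(20)), sprintf("bg%02d", 1:30)))
  sizes <- vapply(c(0.2, 0.05, 0.01, 0), function(a) {
    length(matrixscan_like(cand, pair, alpha = a))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[4], 0)
  # consensus candidates sampled from the pattern pass the default gate
  expect_true(all(sprintf("re%02d", 1:10) %in%
                    matrixscan_like(cand, pair, alpha = 0.05)))
})

test_that("similarity search recovers planted candidates from a mixed pool", {
  pat <- compile_pattern()
  set.seed(7)
  seeds <- vapply(c(14L, 2L, 0L, 11L, 13L, 12L, 0L, 1L, 2L, 6L),
                  function(s) sample_from_pattern(pat, s), character(1))
  pair <- build_halfsite_pwms(align_res(seeds))
  set.seed(8)
  planted <- vapply(sample(0:15, 20, replace = TRUE),
                    function(s) sample_from_pattern(pat, s), character(1))
  bgc <- vapply(sample(20:35, 80, replace = TRUE),
                function(n) random_dna(n), character(1))
  cand <- setNames(c(planted, bgc),
                   c(sprintf("planted%02d", 1:20), sprintf("bg%02d", 1:80)))
  cons <- consensus_candidates(rank_candidates(cand, pair))
  expect_gte(sum(grepl("^planted", cons)), 18L)
  expect_lte(sum(grepl("^bg", cons)), 5L)
})

test_that("pwm_robustness reports full overlap for identical seeds, little for
           background seeds", {
  pat <- compile_pattern()
  set.seed(70)
  seeds <- vapply(1:10, function(i) sample_from_pattern(pat, 0L),
                  character(1))
  cand <- c(setNames(vapply(1:15, function(i) sample_from_pattern(pat, 0L),
                            character(1)), sprintf("re%02d", 1:15)),
            setNames(replicate(35, random_dna(20)), sprintf("bg%02d", 1:35)))
  rb <- pwm_robustness(cand, list(seeds, seeds))
  expect_equal(rb$consensus_overlap[2], rb$n_consensus[1])
  expect_equal(rb$mast_overlap[2], rb$n_mast[1])

  # disjoint random background seed sets barely reproduce each other
  set.seed(71)
  bg_seeds1 <- replicate(10, random_dna(20))
  bg_seeds2 <- replicate(10, random_dna(20))
  rb2 <- pwm_robustness(cand, list(bg_seeds1, bg_seeds2))
  expect_lte(rb2$consensus_overlap[2], max(2L, rb2$n_consensus[1]))
})

test_that("alignment FASTA and ranking TSV writers produce readable output", {
  pat <- compile_pattern()
  set.seed(72)
  res <- vapply(c(0L, 3L), function(s) sample_from_pattern(pat, s),
                character(1))
  aln <- align_res(res)
  fa <- tempfile(fileext = ".fa")
  write_alignment_fasta(aln, fa, ids = c("a", "b"))
  back <- readLines(fa)
  expect_equal(back[c(1, 3)], c(">a", ">b"))
  expect_equal(nchar(back[2]), aln$frame_width)

  pair <- build_halfsite_pwms(aln)
  r <- rank_candidates(setNames(res, c("a", "b")), pair)
  tsv <- tempfile(fileext = ".tsv")
  write_ranking_tsv(r, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("id", "score", "pvalue", "evalue", "in_consensus") %in%
                    names(tab)))
})
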