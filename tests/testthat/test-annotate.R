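# second toy annotation: two close genes on chr1 whose +/-5 kb windows share
# ground, plus a miRNA gene on chr2
toy_annotation2 <- function() {
  gff <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t10000\t12000\t.\t+\t.\tID=gX;biotype=protein_coding",
    "chr1\ttoy\tmRNA\t10000\t12000\t.\t+\t.\tID=gX.t1;Parent=gX",
    "chr1\ttoy\texon\t10000\t10500\t.\t+\t.\tParent=gX.t1",
    "chr1\ttoy\texon\t11500\t12000\t.\t+\t.\tParent=gX.t1",
    "chr1\ttoy\tgene\t13000\t15000\t.\t-\t.\tID=gY;biotype=protein_coding",
    "chr1\ttoy\tmRNA\t13000\t15000\t.\t-\t.\tID=gY.t1;Parent=gY",
    "chr1\ttoy\texon\t13000\t15000\t.\t-\t.\tParent=gY.t1",
    "chr2\ttoy\tgene\t10000\t12000\t.\t+\t.\tID=gZ;biotype=miRNA",
    "chr2\ttoy\tmiRNA\t10000\t12000\t.\t+\t.\tID=gZ.t1;Parent=gZ",
    "chr2\ttoy\texon\t10000\t12000\t.\t+\t.\tParent=gZ.t1",
    "chr2\ttoy\tfive_prime_UTR\t10000\t10150\t.\t+\t.\tParent=gZ.t1")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  load_annotation(path)
}

test_that("load_annotation assembles the gene/transcript/exon hierarchy", {
  ann <- toy_annotation()
  expect_equal(nrow(ann$genes), 3L)
  expect_equal(sort(ann$genes$gene_id), c("gA", "gB", "gM"))
  expect_equal(ann$genes$biotype[ann$genes$gene_id == "gM"], "miRNA")
  expect_equal(nrow(ann$transcripts), 4L)
  # strand-aware TSS
  expect_equal(ann$transcripts$tss[ann$transcripts$transcript_id == "gA.t1"],
               10000L)
  expect_equal(ann$transcripts$tss[ann$transcripts$transcript_id == "gB.t1"],
               45000L)
  expect_equal(sum(ann$exons$transcript_id == "gA.t1"), 3L)

  # orphan features are skipped with a warning
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=t1",
               "chr1\tt\texon\t1\t50\t.\t+\t.\tParent=ghost"), path)
  expect_warning(ann2 <- load_annotation(path), "unknown transcript parent")
  expect_equal(nrow(ann2$exons), 1L)
})

test_that("synthetic gene models round-trip through GFF3 losslessly", {
  cfg <- simulation_config(seed = 8L, n_chroms = 2L, chrom_length = 3e5)
  sim <- gen_genome(cfg)
  ann <- gen_gene_models(sim$genome, 50L, seed = 88L)
  path <- tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- load_annotation(path)
  expect_equal(back$genes, ann$genes, ignore_attr = TRUE)
  expect_equal(back$transcripts[order(back$transcripts$transcript_id), ],
               ann$transcripts[order(ann$transcripts$transcript_id), ],
               ignore_attr = TRUE)
  srt <- function(d) {
    d <- d[order(d$transcript_id, d$start), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(srt(back$exons), srt(ann$exons))
  expect_equal(srt(back$utr5), srt(ann$utr5))
})

test_that("classify_region applies label precedence and signed TSS distance", {
  ann <- toy_annotation()
  cls <- function(gid, s, e) classify_region(ann, gid, s, e)
  # representative transcript of gA is the longer gA.t1
  expect_equal(cls("gA", 11000, 11019),
               data.frame(region = "intron", distance_to_tss = 1000L))
  # overlaps both 5'UTR and exon: 5'UTR wins
  expect_equal(cls("gA", 10050, 10150)$region, "five_prime_UTR")
  expect_equal(cls("gA", 12100, 12120)$region, "exon")
  expect_equal(cls("gA", 9781, 9800),
               data.frame(region = "upstream", distance_to_tss = -200L))
  expect_equal(cls("gA", 16100, 16120)$region, "downstream")
  expect_equal(cls("gA", 9995, 10005)$distance_to_tss, 0L)
  # minus-strand gene: upstream lies at higher coordinates
  expect_equal(cls("gB", 45100, 45119),
               data.frame(region = "upstream", distance_to_tss = -100L))
  expect_equal(cls("gB", 42000, 42019),
               data.frame(region = "intron", distance_to_tss = 2981L))
})

test_that("associate_genes applies the +/-5 kb window with multiplicity", {
  ann <- toy_annotation2()
  pat <- compile_pattern()
  m <- rbind(toy_match("chr1", 6000),    # 3980 bp from gX: upstream
             toy_match("chr1", 1000),    # > 5 kb from everything
             toy_match("chr1", 12400))   # inside both gX and gY windows
  a <- associate_genes(as_matchset(m), ann)
  expect_equal(a$gene_id[a$start == 6000], "gX")
  expect_equal(a$region[a$start == 6000], "upstream")
  expect_equal(a$distance_to_tss[a$start == 6000], -3981L)
  expect_false(1000 %in% a$start)
  both <- a[a$start == 12400, ]
  expect_setequal(both$gene_id, c("gX", "gY"))
  # boundary: window edge is inclusive
  edge <- associate_genes(as_matchset(toy_match("chr1", 4981)), ann)
  expect_equal(edge$gene_id, "gX")  # ends at 5000 = 10000 - 5000
  gap <- associate_genes(as_matchset(toy_match("chr1", 4960)), ann)
  expect_equal(nrow(gap), 0L)
})

test_that("gene association is symmetric under coordinate mirroring", {
  ann <- toy_annotation2()
  G <- 1e6
  m <- rbind(toy_match("chr1", 6000), toy_match("chr1", 12400),
             toy_match("chr1", 30000), toy_match("chr2", 10100))
  a <- associate_genes(as_matchset(m), ann)
  # mirror every interval: [s, e] -> [G - e + 1, G - s + 1], flip strands
  m2 <- m
  m2$start <- G - m$end + 1L
  m2$end <- G - m$start + 1L
  ann2 <- ann
  for (tab in c("genes", "transcripts", "exons", "utr5", "utr3", "cds")) {
    s <- ann2[[tab]]$start
    ann2[[tab]]$start <- G - ann2[[tab]]$end + 1L
    ann2[[tab]]$end <- G - s + 1L
  }
  ann2$genes$strand <- chartr("+-", "-+", ann2$genes$strand)
  ann2$transcripts$strand <- chartr("+-", "-+", ann2$transcripts$strand)
  ann2$transcripts$tss <- ifelse(ann2$transcripts$strand == "-",
                                 ann2$transcripts$end,
                                 ann2$transcripts$start)
  a2 <- associate_genes(as_matchset(m2), ann2)
  expect_equal(nrow(a2), nrow(a))
  expect_equal(sort(paste(a2$gene_id, G - a2$end + 1L)),
               sort(paste(a$gene_id, a$start)))
})

test_that("strand concordance reduces to the gene strand and is ~50% under a
           symmetric generator", {
  expect_true(strand_concordant("+"))
  expect_false(strand_concordant("-"))
  cfg <- simulation_config(seed = 19L, n_chroms = 4L, chrom_length = 2e6,
                           n_planted = 0L)
  sim <- gen_genome(cfg)
  ann <- gen_gene_models(sim$genome, 300L, seed = 20L)
  frac <- mean(strand_concordant(ann$genes$strand))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 300))
})

test_that("repeat_overlap counts >=1 bp intersections, including partial", {
  m <- rbind(toy_match("chr1", 101, 10),  # 101-130
             toy_match("chr1", 500))
  reps <- data.frame(chrom = "chr1", start = c(121, 131), end = c(200, 250),
                     family = c("hAT-AC", "DNA"))
  hits <- repeat_overlap(as_matchset(m), reps)
  expect_true(hits$in_repeat[1])          # 10 bp intersection with 121-200
  expect_equal(hits$families[1], "hAT-AC")
  expect_false(hits$in_repeat[2])
  # adjacency is not overlap
  m131 <- toy_match("chr1", 111, 0)       # 111-130 vs repeat at 131
  expect_false(repeat_overlap(as_matchset(m131),
                              reps[2, , drop = FALSE])$in_repeat)
})

test_that("repeat overlap fraction of random matches tracks repeat coverage", {
  cfg <- simulation_config(seed = 23L, n_chroms = 1L, chrom_length = 5e5)
  sim <- gen_genome(cfg)
  reps <- gen_repeats(sim$genome, 0.4, seed = 24L)
  covered <- sum(reps$end - reps$start + 1)
  frac_cov <- covered / 5e5
  set.seed(25)
  n <- 600L
  m <- do.call(rbind, lapply(sample.int(5e5 - 40L, n), function(s) {
    toy_match("chr1", s)
  }))
  hits <- repeat_overlap(as_matchset(m), reps)
  # a 20 bp match overlaps slightly more ground than a point: allow the
  # binomial 3 sigma band around the point-coverage expectation + edge slack
  p <- mean(hits$in_repeat)
  expect_lt(abs(p - frac_cov), 3 * sqrt(frac_cov * (1 - frac_cov) / n) + 0.03)
})

test_that("RepeatMasker .out and BED repeat parsers agree on coordinates", {
  rm_out <- c(
    "   SW  perc perc perc  query     position in query           matching repeat",
    "score  div. del. ins.  sequence  begin end (left)   repeat  class/family",
    "",
    "  463 11.4  0.0  0.0  chr1   101   200 (1000) + TE-X-4_DR  DNA/hAT-AC   1  100   (0)  1",
    "  300  9.9  0.0  0.0  chr2    51    80  (900) C RLTR1      LTR/ERVK     1   30   (0)  2")
  rpath <- tempfile(fileext = ".out")
  writeLines(rm_out, rpath)
  rm <- read_repeats(rpath, "repeatmasker")
  expect_equal(rm$chrom, c("chr1", "chr2"))
  expect_equal(rm$start, c(101L, 51L))
  expect_equal(rm$end, c(200L, 80L))
  expect_equal(rm$family, c("DNA/hAT-AC", "LTR/ERVK"))

  bpath <- tempfile(fileext = ".bed")
  writeLines(c("# comment", "chr1\t100\t200\tDNA/hAT-AC",
               "chr2\t50\t80\tLTR/ERVK"), bpath)
  bed <- read_repeats(bpath, "bed")
  expect_equal(bed[c("chrom", "start", "end", "family")],
               rm[c("chrom", "start", "end", "family")])
})

test_that("summarize_matches reproduces a hand-computed planted composition", {
  ann <- toy_annotation2()
  m <- rbind(toy_match("chr1", 6000),    # gX only: upstream (concordant)
             toy_match("chr1", 12400),   # gX + gY windows (multi-gene)
             toy_match("chr1", 11000),   # gX intron; also in gY's window
             toy_match("chr2", 10100),   # gZ five_prime_UTR
             toy_match("chr1", 30000),   # intergenic
             toy_match("chr2", 1000))    # intergenic
  ms <- as_matchset(m, genome_length = 1e6)
  a <- associate_genes(ms, ann)
  reps <- data.frame(chrom = "chr1", start = c(6010, 29000),
                     end = c(6100, 30005), family = c("hAT-AC", "DNA"))
  hits <- repeat_overlap(ms, reps)
  st <- summarize_matches(a, ms, hits)
  expect_equal(st$n_patterns, 6L)
  expect_equal(st$n_gene_related, 4L)
  expect_equal(st$n_unique_gene_related, 2L)   # 6000 (gX) and chr2 (gZ)
  expect_equal(st$n_multi_gene_patterns, 2L)   # 11000 and 12400 hit gX + gY
  expect_equal(st$n_genes, 3L)
  expect_equal(st$genes_by_biotype, c(miRNA = 1L, protein_coding = 2L))
  expect_equal(st$n_genes_multi_pattern, 2L)   # gX (3 patterns), gY (2)
  expect_equal(st$n_patterns_same_orientation, 4L)
  expect_equal(st$n_genes_same_orientation, 2L)
  expect_equal(st$region_counts,
               c(five_prime_UTR = 1L, upstream = 1L, intron = 1L,
                 other = 1L))
  expect_equal(st$n_gene_related_in_repeats, 1L)
  expect_equal(st$n_total_in_repeats, 2L)
  expect_equal(st$spacer_histogram[["0"]], 6L)
  expect_equal(sum(st$spacer_histogram), 6L)
  expect_equal(st$density_per_mb, 6)

  # conservation invariants
  expect_equal(st$n_unique_gene_related + st$n_multi_gene_patterns,
               st$n_gene_related)
  expect_equal(sum(st$genes_by_biotype), st$n_genes)
  expect_equal(sum(st$region_counts), st$n_patterns_same_orientation)
})

test_that("summarize_matches on zero matches yields all-zero statistics", {
  ms <- as_matchset(toy_match("chr1", 1)[0, ], genome_length = 1e6)
  st <- summarize_matches(associate_genes(ms, toy_annotation2()), ms)
  expect_equal(st$n_patterns, 0L)
  expect_equal(st$n_gene_related, 0L)
  expect_equal(st$n_genes, 0L)
  expect_equal(sum(st$spacer_histogram), 0L)
  expect_equal(st$density_per_mb, 0)
})

test_that("every Table-1-style field has a named SummaryStats counterpart", {
  ms <- as_matchset(toy_match("chr1", 6000), genome_length = 1e6)
  st <- summarize_matches(associate_genes(ms, toy_annotation2()), ms)
  expect_true(all(c(
    "n_patterns", "n_gene_related", "n_unique_gene_related",
    "n_multi_gene_patterns", "n_genes", "genes_by_biotype",
    "n_genes_multi_pattern", "n_patterns_same_orientation",
    "n_genes_same_orientation", "region_counts",
    "n_gene_related_in_repeats", "n_total_in_repeats", "spacer_histogram",
    "density_per_mb") %in% names(st)))
  expect_setequal(names(st$region_counts),
                  c("five_prime_UTR", "upstream", "intron", "other"))
})
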