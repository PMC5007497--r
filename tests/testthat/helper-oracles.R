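# Independent oracles and small fixture builders.  These deliberately share
# no code with the package internals: set membership instead of lookup
# matrices, per-pair loops instead of masks, plain arithmetic instead of
# GenomicRanges.

# Brute-force scan: test every (position, spacer) pair by direct symbol
# comparison against the IUPAC base sets.
oracle_scan <- function(seq, pattern) {
  chars <- strsplit(toupper(seq), "")[[1]]
  h1 <- strsplit(pattern$half1, "")[[1]]
  h2 <- if (nzchar(pattern$half2)) strsplit(pattern$half2, "")[[1]]
        else character(0)
  tab <- iupac_table()
  sat <- function(sym, base) base %in% tab[[sym]]  # sets hold A/C/G/T only
  L <- length(chars)
  starts <- integer(0); spacers <- integer(0)
  for (st in seq_len(L)) {
    if (st + length(h1) - 1L > L) break
    ok1 <- TRUE
    for (j in seq_along(h1)) {
      if (!sat(h1[j], chars[st + j - 1L])) { ok1 <- FALSE; break }
    }
    if (!ok1) next
    if (length(h2) == 0L) {
      starts <- c(starts, st); spacers <- c(spacers, 0L)
      next
    }
    for (sp in pattern$spacer_min:pattern$spacer_max) {
      e <- st + length(h1) + sp + length(h2) - 1L
      if (e > L) next
      ok2 <- TRUE
      for (j in seq_along(h2)) {
        if (!sat(h2[j], chars[st + length(h1) + sp + j - 1L])) {
          ok2 <- FALSE; break
        }
      }
      if (ok2) { starts <- c(starts, st); spacers <- c(spacers, sp) }
    }
  }
  w <- nchar(pattern$half1) + nchar(pattern$half2)
  out <- data.frame(start = starts, end = starts + w + spacers - 1L,
                    spacer = spacers)
  out[order(out$start, out$end), , drop = FALSE]
}

# Exhaustive p-value: enumerate all 4^width words, score each by summing the
# discretized log-odds cells, weight by background word probability.
oracle_pvalue <- function(pwm, threshold, resolution = 1e-3) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(seq_len(4L)), pwm$width))
  bg <- unclass(pwm$background)
  lo_int <- round(pwm$logodds / resolution)
  p <- 0
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    sc <- sum(lo_int[cbind(idx, seq_len(pwm$width))])
    if (sc >= round(threshold / resolution)) {
      p <- p + prod(bg[idx])
    }
  }
  p
}

match_key <- function(df) sprintf("%s:%d-%d", df$chrom, df$start, df$end)

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# A small deterministic gene annotation built by hand: one + gene with two
# transcripts (the longer is representative), one - gene, one miRNA gene.
toy_annotation <- function() {
  gff <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t10000\t16000\t.\t+\t.\tID=gA;Name=geneA;biotype=protein_coding",
    "chr1\ttoy\tmRNA\t10000\t16000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\ttoy\texon\t10000\t10500\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\texon\t12000\t12800\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\texon\t15000\t16000\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\tfive_prime_UTR\t10000\t10099\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\tthree_prime_UTR\t15800\t16000\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\tCDS\t10100\t10500\t.\t+\t.\tParent=gA.t1",
    "chr1\ttoy\tmRNA\t10000\t12800\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\ttoy\texon\t10000\t10500\t.\t+\t.\tParent=gA.t2",
    "chr1\ttoy\texon\t12000\t12800\t.\t+\t.\tParent=gA.t2",
    "chr1\ttoy\tgene\t40000\t45000\t.\t-\t.\tID=gB;Name=geneB;biotype=protein_coding",
    "chr1\ttoy\tmRNA\t40000\t45000\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\ttoy\texon\t40000\t41000\t.\t-\t.\tParent=gB.t1",
    "chr1\ttoy\texon\t44000\t45000\t.\t-\t.\tParent=gB.t1",
    "chr1\ttoy\tfive_prime_UTR\t44950\t45000\t.\t-\t.\tParent=gB.t1",
    "chr2\ttoy\tgene\t5000\t5100\t.\t+\t.\tID=gM;Name=mir1;biotype=miRNA",
    "chr2\ttoy\tmiRNA\t5000\t5100\t.\t+\t.\tID=gM.t1;Parent=gM",
    "chr2\ttoy\texon\t5000\t5100\t.\t+\t.\tParent=gM.t1")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  load_annotation(path)
}

# a MatchSet wrapper around a hand-built match table
as_matchset <- function(matches, pattern = compile_pattern(),
                        genome_length = NA_real_) {
  structure(list(matches = matches, pattern = pattern,
                 genome_length = genome_length), class = "MatchSet")
}

toy_match <- function(chrom, start, spacer = 0L,
                      pattern = compile_pattern()) {
  w <- nchar(pattern$half1) + nchar(pattern$half2)
  data.frame(chrom = chrom, start = start, end = start + w + spacer - 1L,
             spacer = spacer, strand = "+",
             sequence = strrep("A", w + spacer), stringsAsFactors = FALSE)
}

# Independent gene-context bookkeeping using plain loops and arithmetic (no
# GenomicRanges): region label + TSS distance of one match against one gene.
oracle_region <- function(ann, gid, s, e) {
  txs <- ann$transcripts[ann$transcripts$gene_id == gid, , drop = FALSE]
  txs <- txs[order(-(txs$end - txs$start), txs$transcript_id), , drop = FALSE]
  tx <- txs[1, ]
  hit <- function(tab) {
    tab <- tab[tab$transcript_id == tx$transcript_id, , drop = FALSE]
    ok <- FALSE
    for (i in seq_len(nrow(tab))) {
      if (s <= tab$end[i] && e >= tab$start[i]) ok <- TRUE
    }
    ok
  }
  dist <- if (tx$strand == "-") {
    if (s > tx$tss) tx$tss - s else if (e < tx$tss) tx$tss - e else 0L
  } else {
    if (e < tx$tss) e - tx$tss else if (s > tx$tss) s - tx$tss else 0L
  }
  region <- if (hit(ann$utr5)) "five_prime_UTR"
    else if (hit(ann$exons)) "exon"
    else if (s <= tx$end && e >= tx$start) "intron"
    else if (dist < 0) "upstream" else "downstream"
  list(region = region, dist = as.integer(dist))
}

# Independent Table-1-style roll-up over a match table.
oracle_summary <- function(m, ann, repeats, genome_length,
                           spacer_range = 0:15, window = 5000) {
  key <- sprintf("%s:%d-%d", m$chrom, m$start, m$end)
  g <- ann$genes
  pairs <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(g))) {
      if (m$chrom[i] == g$chrom[j] &&
          m$start[i] <= g$end[j] + window &&
          m$end[i] >= g$start[j] - window) {
        r <- oracle_region(ann, g$gene_id[j], m$start[i], m$end[i])
        pairs[[length(pairs) + 1L]] <- data.frame(
          match = key[i], gene = g$gene_id[j], biotype = g$biotype[j],
          strand = g$strand[j], region = r$region,
          stringsAsFactors = FALSE)
      }
    }
  }
  pr <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(match = character(0), gene = character(0),
               biotype = character(0), strand = character(0),
               region = character(0))
  in_rep <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(repeats))) {
      if (m$chrom[i] == repeats$chrom[j] &&
          m$start[i] <= repeats$end[j] && m$end[i] >= repeats$start[j]) {
        in_rep[i] <- TRUE
      }
    }
  }
  genes_per <- tapply(pr$gene, pr$match, function(x) length(unique(x)))
  conc <- pr[pr$strand == "+", , drop = FALSE]
  region_counts <- c(five_prime_UTR = 0L, upstream = 0L, intron = 0L,
                     other = 0L)
  if (nrow(conc)) {
    conc <- conc[order(conc$match, conc$gene), , drop = FALSE]
    first <- conc[!duplicated(conc$match), , drop = FALSE]
    lab <- ifelse(first$region %in% c("five_prime_UTR", "upstream",
                                      "intron"), first$region, "other")
    tb <- table(factor(lab, levels = names(region_counts)))
    region_counts[] <- as.integer(tb)
  }
  gene_tab <- unique(pr[c("gene", "biotype", "strand")])
  per_gene <- tapply(pr$match, pr$gene, function(x) length(unique(x)))
  bt <- table(gene_tab$biotype)
  list(
    n_patterns = nrow(m),
    n_gene_related = length(genes_per),
    n_unique_gene_related = sum(genes_per == 1L),
    n_multi_gene_patterns = sum(genes_per > 1L),
    n_genes = nrow(gene_tab),
    genes_by_biotype = stats::setNames(as.integer(bt), names(bt)),
    n_genes_multi_pattern = sum(per_gene > 1L),
    n_patterns_same_orientation = length(unique(conc$match)),
    n_genes_same_orientation = length(unique(conc$gene)),
    region_counts = region_counts,
    n_gene_related_in_repeats = sum(in_rep & key %in% pr$match),
    n_total_in_repeats = sum(in_rep),
    spacer_histogram = stats::setNames(
      as.integer(table(factor(m$spacer, levels = spacer_range))),
      spacer_range),
    density_per_mb = nrow(m) / (genome_length / 1e6))
}
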