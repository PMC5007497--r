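# Gene-context annotation of motif matches: +/-5 kb gene association, gene
# region labelling with TSS distances, strand concordance, repeat overlap,
# and the summary roll-up.

#' Load gene models from GFF3/GTF
#'
#' Assembles the gene -> transcript -> exon/UTR/CDS hierarchy via
#' `Parent`/`ID` attributes.  Features whose parent is missing are skipped
#' with a warning.
#'
#' @param path GFF3 or GTF file (anything `rtracklayer::import` reads).
#' @return A `GeneAnnotation`: list of data.frames `genes` (`gene_id`,
#'   `symbol`, `biotype`, `chrom`, `strand`, `start`, `end`), `transcripts`
#'   (`transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`),
#'   `exons`, `utr5`, `utr3`, `cds` (each `transcript_id`, `start`, `end`).
#' @export
load_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  get_attr <- function(name, default = NA_character_) {
    if (name %in% colnames(meta)) as.character(meta[[name]])
    else rep(default, length(gr))
  }
  id <- get_attr("ID")
  parent <- if ("Parent" %in% colnames(meta)) {
    vapply(as.list(meta$Parent), function(p) {
      if (length(p)) as.character(p[1]) else NA_character_
    }, character(1))
  } else rep(NA_character_, length(gr))
  type <- as.character(meta$type)
  df <- data.frame(
    type = type, id = id, parent = parent,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    symbol = get_attr("Name"), biotype = get_attr("biotype"),
    stringsAsFactors = FALSE)

  is_gene <- df$type == "gene"
  genes <- data.frame(
    gene_id = df$id[is_gene],
    symbol = ifelse(is.na(df$symbol[is_gene]), df$id[is_gene],
                    df$symbol[is_gene]),
    biotype = ifelse(is.na(df$biotype[is_gene]), "protein_coding",
                     df$biotype[is_gene]),
    chrom = df$chrom[is_gene], strand = df$strand[is_gene],
    start = df$start[is_gene], end = df$end[is_gene],
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene IDs in annotation")

  is_tx <- df$type %in% c("mRNA", "transcript", "miRNA", "ncRNA", "lnc_RNA")
  tx <- df[is_tx, , drop = FALSE]
  orphan_tx <- !(tx$parent %in% genes$gene_id)
  if (any(orphan_tx)) {
    warning(sum(orphan_tx), " transcript(s) with unknown gene parent skipped")
    tx <- tx[!orphan_tx, , drop = FALSE]
  }
  transcripts <- data.frame(
    transcript_id = tx$id, gene_id = tx$parent, chrom = tx$chrom,
    strand = tx$strand, start = tx$start, end = tx$end,
    tss = ifelse(tx$strand == "-", tx$end, tx$start),
    stringsAsFactors = FALSE)

  child_table <- function(types) {
    ch <- df[df$type %in% types, , drop = FALSE]
    orphan <- !(ch$parent %in% transcripts$transcript_id)
    if (any(orphan)) {
      warning(sum(orphan), " ", paste(types, collapse = "/"),
              " feature(s) with unknown transcript parent skipped")
      ch <- ch[!orphan, , drop = FALSE]
    }
    out <- data.frame(transcript_id = ch$parent, start = ch$start,
                      end = ch$end, stringsAsFactors = FALSE)
    out[order(out$transcript_id, out$start), , drop = FALSE]
  }
  structure(list(genes = genes, transcripts = transcripts,
                 exons = child_table("exon"),
                 utr5 = child_table("five_prime_UTR"),
                 utr3 = child_table("three_prime_UTR"),
                 cds = child_table("CDS")),
            class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat("GeneAnnotation:", nrow(x$genes), "gene(s),", nrow(x$transcripts),
      "transcript(s),", nrow(x$exons), "exon(s)\n")
  invisible(x)
}

#' Write a GeneAnnotation as GFF3
#'
#' @param ann A `GeneAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tp53re\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  }
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                          sprintf("ID=%s;Name=%s;biotype=%s",
                                  g$gene_id, g$symbol, g$biotype)))
    txs <- ann$transcripts[ann$transcripts$gene_id == g$gene_id, ,
                           drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      t <- txs[j, ]
      lines <- c(lines, fmt(t$chrom, "mRNA", t$start, t$end, t$strand,
                            sprintf("ID=%s;Parent=%s",
                                    t$transcript_id, t$gene_id)))
      for (tab in c("exons", "utr5", "utr3", "cds")) {
        type <- c(exons = "exon", utr5 = "five_prime_UTR",
                  utr3 = "three_prime_UTR", cds = "CDS")[[tab]]
        feats <- ann[[tab]][ann[[tab]]$transcript_id == t$transcript_id, ,
                            drop = FALSE]
        for (k in seq_len(nrow(feats))) {
          lines <- c(lines, fmt(t$chrom, type, feats$start[k], feats$end[k],
                                t$strand,
                                sprintf("Parent=%s", t$transcript_id)))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Representative transcript of a gene: longest span, ties broken by
# lexicographically smallest transcript_id.
.representative_transcript <- function(ann, gene_id) {
  txs <- ann$transcripts[ann$transcripts$gene_id == gene_id, , drop = FALSE]
  if (nrow(txs) == 0L) return(NULL)
  span <- txs$end - txs$start
  txs <- txs[order(-span, txs$transcript_id), , drop = FALSE]
  txs[1, , drop = FALSE]
}

.overlaps_any <- function(start, end, tab) {
  nrow(tab) > 0L && any(pmax(start, tab$start) <= pmin(end, tab$end))
}

#' Gene-region label and TSS distance of a match relative to one gene
#'
#' The match is classified against the gene's representative transcript
#' (longest; ties by transcript id) with label precedence 5'UTR > exon >
#' intron > upstream > downstream.  `distance_to_tss` is measured from the
#' match edge nearest the TSS and signed along the gene strand (negative =
#' upstream); a match spanning the TSS has distance 0.
#'
#' @param ann A `GeneAnnotation`.
#' @param gene_id Gene to classify against.
#' @param start,end Match interval, 1-based inclusive (vectorized).
#' @return Data.frame with `region` and `distance_to_tss`.
#' @export
classify_region <- function(ann, gene_id, start, end) {
  tx <- .representative_transcript(ann, gene_id)
  gene <- ann$genes[ann$genes$gene_id == gene_id, , drop = FALSE]
  if (is.null(tx)) {
    # no transcript: fall back to the gene span itself
    tx <- data.frame(transcript_id = NA_character_, gene_id = gene_id,
                     chrom = gene$chrom, strand = gene$strand,
                     start = gene$start, end = gene$end,
                     tss = if (gene$strand == "-") gene$end else gene$start,
                     stringsAsFactors = FALSE)
  }
  utr5 <- ann$utr5[ann$utr5$transcript_id %in% tx$transcript_id, ,
                   drop = FALSE]
  exons <- ann$exons[ann$exons$transcript_id %in% tx$transcript_id, ,
                     drop = FALSE]
  n <- length(start)
  region <- character(n)
  dist <- integer(n)
  minus <- tx$strand == "-"
  for (i in seq_len(n)) {
    s <- start[i]; e <- end[i]
    dist[i] <- if (minus) {
      if (s > tx$tss) tx$tss - s else if (e < tx$tss) tx$tss - e else 0L
    } else {
      if (e < tx$tss) e - tx$tss else if (s > tx$tss) s - tx$tss else 0L
    }
    region[i] <-
      if (.overlaps_any(s, e, utr5)) "five_prime_UTR"
      else if (.overlaps_any(s, e, exons)) "exon"
      else if (s <= tx$end && e >= tx$start) "intron"
      else if (dist[i] < 0L) "upstream"
      else "downstream"
  }
  data.frame(region = region, distance_to_tss = as.integer(dist),
             stringsAsFactors = FALSE)
}

#' Strand concordance of a forward-scanned match with a gene
#'
#' Matches are reported on the forward strand by convention, so concordance
#' reduces to the gene lying on `+`; kept as an explicit operation (and
#' caveat) because the pattern class itself is strand-symmetric.
#'
#' @param gene_strand Character vector of gene strands (`+`/`-`).
#' @param match_strand Match strand (default `+`).
#' @return Logical vector.
#' @export
strand_concordant <- function(gene_strand, match_strand = "+") {
  gene_strand == match_strand
}

#' Associate matches with genes within a +/- window
#'
#' A match is gene-related iff its interval overlaps
#' `[gene_start - window, gene_end + window]`.  A match inside several gene
#' windows yields one row per (match, gene) pair.
#'
#' @param ms A `MatchSet` (or its `matches` data.frame).
#' @param ann A `GeneAnnotation`.
#' @param window Flanking window in bp (default 5000).
#' @return Data.frame with one row per (match, gene) pair: the match columns,
#'   `match_id`, plus `gene_id`, `symbol`, `biotype`, `gene_strand`,
#'   `region`, `distance_to_tss`, `strand_concordant`.
#' @export
associate_genes <- function(ms, ann, window = 5000L) {
  m <- if (inherits(ms, "MatchSet")) ms$matches else ms
  empty <- data.frame(match_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      spacer = integer(0), strand = character(0),
                      sequence = character(0), gene_id = character(0),
                      symbol = character(0), biotype = character(0),
                      gene_strand = character(0), region = character(0),
                      distance_to_tss = integer(0),
                      strand_concordant = logical(0), stringsAsFactors = FALSE)
  if (nrow(m) == 0L || nrow(ann$genes) == 0L) return(empty)
  mgr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$start, m$end))
  g <- ann$genes
  ggr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(1L, g$start - window), g$end + window))
  ov <- GenomicRanges::findOverlaps(mgr, ggr, ignore.strand = TRUE)
  if (length(ov) == 0L) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  rows <- lapply(seq_along(qi), function(k) {
    mi <- qi[k]; gi <- si[k]
    cls <- classify_region(ann, g$gene_id[gi], m$start[mi], m$end[mi])
    data.frame(
      match_id = sprintf("%s:%d-%d", m$chrom[mi], m$start[mi], m$end[mi]),
      chrom = m$chrom[mi], start = m$start[mi], end = m$end[mi],
      spacer = m$spacer[mi], strand = m$strand[mi],
      sequence = m$sequence[mi], gene_id = g$gene_id[gi],
      symbol = g$symbol[gi], biotype = g$biotype[gi],
      gene_strand = g$strand[gi], region = cls$region,
      distance_to_tss = cls$distance_to_tss,
      strand_concordant = strand_concordant(g$strand[gi], m$strand[mi]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
}

#' Repeat/transposable-element overlap of matches
#'
#' Overlap means at least 1 bp of intersection; partial overlap counts.
#'
#' @param ms A `MatchSet` (or its `matches` data.frame).
#' @param repeats Data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `family`.
#' @return Data.frame aligned with the matches: `in_repeat` (logical) and
#'   `families` (comma-joined labels, `""` if none).
#' @export
repeat_overlap <- function(ms, repeats) {
  m <- if (inherits(ms, "MatchSet")) ms$matches else ms
  out <- data.frame(in_repeat = rep(FALSE, nrow(m)),
                    families = rep("", nrow(m)), stringsAsFactors = FALSE)
  if (nrow(m) == 0L || is.null(repeats) || nrow(repeats) == 0L) return(out)
  if (is.null(repeats$family)) repeats$family <- "repeat"
  mgr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$start, m$end))
  rgr <- GenomicRanges::GRanges(repeats$chrom,
                                IRanges::IRanges(repeats$start, repeats$end))
  ov <- GenomicRanges::findOverlaps(mgr, rgr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out$in_repeat[unique(qi)] <- TRUE
  fam <- vapply(split(repeats$family[si], qi), function(f) {
    paste(sort(unique(f)), collapse = ",")
  }, character(1))
  out$families[as.integer(names(fam))] <- fam
  out
}

#' Read repeat intervals from BED or RepeatMasker .out
#'
#' @param path Input file.
#' @param format `"bed"` (0-based half-open; family taken from the name
#'   column when present) or `"repeatmasker"` (standard whitespace table;
#'   family from the repeat class/family column).
#' @return Data.frame `chrom`, `start`, `end` (1-based inclusive), `family`.
#' @export
read_repeats <- function(path, format = c("bed", "repeatmasker")) {
  format <- match.arg(format)
  if (format == "bed") {
    lines <- grep("^(#|track|browser)", readLines(path, warn = FALSE),
                  value = TRUE, invert = TRUE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), family = character(0),
                        stringsAsFactors = FALSE))
    }
    f <- strsplit(lines, "\t")
    data.frame(chrom = vapply(f, `[`, character(1), 1L),
               start = as.integer(vapply(f, `[`, character(1), 2L)) + 1L,
               end = as.integer(vapply(f, `[`, character(1), 3L)),
               family = vapply(f, function(x) {
                 if (length(x) >= 4L) x[4] else "repeat"
               }, character(1)),
               stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    body <- grep("^\\s*[0-9]+\\s", lines, value = TRUE)
    f <- strsplit(trimws(body), "\\s+")
    data.frame(chrom = vapply(f, `[`, character(1), 5L),
               start = as.integer(vapply(f, `[`, character(1), 6L)),
               end = as.integer(vapply(f, `[`, character(1), 7L)),
               family = vapply(f, `[`, character(1), 11L),
               stringsAsFactors = FALSE)
  }
}

#' Summary statistics of a scan + annotation pass
#'
#' The roll-up reported for a genome-wide scan: totals, gene association and
#' multiplicity, orientation, gene-region composition (among same-orientation
#' patterns), repeat overlap, the spacer-length histogram and the per-Mb
#' pattern density.
#'
#' @param annotations Output of [associate_genes()].
#' @param ms The `MatchSet` the annotations came from.
#' @param repeat_hits Optional output of [repeat_overlap()] aligned with the
#'   matches; when absent the repeat counters are `NA`.
#' @return A `SummaryStats` list; see Details for fields.
#' @details Fields: `n_patterns`, `n_gene_related`, `n_unique_gene_related`,
#'   `n_multi_gene_patterns`, `n_genes`, `genes_by_biotype`,
#'   `n_genes_multi_pattern`, `n_patterns_same_orientation`,
#'   `n_genes_same_orientation`, `region_counts` (five_prime_UTR, upstream,
#'   intron, other; computed over same-orientation patterns, one gene per
#'   pattern), `n_gene_related_in_repeats`, `n_total_in_repeats`,
#'   `spacer_histogram`, `density_per_mb`.
#' @export
summarize_matches <- function(annotations, ms, repeat_hits = NULL) {
  m <- ms$matches
  key <- sprintf("%s:%d-%d", m$chrom, m$start, m$end)
  n_patterns <- nrow(m)
  a <- annotations
  genes_per_pattern <- if (nrow(a)) {
    tapply(a$gene_id, a$match_id, function(x) length(unique(x)))
  } else integer(0)
  n_gene_related <- length(genes_per_pattern)
  n_multi <- sum(genes_per_pattern > 1L)
  gene_tab <- if (nrow(a)) {
    unique(a[c("gene_id", "biotype", "gene_strand")])
  } else data.frame(gene_id = character(0), biotype = character(0),
                    gene_strand = character(0))
  patterns_per_gene <- if (nrow(a)) {
    tapply(a$match_id, a$gene_id, function(x) length(unique(x)))
  } else integer(0)
  conc <- a[a$strand_concordant, , drop = FALSE]
  same_orient_patterns <- unique(conc$match_id)
  # one representative (first by gene id) annotation per same-orientation
  # pattern, for the region composition
  region_counts <- c(five_prime_UTR = 0L, upstream = 0L, intron = 0L,
                     other = 0L)
  if (nrow(conc)) {
    conc <- conc[order(conc$match_id, conc$gene_id), , drop = FALSE]
    rep_ann <- conc[!duplicated(conc$match_id), , drop = FALSE]
    lab <- ifelse(rep_ann$region %in% c("five_prime_UTR", "upstream",
                                        "intron"),
                  rep_ann$region, "other")
    tb <- table(factor(lab, levels = names(region_counts)))
    region_counts[] <- as.integer(tb)
  }
  spacer_levels <- ms$pattern$spacer_min:ms$pattern$spacer_max
  spacer_histogram <- table(factor(m$spacer, levels = spacer_levels))
  in_rep <- if (!is.null(repeat_hits)) repeat_hits$in_repeat else NULL
  structure(list(
    n_patterns = n_patterns,
    n_gene_related = n_gene_related,
    n_unique_gene_related = n_gene_related - n_multi,
    n_multi_gene_patterns = n_multi,
    n_genes = nrow(gene_tab),
    genes_by_biotype = if (nrow(gene_tab)) {
      tab <- table(gene_tab$biotype)
      stats::setNames(as.integer(tab), names(tab))
    } else stats::setNames(integer(0), character(0)),
    n_genes_multi_pattern = sum(patterns_per_gene > 1L),
    n_patterns_same_orientation = length(same_orient_patterns),
    n_genes_same_orientation =
      length(unique(conc$gene_id)),
    region_counts = region_counts,
    n_gene_related_in_repeats = if (is.null(in_rep)) NA_integer_ else {
      sum(key %in% a$match_id & in_rep)
    },
    n_total_in_repeats = if (is.null(in_rep)) NA_integer_ else sum(in_rep),
    spacer_histogram = stats::setNames(as.integer(spacer_histogram),
                                       names(spacer_histogram)),
    density_per_mb = if (is.na(ms$genome_length) || ms$genome_length == 0) {
      NA_real_
    } else n_patterns / (ms$genome_length / 1e6)
  ), class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat("General features of the scanned patterns\n")
  cat(sprintf("  Number of patterns                            %d\n",
              x$n_patterns))
  cat(sprintf("  Number of gene-related patterns               %d\n",
              x$n_gene_related))
  cat(sprintf("  Number of unique gene-related patterns        %d\n",
              x$n_unique_gene_related))
  cat(sprintf("  Patterns proximal to more than one gene       %d\n",
              x$n_multi_gene_patterns))
  bt <- paste(sprintf("%d %s", x$genes_by_biotype,
                      names(x$genes_by_biotype)), collapse = ", ")
  cat(sprintf("  Genes (grouped by biotype)                    %s\n",
              if (nzchar(bt)) bt else "0"))
  cat(sprintf("  Genes with more than one associated pattern   %d\n",
              x$n_genes_multi_pattern))
  cat(sprintf("  Patterns in the same orientation of genes     %d\n",
              x$n_patterns_same_orientation))
  cat(sprintf("  Genes in the same orientation of patterns     %d\n",
              x$n_genes_same_orientation))
  for (r in names(x$region_counts)) {
    cat(sprintf("  Patterns in %-33s %d/%d\n", r, x$region_counts[[r]],
                x$n_patterns_same_orientation))
  }
  cat(sprintf("  Gene-related patterns within repeats          %s/%d\n",
              x$n_gene_related_in_repeats, x$n_gene_related))
  cat(sprintf("  All patterns within repeats                   %s/%d\n",
              x$n_total_in_repeats, x$n_patterns))
  cat(sprintf("  Pattern density                               %.2f per Mb\n",
              x$density_per_mb))
  invisible(x)
}

#' Write SummaryStats as machine-readable key=value TSV
#' @param stats A `SummaryStats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(stats, path) {
  flat <- c()
  for (nm in names(stats)) {
    v <- stats[[nm]]
    if (length(v) == 1L && is.null(names(v))) {
      flat[nm] <- as.character(v)
    } else {
      for (k in names(v)) flat[paste0(nm, ".", k)] <- as.character(v[[k]])
    }
  }
  utils::write.table(data.frame(key = names(flat), value = unname(flat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write annotated pattern-gene pairs as TSV
#'
#' A header comment records the orientation caveat: matches are reported on
#' the forward strand by convention because the pattern class is
#' strand-symmetric.
#'
#' @param annotations Output of [associate_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# pattern strand is always '+' (forward-strand scan of a",
                   "strand-symmetric pattern); strand_concordant therefore",
                   "records the gene strand"), con)
  utils::write.table(annotations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
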