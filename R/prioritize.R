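# Deterministic candidate filtering and ranking-merge bookkeeping around the
# external gene prioritization tools (whose TSV outputs are consumed, never
# recomputed).

#' Prioritization criteria
#'
#' Any criterion left `NULL` is not applied; with every criterion `NULL` the
#' filter is the identity.
#'
#' @param allowed_regions Region labels a pattern must fall in (default
#'   upstream or 5'UTR, the canonical RE locations); `NULL` to skip.
#' @param max_abs_tss_distance Maximum `|distance_to_TSS|` in bp; `NULL` to
#'   skip.
#' @param require_strand_concordance Keep only gene-concordant patterns.
#' @param min_patterns_per_gene Minimum distinct patterns per gene; `NULL` to
#'   skip.
#' @param top_k_per_ranking Per-ranking cutoff used by [merge_rankings()].
#' @return A `PrioritizationCriteria` list.
#' @export
prioritization_criteria <- function(
    allowed_regions = c("upstream", "five_prime_UTR"),
    max_abs_tss_distance = NULL,
    require_strand_concordance = FALSE,
    min_patterns_per_gene = NULL,
    top_k_per_ranking = 50L) {
  stopifnot(top_k_per_ranking >= 1L)
  structure(list(allowed_regions = allowed_regions,
                 max_abs_tss_distance = max_abs_tss_distance,
                 require_strand_concordance = require_strand_concordance,
                 min_patterns_per_gene = min_patterns_per_gene,
                 top_k_per_ranking = as.integer(top_k_per_ranking)),
            class = "PrioritizationCriteria")
}

#' Filter annotated pattern-gene pairs by prioritization criteria
#'
#' Deterministic and order-preserving; idempotent by construction.
#'
#' @param annotations Output of [associate_genes()].
#' @param criteria A `PrioritizationCriteria`.
#' @return The retained rows of `annotations`.
#' @export
filter_candidates <- function(annotations,
                              criteria = prioritization_criteria()) {
  keep <- rep(TRUE, nrow(annotations))
  if (!is.null(criteria$allowed_regions)) {
    keep <- keep & annotations$region %in% criteria$allowed_regions
  }
  if (!is.null(criteria$max_abs_tss_distance)) {
    keep <- keep &
      abs(annotations$distance_to_tss) <= criteria$max_abs_tss_distance
  }
  if (isTRUE(criteria$require_strand_concordance)) {
    keep <- keep & annotations$strand_concordant
  }
  out <- annotations[keep, , drop = FALSE]
  if (!is.null(criteria$min_patterns_per_gene) && nrow(out) > 0L) {
    per_gene <- tapply(out$match_id, out$gene_id,
                       function(x) length(unique(x)))
    ok_genes <- names(per_gene)[per_gene >= criteria$min_patterns_per_gene]
    out <- out[out$gene_id %in% ok_genes, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Map genes through an ortholog table, keeping one homology type
#'
#' @param genes Character vector of source gene ids.
#' @param pairs Data.frame with `source_id`, `target_id`, `homology_type`
#'   (vocabulary: one2one, one2many, many2many), e.g. read from a TSV export.
#' @param keep Homology type to retain (default `"one2one"`, the type that
#'   best preserves functional equivalence across species).
#' @return Data.frame `gene_id`, `ortholog` (`NA` when no surviving pair).
#' @export
join_orthologs <- function(genes, pairs, keep = "one2one") {
  stopifnot(all(c("source_id", "target_id", "homology_type") %in%
                  names(pairs)))
  bad <- !pairs$homology_type %in% c("one2one", "one2many", "many2many")
  if (any(bad)) {
    stop("unknown homology type(s): ",
         paste(unique(pairs$homology_type[bad]), collapse = ", "))
  }
  kept <- pairs[pairs$homology_type == keep, , drop = FALSE]
  if (keep == "one2one") {
    conflict <- tapply(kept$target_id, kept$source_id,
                       function(x) length(unique(x)))
    if (any(conflict > 1L)) {
      stop("conflicting one2one rows for source gene(s): ",
           paste(names(conflict)[conflict > 1L], collapse = ", "))
    }
  }
  idx <- match(genes, kept$source_id)
  data.frame(gene_id = genes, ortholog = kept$target_id[idx],
             stringsAsFactors = FALSE)
}

#' Merge external prioritization rankings by top-k union
#'
#' Takes the top `k` genes of each ranking (by its `rank` column) and returns
#' their union with provenance: which ranking(s) admitted each gene.
#'
#' @param rankings Named list of data.frames (`gene_id`, `score`, `rank`) or
#'   of TSV file paths with those columns.
#' @param top_k Per-ranking cutoff (default 50).
#' @return Data.frame `gene_id`, `sources` (comma-joined ranking names),
#'   `best_rank` (smallest admitting rank), sorted by `best_rank` then id.
#' @export
merge_rankings <- function(rankings, top_k = 50L) {
  if (is.null(names(rankings))) {
    names(rankings) <- sprintf("ranking%d", seq_along(rankings))
  }
  tops <- lapply(names(rankings), function(nm) {
    r <- rankings[[nm]]
    if (is.character(r) && length(r) == 1L) {
      r <- utils::read.table(r, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    }
    if (!all(c("gene_id", "rank") %in% names(r))) {
      stop("ranking '", nm, "' lacks gene_id/rank columns")
    }
    r <- r[order(r$rank), , drop = FALSE]
    r <- utils::head(r, top_k)
    data.frame(gene_id = r$gene_id, source = nm, rank = r$rank,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, tops)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(gene_id = character(0), sources = character(0),
                      best_rank = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(all, all$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1],
               sources = paste(sort(unique(d$source)), collapse = ","),
               best_rank = min(d$rank), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$best_rank, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
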