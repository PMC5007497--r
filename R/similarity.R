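# PWM-seeded similarity re-search: align validated response elements in a
# fixed frame, build one PWM per decamer, rank candidate patterns by E-value
# (MAST-like) and by exact p-value (matrix-scan-like), and intersect the two
# significant sets.

#' Fixed-frame alignment of response elements with variable spacers
#'
#' Each RE is laid out in a frame of width `h1 + max(spacer) + h2`: the first
#' half-site left-justified in columns `1..h1`, the second half-site
#' right-justified in the last `h2` columns, the spacer immediately after the
#' first half-site and gap characters (`-`) filling the remainder.  The two
#' half-site column blocks are therefore gap-free by construction.
#'
#' @param sequences Character vector of RE sequences (length
#'   `h1 + spacer + h2` each).
#' @param spacers Integer vector of spacer lengths; inferred from the
#'   sequence lengths when `NULL`.
#' @param pattern The `IUPACPattern` defining the half-site widths and the
#'   admissible spacer range.
#' @return A `MotifAlignment`: list with `rows` (character matrix with `-`
#'   gaps), `sequences`, `spacers`, `frame_width`, `pattern`.
#' @export
align_res <- function(sequences, spacers = NULL, pattern = compile_pattern()) {
  h1 <- nchar(pattern$half1); h2 <- nchar(pattern$half2)
  if (is.null(spacers)) spacers <- nchar(sequences) - h1 - h2
  spacers <- as.integer(spacers)
  if (any(nchar(sequences) != h1 + spacers + h2)) {
    stop("sequence length must equal h1 + spacer + h2")
  }
  if (any(spacers < pattern$spacer_min | spacers > pattern$spacer_max)) {
    stop("spacer outside the pattern's admissible range")
  }
  frame_width <- h1 + max(spacers) + h2
  rows <- matrix("-", nrow = length(sequences), ncol = frame_width)
  for (i in seq_along(sequences)) {
    ch <- strsplit(toupper(sequences[i]), "")[[1]]
    rows[i, seq_len(h1 + spacers[i])] <- ch[seq_len(h1 + spacers[i])]
    rows[i, (frame_width - h2 + 1L):frame_width] <-
      ch[(h1 + spacers[i] + 1L):length(ch)]
  }
  structure(list(rows = rows, sequences = toupper(sequences),
                 spacers = spacers, frame_width = frame_width,
                 pattern = pattern), class = "MotifAlignment")
}

#' @export
print.MotifAlignment <- function(x, ...) {
  cat("MotifAlignment:", nrow(x$rows), "sequence(s), frame width",
      x$frame_width, "\n")
  for (i in seq_len(min(nrow(x$rows), 12L))) {
    cat(" ", paste(x$rows[i, ], collapse = ""), "\n")
  }
  invisible(x)
}

#' Write a MotifAlignment as aligned FASTA
#' @param aln A `MotifAlignment`.
#' @param path Output path.
#' @param ids Optional sequence ids (default `re1..reN`).
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("re%d", seq_len(nrow(aln$rows)))
  lines <- unlist(lapply(seq_len(nrow(aln$rows)), function(i) {
    c(paste0(">", ids[i]), paste(aln$rows[i, ], collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Build the two half-site PWMs from a fixed-frame alignment
#'
#' The left PWM is built from alignment columns `1..h1`, the right PWM from
#' the last `h2` columns; gap/spacer columns never enter the counts.
#'
#' @param aln A `MotifAlignment`.
#' @param pseudocount,background Passed to [build_pwm()].
#' @return A `PWMPair` with the alignment pattern's spacer bounds.
#' @export
build_halfsite_pwms <- function(aln, pseudocount = 0.25,
                                background = uniform_background()) {
  h1 <- nchar(aln$pattern$half1); h2 <- nchar(aln$pattern$half2)
  left_sites <- apply(aln$rows[, seq_len(h1), drop = FALSE], 1, paste,
                      collapse = "")
  right_sites <- apply(
    aln$rows[, (aln$frame_width - h2 + 1L):aln$frame_width, drop = FALSE],
    1, paste, collapse = "")
  pwm_pair(build_pwm(left_sites, pseudocount, background),
           build_pwm(right_sites, pseudocount, background),
           aln$pattern$spacer_min, aln$pattern$spacer_max)
}

# Combined score of one candidate.  An RE-sized candidate (length within
# w1 + spacer range + w2) is scored in its end-anchored frame - first
# half-site at the 5' end, second at the 3' end, spacer inferred from the
# length - the one placement that uses the whole candidate.  A longer
# sequence is scanned and the best placement reported.
.best_pair_score <- function(seq, pair) {
  w1 <- pair$left$width; w2 <- pair$right$width
  len <- nchar(seq)
  if (len < w1 + w2 + pair$spacer_min) {
    stop("candidate shorter than the two half-sites plus minimum spacer")
  }
  if (len <= w1 + w2 + pair$spacer_max) {
    return(score_site(pair$left, substr(seq, 1L, w1)) +
             score_site(pair$right, substr(seq, len - w2 + 1L, len)))
  }
  best <- -Inf
  for (s in pair$spacer_min:pair$spacer_max) {
    total <- w1 + s + w2
    for (off in 0:(len - total)) {
      sc <- score_site(pair$left, substr(seq, off + 1L, off + w1)) +
        score_site(pair$right, substr(seq, off + w1 + s + 1L, off + total))
      if (sc > best) best <- sc
    }
  }
  best
}

#' Score and rank candidate patterns against a half-site PWM pair
#'
#' Every candidate gets its best combined score over all admissible
#' placements, the exact p-value of that score under the background, and an
#' E-value against the number of candidates.  Two significance calls are
#' made: MAST-like (`evalue <= evalue_cutoff`, default 10) and
#' matrix-scan-like (`pvalue < alpha`, default 0.05); their intersection is
#' the consensus set.
#'
#' @param candidates Named character vector of candidate sequences (names are
#'   candidate ids), or a data.frame with `id` and `sequence` columns.
#' @param pair A `PWMPair`.
#' @param background A `Background` for the p-value null; defaults to the
#'   PWMs' own backgrounds.
#' @param evalue_cutoff MAST-like E-value cutoff.
#' @param alpha Matrix-scan-like p-value threshold.
#' @param bh_correct Apply Benjamini-Hochberg correction to the p-values
#'   before the `alpha` gate (off by default: the per-site gate is
#'   conventionally uncorrected in this kind of screen).
#' @param resolution p-value score grid, bits.
#' @return A `CandidateRanking`: list with `table` (id, sequence, score,
#'   pvalue, evalue, rank, in_mast, in_scan, in_consensus; sorted by
#'   ascending E-value, ties by id), `evalue_cutoff`, `alpha`.
#' @export
rank_candidates <- function(candidates, pair, background = NULL,
                            evalue_cutoff = 10, alpha = 0.05,
                            bh_correct = FALSE, resolution = 1e-3) {
  if (is.data.frame(candidates)) {
    cand <- stats::setNames(candidates$sequence, candidates$id)
  } else {
    cand <- candidates
    if (is.null(names(cand))) {
      names(cand) <- sprintf("cand%d", seq_along(cand))
    }
  }
  if (anyDuplicated(names(cand))) stop("duplicate candidate ids")
  scores <- vapply(cand, .best_pair_score, numeric(1), pair = pair)
  dist <- score_distribution(pair, background, resolution)
  pvals <- .dist_pvalue(dist, scores)
  evals <- site_evalue(pvals, length(cand))
  gate_p <- if (bh_correct) stats::p.adjust(pvals, method = "BH") else pvals
  tab <- data.frame(id = names(cand), sequence = unname(cand),
                    score = unname(scores), pvalue = unname(pvals),
                    evalue = unname(evals),
                    in_mast = unname(evals) <= evalue_cutoff,
                    in_scan = unname(gate_p) < alpha,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$evalue, tab$id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$in_consensus <- tab$in_mast & tab$in_scan
  rownames(tab) <- NULL
  structure(list(table = tab, evalue_cutoff = evalue_cutoff, alpha = alpha),
            class = "CandidateRanking")
}

#' @export
print.CandidateRanking <- function(x, ...) {
  cat(sprintf(
    "CandidateRanking: %d candidates; %d pass E<=%g, %d pass p<%g, %d consensus\n",
    nrow(x$table), sum(x$table$in_mast), x$evalue_cutoff,
    sum(x$table$in_scan), x$alpha, sum(x$table$in_consensus)))
  invisible(x)
}

#' MAST-like significant candidates (ascending E-value, cutoff 10)
#'
#' @inheritParams rank_candidates
#' @return Character vector of candidate ids with `evalue <= evalue_cutoff`,
#'   ordered by ascending E-value (ties by id).
#' @export
mast_like_rank <- function(candidates, pair, background = NULL,
                           evalue_cutoff = 10, resolution = 1e-3) {
  r <- rank_candidates(candidates, pair, background,
                       evalue_cutoff = evalue_cutoff, resolution = resolution)
  r$table$id[r$table$in_mast]
}

#' Matrix-scan-like significant candidates (best-score p-value < alpha)
#'
#' @inheritParams rank_candidates
#' @return Character vector of candidate ids with `pvalue < alpha`.
#' @export
matrixscan_like <- function(candidates, pair, background = NULL,
                            alpha = 0.05, bh_correct = FALSE,
                            resolution = 1e-3) {
  r <- rank_candidates(candidates, pair, background, alpha = alpha,
                       bh_correct = bh_correct, resolution = resolution)
  r$table$id[r$table$in_scan]
}

#' Consensus candidates: intersection of the two significant sets
#'
#' @param ranking A `CandidateRanking`.
#' @return Character vector of ids in both significant sets, ordered by the
#'   MAST-like rank.
#' @export
consensus_candidates <- function(ranking) {
  stopifnot(inherits(ranking, "CandidateRanking"))
  ranking$table$id[ranking$table$in_consensus]
}

#' Write a CandidateRanking as TSV
#' @param ranking A `CandidateRanking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(ranking$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Seed-set robustness of the similarity search
#'
#' Rebuilds the half-site PWM pair from each seed set of REs, reruns the
#' ranking on the same candidate pool, and reports the overlap of each seed
#' set's significant/consensus sets with those of the first seed set (the
#' reference) - the PWM-II/PWM-III experiment generalized.
#'
#' @param candidates As in [rank_candidates()].
#' @param seed_sets List of RE seed sets; each element is a character vector
#'   of RE sequences (spacers inferred from length) or a data.frame with
#'   `sequence` and `spacer`.
#' @param pattern The `IUPACPattern` framing the alignment.
#' @param pseudocount,background,evalue_cutoff,alpha,resolution Passed
#'   through.
#' @return Data.frame, one row per seed set: sizes of its significant sets
#'   and overlaps (`mast_overlap`, `scan_overlap`, `consensus_overlap`) with
#'   seed set 1.
#' @export
pwm_robustness <- function(candidates, seed_sets,
                           pattern = compile_pattern(), pseudocount = 0.25,
                           background = uniform_background(),
                           evalue_cutoff = 10, alpha = 0.05,
                           resolution = 1e-3) {
  stopifnot(length(seed_sets) >= 2L)
  sets <- lapply(seed_sets, function(ss) {
    if (is.data.frame(ss)) {
      aln <- align_res(ss$sequence, ss$spacer, pattern)
    } else {
      aln <- align_res(ss, pattern = pattern)
    }
    pair <- build_halfsite_pwms(aln, pseudocount, background)
    r <- rank_candidates(candidates, pair, background,
                         evalue_cutoff = evalue_cutoff, alpha = alpha,
                         resolution = resolution)
    list(mast = r$table$id[r$table$in_mast],
         scan = r$table$id[r$table$in_scan],
         consensus = consensus_candidates(r))
  })
  ref <- sets[[1]]
  do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(seed_set = i,
               n_mast = length(s$mast), n_scan = length(s$scan),
               n_consensus = length(s$consensus),
               mast_overlap = length(intersect(s$mast, ref$mast)),
               scan_overlap = length(intersect(s$scan, ref$scan)),
               consensus_overlap =
                 length(intersect(s$consensus, ref$consensus)))
  }))
}
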