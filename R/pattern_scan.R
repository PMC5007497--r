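# Exact degenerate scanning of the bipartite p53 motif: two IUPAC half-sites
# separated by a variable, unconstrained spacer (default RRRCWWGYYY x2,
# spacer 0-15 bp).

#' The canonical p53 response-element pattern
#' @export
P53_PATTERN_SPEC <- "RRRCWWGYYYN{0,15}RRRCWWGYYY"

#' Compile a bipartite IUPAC pattern specification
#'
#' Accepts either `<half1>N{a,b}<half2>` (two IUPAC half-sites separated by a
#' run of `a` to `b` unconstrained bases) or a plain IUPAC string (treated as
#' a single block: spacer 0-0, empty second half).  Whitespace inside the
#' braces is tolerated, matching the common command-line spelling
#' `"RRRCWWGYYYN{0, 15}RRRCWWGYYY"`.
#'
#' @param spec Pattern specification string.
#' @return An `IUPACPattern`: list with `half1`, `half2`, `spacer_min`,
#'   `spacer_max`, `spec`.
#' @examples
#' compile_pattern("RRRCWWGYYYN{0,15}RRRCWWGYYY")
#' compile_pattern("ACGT")
#' @export
compile_pattern <- function(spec = P53_PATTERN_SPEC) {
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  syms <- paste(names(.IUPAC_BASES), collapse = "")
  bip <- regmatches(spec, regexec(
    paste0("^([", syms, "]+)N\\{\\s*([0-9]+)\\s*,\\s*([0-9]+)\\s*\\}",
           "([", syms, "]+)$"), spec))[[1]]
  if (length(bip) == 5L) {
    half1 <- bip[2]; half2 <- bip[5]
    smin <- as.integer(bip[3]); smax <- as.integer(bip[4])
    if (smin > smax) {
      stop("spacer bounds reversed in ", spec, ": {", smin, ",", smax, "}")
    }
  } else if (grepl("[{}]", spec)) {
    stop("malformed spacer braces in pattern: ", spec)
  } else {
    if (grepl(paste0("[^", syms, "]"), toupper(spec))) {
      stop("non-IUPAC characters in pattern: ", spec)
    }
    half1 <- toupper(spec); half2 <- ""
    smin <- 0L; smax <- 0L
  }
  structure(list(half1 = toupper(half1), half2 = toupper(half2),
                 spacer_min = smin, spacer_max = smax, spec = spec),
            class = "IUPACPattern")
}

#' @export
print.IUPACPattern <- function(x, ...) {
  cat("IUPACPattern:", x$half1,
      if (nzchar(x$half2)) sprintf("N{%d,%d} %s", x$spacer_min, x$spacer_max,
                                   x$half2) else "", "\n")
  invisible(x)
}

#' Total motif length for a given spacer
#' @param pattern An `IUPACPattern`.
#' @keywords internal
pattern_halves_width <- function(pattern) {
  nchar(pattern$half1) + nchar(pattern$half2)
}

# Map a sequence to base indices 1..5 (A,C,G,T,N); anything unexpected is
# treated like N, i.e. never satisfies a pattern symbol.
.base_index <- function(seq) {
  lk <- rep(5L, 128L)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("C")] <- 2L
  lk[utf8ToInt("G")] <- 3L; lk[utf8ToInt("T")] <- 4L
  codes <- utf8ToInt(toupper(seq))
  codes[codes < 1L | codes > 128L] <- utf8ToInt("N")
  lk[codes]
}

# Logical vector over start positions 1..(L-k+1): does the half-site `half`
# (IUPAC, length k) hold symbol-wise at each start?
.half_mask <- function(base_idx, half) {
  k <- nchar(half)
  L <- length(base_idx)
  n <- L - k + 1L
  if (n < 1L) return(logical(0))
  syms <- strsplit(half, "")[[1]]
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    ok <- ok & unname(.IUPAC_MATCH[syms[j], ])[base_idx[j:(j + n - 1L)]]
  }
  ok
}

#' Scan one sequence for a bipartite IUPAC pattern
#'
#' Exact, forward-strand, case-insensitive matching.  Every `(start, spacer)`
#' combination where the first half-site holds at `start` and the second at
#' `start + h1 + spacer` is reported, so overlapping matches and multiple
#' spacer variants at the same start all appear.  Genomic `N` never satisfies
#' a half-site symbol; spacer positions are unconstrained.
#'
#' @param seq A nucleotide string.
#' @param pattern An `IUPACPattern` from [compile_pattern()].
#' @param collapse `"none"` (default) reports all spacer variants;
#'   `"longest"` keeps only the largest spacer per start position.
#' @return A data.frame with columns `start`, `end` (1-based inclusive),
#'   `spacer`, `strand` (always `"+"`), `sequence`, sorted by `(start, end)`.
#' @examples
#' p <- compile_pattern()
#' scan_sequence("AGACATGTCTAGACATGTCC", p)
#' @export
scan_sequence <- function(seq, pattern, collapse = c("none", "longest")) {
  collapse <- match.arg(collapse)
  stopifnot(inherits(pattern, "IUPACPattern"))
  empty <- data.frame(start = integer(0), end = integer(0),
                      spacer = integer(0), strand = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (!nzchar(seq)) return(empty)
  h1 <- nchar(pattern$half1); h2 <- nchar(pattern$half2)
  bi <- .base_index(seq)
  L <- length(bi)
  ok1 <- .half_mask(bi, pattern$half1)
  if (h2 == 0L) {
    starts <- which(ok1)
    spacers <- rep(0L, length(starts))
  } else {
    ok2 <- .half_mask(bi, pattern$half2)
    starts <- integer(0); spacers <- integer(0)
    for (s in pattern$spacer_min:pattern$spacer_max) {
      nmax <- L - (h1 + h2 + s) + 1L
      if (nmax < 1L) next
      hit <- which(ok1[seq_len(nmax)] & ok2[seq_len(nmax) + h1 + s])
      starts <- c(starts, hit)
      spacers <- c(spacers, rep(s, length(hit)))
    }
  }
  if (length(starts) == 0L) return(empty)
  ends <- starts + h1 + spacers + h2 - 1L
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]; spacers <- spacers[o]
  if (collapse == "longest") {
    keep <- !duplicated(starts, fromLast = TRUE)  # largest end per start
    starts <- starts[keep]; ends <- ends[keep]; spacers <- spacers[keep]
  }
  data.frame(start = starts, end = ends, spacer = spacers,
             strand = "+", sequence = substring(seq, starts, ends),
             stringsAsFactors = FALSE)
}

#' Scan a whole genome for a bipartite IUPAC pattern
#'
#' Per-chromosome [scan_sequence()] on the forward strand only.  The
#' degenerate half-site `RRRCWWGYYY` is self-reverse-complementary and the
#' spacer is unconstrained, so the pattern class is strand-symmetric and a
#' minus-strand pass would only double-count; all matches are labelled `+`.
#'
#' @param g A `Genome`.
#' @param pattern An `IUPACPattern`; default is the canonical p53 RE pattern.
#' @param collapse See [scan_sequence()].
#' @return A `MatchSet`: list with `matches` (data.frame: `chrom`, `start`,
#'   `end`, `spacer`, `strand`, `sequence`; coordinates 1-based inclusive,
#'   sorted by chromosome then position), `pattern`, and `genome_length`.
#' @export
scan_genome <- function(g, pattern = compile_pattern(),
                        collapse = c("none", "longest")) {
  collapse <- match.arg(collapse)
  stopifnot(inherits(g, "Genome"))
  per <- lapply(names(g), function(id) {
    m <- scan_sequence(unclass(g)[[id]], pattern, collapse = collapse)
    if (nrow(m) > 0L) cbind(chrom = id, m, stringsAsFactors = FALSE)
    else cbind(chrom = character(0), m)
  })
  matches <- if (length(per)) {
    do.call(rbind, c(per, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(matches)) {
    matches <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), spacer = integer(0),
                          strand = character(0), sequence = character(0),
                          stringsAsFactors = FALSE)
  }
  # duplicates are impossible by construction; keep the safeguard cheap
  matches <- matches[!duplicated(matches[c("chrom", "start", "end")]), ,
                     drop = FALSE]
  rownames(matches) <- NULL
  structure(list(matches = matches, pattern = pattern,
                 genome_length = genome_length(g)),
            class = "MatchSet")
}

#' @export
print.MatchSet <- function(x, ...) {
  cat("MatchSet:", nrow(x$matches), "match(es) of", x$pattern$spec,
      "in", format(x$genome_length, big.mark = ","), "bp\n")
  if (nrow(x$matches) > 0L) print(utils::head(x$matches))
  invisible(x)
}

#' Spacer length from printed 1-based inclusive coordinates
#'
#' Recovers the spacer of a bipartite match from its genomic interval:
#' `spacer = (end - start + 1) - h1 - h2`.  Useful for reading published
#' coordinate tables back into the pattern model.
#'
#' @param start,end 1-based inclusive interval bounds (vectorized).
#' @param pattern An `IUPACPattern`.
#' @return Integer vector of spacer lengths.
#' @examples
#' infer_spacer(30761068, 30761101, compile_pattern())  # 14
#' @export
infer_spacer <- function(start, end, pattern = compile_pattern()) {
  stopifnot(all(end >= start))
  w <- pattern_halves_width(pattern)
  sp <- (end - start + 1) - w
  if (any(sp < 0)) {
    stop("interval shorter than the two half-sites (", w, " bp)")
  }
  as.integer(sp)
}

#' Write a MatchSet as TSV (1-based inclusive coordinates)
#'
#' @param ms A `MatchSet` (or its `matches` data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(ms, path) {
  m <- if (inherits(ms, "MatchSet")) ms$matches else ms
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a match TSV written by [write_matches_tsv()]
#'
#' @param path TSV path.
#' @param pattern The `IUPACPattern` the matches came from.
#' @param genome_length Total genome length (for density statistics); `NA` if
#'   unknown.
#' @return A `MatchSet`.
#' @export
read_matches_tsv <- function(path, pattern = compile_pattern(),
                             genome_length = NA_real_) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(chrom = "character",
                                        sequence = "character",
                                        strand = "character"),
                         stringsAsFactors = FALSE)
  structure(list(matches = m, pattern = pattern,
                 genome_length = genome_length), class = "MatchSet")
}

#' Export matches as BED6 (0-based half-open)
#'
#' The score column carries the spacer length, noted in a header comment.
#'
#' @param ms A `MatchSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(ms, path) {
  m <- ms$matches
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6; score column holds the spacer length (bp)", con)
  if (nrow(m) > 0L) {
    bed <- data.frame(m$chrom, m$start - 1L, m$end,
                      sprintf("%s:%d-%d", m$chrom, m$start, m$end),
                      m$spacer, m$strand)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
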