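# Genome container and FASTA I/O.

#' Construct a genome from named sequences
#'
#' @param seqs Named character vector (or list) of nucleotide sequences over
#'   A/C/G/T/N and lowercase (soft-masked) variants; names are
#'   chromosome/contig ids.
#' @return A `Genome` object: a named character vector with class `Genome`.
#' @examples
#' g <- genome(c(chr1 = "ACGTACGT", chr2 = "NNNNACGT"))
#' genome_length(g)
#' @export
genome <- function(seqs = character(0)) {
  seqs <- unlist(as.list(seqs))
  if (length(seqs) == 0) seqs <- character(0)
  storage.mode(seqs) <- "character"
  ids <- names(seqs)
  if (length(seqs) > 0 && (is.null(ids) || any(!nzchar(ids)))) {
    stop("every sequence needs a non-empty name")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(seqs, class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome:", length(x), "sequence(s),", genome_length(x), "bp total\n")
  for (id in utils::head(names(x), 10L)) {
    cat(sprintf("  %s  %d bp\n", id, nchar(x[[id]])))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Total genome length in bases
#'
#' @param g A `Genome`.
#' @return Sum of sequence lengths (double, to avoid integer overflow on
#'   gigabase genomes).
#' @export
genome_length <- function(g) {
  if (length(g) == 0) return(0)
  sum(as.numeric(nchar(unclass(g))))
}

#' Per-sequence lengths
#'
#' @param g A `Genome`.
#' @return Named integer vector of sequence lengths.
#' @export
genome_seqlengths <- function(g) {
  vapply(unclass(g), nchar, integer(1))
}

#' Read a (multi-)FASTA file into a Genome
#'
#' Wrapped and unwrapped records are both accepted; case is preserved so that
#' soft-masked regions remain identifiable (the scanner itself is
#' case-insensitive).  The record id is the first whitespace-delimited token
#' of the header.  An empty file yields an empty `Genome`.
#'
#' @param path Path to a FASTA file.
#' @return A `Genome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines)))) return(genome())
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "[ \t]+"), `[`, character(1), 1L)
  genome(seqs)
}

#' Write a Genome to FASTA
#'
#' @param g A `Genome`.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  ss <- Biostrings::BStringSet(unclass(g))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
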