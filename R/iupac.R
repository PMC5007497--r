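# IUPAC nucleotide alphabet: degenerate symbols, complements, and the
# symbol/base compatibility relation used by the exact pattern scanner.

.IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"),           # purine
  Y = c("C", "T"),           # pyrimidine
  W = c("A", "T"),
  S = c("C", "G"),
  K = c("G", "T"),
  M = c("A", "C"),
  B = c("C", "G", "T"),
  D = c("A", "G", "T"),
  H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", W = "W", S = "S",
  K = "M", M = "K", B = "V", V = "B",
  D = "H", H = "D", N = "N"
)

# symbol x base logical matrix; columns A,C,G,T,N.  A genomic N (assembly gap)
# satisfies no pattern symbol, not even pattern N: gaps must never be reported
# as part of a half-site.  Spacer positions are unconstrained by construction
# (the scanner never tests them), so gaps are still allowed inside spacers.
.IUPAC_MATCH <- local({
  syms <- names(.IUPAC_BASES)
  m <- matrix(FALSE, nrow = length(syms), ncol = 5,
              dimnames = list(syms, c("A", "C", "G", "T", "N")))
  for (s in syms) m[s, .IUPAC_BASES[[s]]] <- TRUE
  m
})

#' IUPAC symbol table
#'
#' The degenerate nucleotide alphabet used throughout the package: each symbol
#' names a set of unambiguous bases (e.g. `R` = purine = A/G, `Y` = pyrimidine
#' = C/T, `W` = A/T, `N` = any).
#'
#' @return Named list mapping each IUPAC symbol to its base set.
#' @examples
#' iupac_table()$R
#' @export
iupac_table <- function() .IUPAC_BASES

#' Complement an IUPAC symbol
#'
#' @param symbol Character vector of single IUPAC symbols.
#' @return The complementary symbol(s); an involution (`W`, `S`, `N` are
#'   self-complementary).
#' @examples
#' iupac_complement(c("A", "R", "W"))
#' @export
iupac_complement <- function(symbol) {
  out <- .IUPAC_COMPLEMENT[toupper(symbol)]
  if (anyNA(out)) {
    stop("unknown IUPAC symbol(s): ",
         paste(unique(symbol[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Does a genomic base satisfy an IUPAC pattern symbol?
#'
#' The compatibility relation the exact scanner applies position by position.
#' A genomic `N` (assembly gap) satisfies no symbol, including pattern `N`:
#' gap runs must not be reported inside a half-site.  Matching is
#' case-insensitive on both sides.
#'
#' @param symbol IUPAC symbol(s) from the pattern.
#' @param base Genome base(s): A, C, G, T or N.
#' @return Logical vector (recycled to common length).
#' @examples
#' iupac_matches("R", "A")  # TRUE: R is A or G
#' iupac_matches("W", "G")  # FALSE
#' iupac_matches("N", "N")  # FALSE: gaps never match
#' @export
iupac_matches <- function(symbol, base) {
  symbol <- toupper(symbol)
  base <- toupper(base)
  if (!all(symbol %in% rownames(.IUPAC_MATCH))) {
    stop("unknown IUPAC symbol(s): ",
         paste(unique(symbol[!symbol %in% rownames(.IUPAC_MATCH)]),
               collapse = ", "))
  }
  if (!all(base %in% colnames(.IUPAC_MATCH))) {
    stop("base must be one of A, C, G, T, N")
  }
  .IUPAC_MATCH[cbind(symbol, base)]
}

#' Reverse complement of a nucleotide or IUPAC string
#'
#' Symbol-wise complement, then reversal; an involution.  Case is preserved
#' (soft-masked lowercase stays lowercase).  The canonical half-site
#' `RRRCWWGYYY` is its own reverse complement, which is why forward-strand
#' scanning suffices for the bipartite motif.
#'
#' @param seq Character vector of IUPAC strings.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("RRRCWWGYYY")
#' reverse_complement(reverse_complement("ACGTN")) == "ACGTN"
#' @export
reverse_complement <- function(seq) {
  up <- "ACGTRYWSKMBDHVN"
  lo <- tolower(up)
  cmp <- paste(.IUPAC_COMPLEMENT[strsplit(up, "")[[1]]], collapse = "")
  bad <- grepl(paste0("[^", up, lo, "]"), seq)
  if (any(bad)) stop("non-IUPAC character in sequence")
  comp <- chartr(paste0(up, lo), paste0(cmp, tolower(cmp)), seq)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}
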