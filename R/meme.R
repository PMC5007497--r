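# MEME minimal motif format and plain-text background files.

#' Write half-site PWMs in MEME minimal motif format
#'
#' One letter-probability matrix block per PWM; `nsites` records the number
#' of sites the matrix was built from.
#'
#' @param pwms A `HalfSitePWM`, a `PWMPair`, or a named list of
#'   `HalfSitePWM`s.
#' @param path Output path.
#' @param background A `Background` for the header; defaults to the first
#'   PWM's background.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = NULL) {
  if (inherits(pwms, "HalfSitePWM")) pwms <- list(motif = pwms)
  if (inherits(pwms, "PWMPair")) {
    pwms <- list(left_halfsite = pwms$left, right_halfsite = pwms$right)
  }
  stopifnot(all(vapply(pwms, inherits, logical(1), "HalfSitePWM")))
  if (is.null(background)) background <- pwms[[1]]$background
  background <- as_background(background)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", .BASES, unclass(background)),
                     collapse = " "), ""), con)
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    nsites <- sum(p$counts[, 1])
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %g E= 0",
      p$width, nsites), con)
    writeLines(apply(p$freqs, 2, function(col) {
      paste(sprintf("%.6f", col), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' Reconstructs `HalfSitePWM` objects from the letter-probability blocks;
#' counts are recovered as `freqs * nsites` (pseudocount 0), so a write/read
#' round trip preserves frequencies to the printed precision.
#'
#' @param path MEME minimal format file.
#' @return Named list of `HalfSitePWM`s.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- uniform_background()
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1L]), "[ \t]+")[[1]]
    v <- as.numeric(toks[c(FALSE, TRUE)])
    names(v) <- toks[c(TRUE, FALSE)]
    bg <- as_background(v / sum(v))
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (i in starts) {
    nm <- strsplit(trimws(lines[i]), "[ \t]+")[[1]][2]
    j <- i + 1L
    while (j <= length(lines) && !grepl("^letter-probability", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) stop("MOTIF without letter-probability matrix")
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[j]))
    nsites <- as.numeric(sub(".*nsites= *([0-9.eE+-]+).*", "\\1", lines[j]))
    if (is.na(nsites)) nsites <- 20
    rows <- lines[(j + 1L):(j + w)]
    freqs <- t(vapply(strsplit(trimws(rows), "[ \t]+"), as.numeric,
                      numeric(4)))
    counts <- t(freqs) * nsites
    dimnames(counts) <- list(.BASES, NULL)
    freqs <- sweep(counts, 2, colSums(counts), "/")
    logodds <- log2(sweep(freqs, 1, unclass(bg), "/"))
    logodds[freqs == 0] <- .SENTINEL
    out[[nm]] <- structure(list(width = w, counts = counts, pseudocount = 0,
                                background = bg, freqs = freqs,
                                logodds = logodds), class = "HalfSitePWM")
  }
  out
}

#' Write a background model as a 4-line key=value text file
#' @param background A `Background`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(background, path) {
  background <- as_background(background)
  writeLines(sprintf("%s=%.10f", .BASES, unclass(background)), path)
  invisible(path)
}

#' Read a background model from a key=value text file
#' @param path File with lines like `A=0.25`.
#' @return A `Background`.
#' @export
read_background <- function(path) {
  lines <- grep("=", readLines(path, warn = FALSE), value = TRUE)
  kv <- strsplit(trimws(lines), "=")
  v <- as.numeric(vapply(kv, `[`, character(1), 2L))
  names(v) <- toupper(trimws(vapply(kv, `[`, character(1), 1L)))
  as_background(v / sum(v))
}
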