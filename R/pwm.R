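# Half-site position weight matrices: counts -> frequencies -> log2 odds,
# exact score p-values by dynamic-programming convolution, and PWM-based
# genome scanning with the same variable-spacer geometry as the exact scan.

.BASES <- c("A", "C", "G", "T")
.SENTINEL <- -1e9  # score of a base with zero model frequency (pseudocount 0)

#' Background nucleotide model
#'
#' @param x Named numeric vector with entries for A, C, G, T (any order).
#'   Probabilities must be positive and sum to 1 (tolerance 1e-9).
#' @return Named numeric vector in A,C,G,T order, class `Background`.
#' @examples
#' as_background(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
#' @export
as_background <- function(x) {
  if (inherits(x, "Background")) return(x)
  stopifnot(is.numeric(x), all(.BASES %in% names(x)))
  x <- x[.BASES]
  if (any(x <= 0)) stop("background probabilities must be positive")
  if (abs(sum(x) - 1) > 1e-9) stop("background probabilities must sum to 1")
  structure(x, class = "Background")
}

#' Uniform background (each base 1/4)
#' @export
uniform_background <- function() {
  as_background(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

#' Estimate background frequencies from a genome by base counting
#'
#' `N` and other ambiguous characters are ignored; counting is
#' case-insensitive.
#'
#' @param g A `Genome`.
#' @return A `Background`.
#' @export
background_from_genome <- function(g) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in unclass(g)) {
    bi <- .base_index(s)
    tab <- tabulate(bi, nbins = 5L)
    counts <- counts + tab[1:4]
  }
  if (sum(counts) == 0) stop("no unambiguous bases in genome")
  as_background(counts / sum(counts))
}

#' Build a half-site PWM from aligned, ungapped sites
#'
#' Frequencies are `(count + pseudocount) / (n + 4 * pseudocount)` per
#' position; log-odds are `log2(freq / background)`.  With pseudocount 0 a
#' zero-frequency cell gets a large negative sentinel instead of `-Inf`, so
#' scores stay orderable; any word touching such a cell is impossible under
#' the model.
#'
#' @param sites Character vector of equal-length A/C/G/T sequences.
#' @param pseudocount Per-cell pseudocount (default 0.25, i.e. one
#'   uniform-background observation spread over the four bases).
#' @param background A `Background` (default uniform).
#' @return A `HalfSitePWM`: list with `width`, `counts`, `pseudocount`,
#'   `background`, `freqs`, `logodds` (matrices are 4 x width, rows A,C,G,T).
#' @examples
#' build_pwm(c("AAACATGTTT", "GGGCTAGCCC"), pseudocount = 0.25)
#' @export
build_pwm <- function(sites, pseudocount = 0.25,
                      background = uniform_background()) {
  background <- as_background(background)
  if (length(sites) == 0L) stop("need at least one site")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites differ in width")
  if (w == 0L) stop("sites are empty strings")
  mat <- do.call(rbind, strsplit(toupper(sites), ""))
  if (!all(mat %in% .BASES)) {
    stop("sites must contain only A/C/G/T (resolve gaps and ambiguities first)")
  }
  counts <- vapply(seq_len(w), function(j) {
    tabulate(factor(mat[, j], levels = .BASES), nbins = 4L)
  }, integer(4))
  dimnames(counts) <- list(.BASES, NULL)
  n <- length(sites)
  freqs <- (counts + pseudocount) / (n + 4 * pseudocount)
  logodds <- log2(sweep(freqs, 1, unclass(background), "/"))
  logodds[freqs == 0] <- .SENTINEL
  structure(list(width = as.integer(w), counts = counts,
                 pseudocount = pseudocount, background = background,
                 freqs = freqs, logodds = logodds),
            class = "HalfSitePWM")
}

#' @export
print.HalfSitePWM <- function(x, ...) {
  cat("HalfSitePWM: width", x$width, "- consensus",
      paste(.BASES[apply(x$freqs, 2, which.max)], collapse = ""), "\n")
  invisible(x)
}

#' Pair two half-site PWMs with a spacer range
#'
#' @param left,right `HalfSitePWM` objects for the 5' and 3' decamers.
#' @param spacer_min,spacer_max Allowed spacer lengths in bp.
#' @return A `PWMPair`.
#' @export
pwm_pair <- function(left, right, spacer_min = 0L, spacer_max = 15L) {
  stopifnot(inherits(left, "HalfSitePWM"), inherits(right, "HalfSitePWM"),
            spacer_min >= 0L, spacer_max >= spacer_min)
  structure(list(left = left, right = right,
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max)),
            class = "PWMPair")
}

#' Log-odds score of a word under a half-site PWM
#'
#' Sum over positions of `logodds[base, position]`, in bits.
#'
#' @param pwm A `HalfSitePWM`.
#' @param word Character vector of A/C/G/T words of length `pwm$width`.
#' @return Numeric vector of scores in bits.
#' @examples
#' pwm <- build_pwm("ACG", pseudocount = 0)
#' score_site(pwm, "ACG")  # 6 bits under uniform background
#' @export
score_site <- function(pwm, word) {
  stopifnot(inherits(pwm, "HalfSitePWM"))
  if (any(nchar(word) != pwm$width)) {
    stop("word length must equal PWM width (", pwm$width, ")")
  }
  lo <- rbind(pwm$logodds, N = .SENTINEL)
  vapply(word, function(wd) {
    bi <- .base_index(wd)
    if (any(bi == 5L)) stop("ambiguous base in word: ", wd)
    sum(lo[cbind(bi, seq_len(pwm$width))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Maximum achievable score of a PWM or PWM pair
#'
#' @param x A `HalfSitePWM` or `PWMPair`.
#' @return Best possible log-odds score, in bits.
#' @export
max_score <- function(x) {
  if (inherits(x, "PWMPair")) return(max_score(x$left) + max_score(x$right))
  sum(apply(x$logodds, 2, max))
}

# Exact distribution of the (discretized) PWM score of a random word drawn
# from the background: per-position distributions convolved by shift-and-add.
# Sentinel cells carry their probability mass in `ninf`.
.score_distribution <- function(pwm, background = pwm$background,
                                resolution = 1e-3) {
  background <- as_background(background)
  lo <- pwm$logodds
  ninf <- 0
  # start: point mass at 0
  probs <- 1; min_int <- 0L
  for (j in seq_len(pwm$width)) {
    cell <- lo[, j]
    finite <- cell > .SENTINEL / 2
    ninf <- ninf + (1 - ninf) * sum(unclass(background)[!finite])
    if (!any(finite)) { probs <- numeric(0); break }
    sint <- as.integer(round(cell[finite] / resolution))
    p <- unclass(background)[finite]
    lo_int <- min_int + min(sint)
    hi_int <- min_int + length(probs) - 1L + max(sint)
    out <- numeric(hi_int - lo_int + 1L)
    for (k in seq_along(sint)) {
      off <- (min_int + sint[k]) - lo_int
      idx <- seq_along(probs) + off
      out[idx] <- out[idx] + probs * p[k]
    }
    probs <- out; min_int <- lo_int
  }
  structure(list(resolution = resolution, min_int = min_int, probs = probs,
                 ninf_mass = ninf), class = "ScoreDistribution")
}

# Convolution of two independent score distributions (the combined
# half-site-pair score).  Direct shift-and-add over the shorter support.
.convolve_distributions <- function(a, b) {
  stopifnot(a$resolution == b$resolution)
  ninf <- a$ninf_mass + b$ninf_mass - a$ninf_mass * b$ninf_mass
  if (length(a$probs) == 0L || length(b$probs) == 0L) {
    return(structure(list(resolution = a$resolution, min_int = 0L,
                          probs = numeric(0), ninf_mass = 1),
                     class = "ScoreDistribution"))
  }
  if (length(a$probs) < length(b$probs)) { tmp <- a; a <- b; b <- tmp }
  out <- numeric(length(a$probs) + length(b$probs) - 1L)
  for (k in seq_along(b$probs)) {
    if (b$probs[k] == 0) next
    idx <- seq_along(a$probs) + (k - 1L)
    out[idx] <- out[idx] + a$probs * b$probs[k]
  }
  structure(list(resolution = a$resolution, min_int = a$min_int + b$min_int,
                 probs = out, ninf_mass = ninf),
            class = "ScoreDistribution")
}

# P(X >= score) under a ScoreDistribution; the sentinel/-inf mass only counts
# when the threshold itself is at (or below) the sentinel level.
.dist_pvalue <- function(dist, score) {
  vapply(score, function(s) {
    if (s <= .SENTINEL / 2) return(1)
    if (length(dist$probs) == 0L) return(0)
    t_int <- as.integer(round(s / dist$resolution))
    first <- t_int - dist$min_int + 1L
    if (first <= 1L) return(sum(dist$probs))
    if (first > length(dist$probs)) return(0)
    sum(dist$probs[first:length(dist$probs)])
  }, numeric(1))
}

#' Exact p-value of a PWM score
#'
#' `P(score of a random background word >= score)`, computed exactly by
#' dynamic-programming convolution of the per-position score distributions on
#' a discretized score grid (default 1e-3 bits).  Decreases (weakly) as the
#' score increases; any score below the achievable minimum has p-value 1 and
#' any score above the maximum has p-value 0.
#'
#' @param pwm A `HalfSitePWM` or `PWMPair` (for a pair the combined-score
#'   distribution is the convolution of the two half distributions; the
#'   spacer contributes no score).
#' @param background A `Background`; defaults to the PWM's own.
#' @param score Numeric vector of scores in bits.
#' @param resolution Score grid, bits.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
score_pvalue <- function(pwm, score, background = NULL, resolution = 1e-3) {
  dist <- score_distribution(pwm, background, resolution)
  .dist_pvalue(dist, score)
}

#' Exact background score distribution of a PWM or pair
#'
#' @inheritParams score_pvalue
#' @return A `ScoreDistribution` (resolution, integer-grid support,
#'   probabilities, and the probability mass of model-impossible words).
#' @export
score_distribution <- function(pwm, background = NULL, resolution = 1e-3) {
  if (inherits(pwm, "PWMPair")) {
    bgl <- if (is.null(background)) pwm$left$background else background
    bgr <- if (is.null(background)) pwm$right$background else background
    return(.convolve_distributions(
      .score_distribution(pwm$left, bgl, resolution),
      .score_distribution(pwm$right, bgr, resolution)))
  }
  stopifnot(inherits(pwm, "HalfSitePWM"))
  bg <- if (is.null(background)) pwm$background else background
  .score_distribution(pwm, bg, resolution)
}

#' E-value of a site given its p-value and the number of candidates scored
#'
#' The expected number of sites in a random candidate set of the same size
#' scoring at least as well: `pvalue * n_candidates`.
#'
#' @param pvalue Numeric vector of p-values.
#' @param n_candidates Number of candidates scored.
#' @return Numeric vector of E-values.
#' @export
site_evalue <- function(pvalue, n_candidates) {
  stopifnot(n_candidates >= 0)
  pvalue * n_candidates
}

# per-position half-site scores along a sequence: numeric vector over starts
# 1..(L-w+1); positions touching N (or other ambiguity) get the sentinel.
.half_scores <- function(base_idx, pwm) {
  w <- pwm$width
  n <- length(base_idx) - w + 1L
  if (n < 1L) return(numeric(0))
  lo <- rbind(pwm$logodds, N = .SENTINEL)
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + lo[cbind(base_idx[j:(j + n - 1L)], j)]
  }
  sc
}

#' PWM scan of a genome with variable spacer
#'
#' For every position and spacer in range, the combined score is
#' `score_site(left, first decamer) + score_site(right, second decamer)`; the
#' spacer itself is unconstrained and unscored.  Sites reaching `min_score`
#' are reported with the exact p-value of their combined score and an E-value
#' against the number of (position, spacer) candidates scanned.  Forward
#' strand only, like [scan_genome()].
#'
#' @param g A `Genome`.
#' @param pair A `PWMPair`.
#' @param background A `Background`; defaults to the PWMs' own.
#' @param min_score Reporting threshold in bits; default 80% of the maximum
#'   achievable combined score.
#' @param resolution p-value score grid, bits.
#' @return Data.frame of scored sites (`chrom`, `start`, `end`, `spacer`,
#'   `strand`, `sequence`, `score`, `pvalue`, `evalue`) sorted by decreasing
#'   score, with attribute `n_scanned` (candidates scored).
#' @export
pwm_scan <- function(g, pair, background = NULL, min_score = NULL,
                     resolution = 1e-3) {
  stopifnot(inherits(g, "Genome"), inherits(pair, "PWMPair"))
  if (is.null(min_score)) min_score <- 0.8 * max_score(pair)
  w1 <- pair$left$width; w2 <- pair$right$width
  rows <- list(); n_scanned <- 0
  for (id in names(g)) {
    seq <- unclass(g)[[id]]
    bi <- .base_index(seq)
    L <- length(bi)
    sl <- .half_scores(bi, pair$left)
    sr <- .half_scores(bi, pair$right)
    for (s in pair$spacer_min:pair$spacer_max) {
      nmax <- L - (w1 + w2 + s) + 1L
      if (nmax < 1L) next
      n_scanned <- n_scanned + nmax
      comb <- sl[seq_len(nmax)] + sr[seq_len(nmax) + w1 + s]
      hit <- which(comb >= min_score)
      if (length(hit) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = id, start = hit, end = hit + w1 + s + w2 - 1L,
        spacer = s, strand = "+",
        sequence = substring(seq, hit, hit + w1 + s + w2 - 1L),
        score = comb[hit], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), spacer = integer(0),
                         strand = character(0), sequence = character(0),
                         score = numeric(0), stringsAsFactors = FALSE)
  dist <- score_distribution(pair, background, resolution)
  out$pvalue <- .dist_pvalue(dist, out$score)
  out$evalue <- site_evalue(out$pvalue, n_scanned)
  out <- out[order(-out$score, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scanned") <- n_scanned
  out
}
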