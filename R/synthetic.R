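# Synthetic genomes with planted motifs, toy gene models and repeat
# intervals: known ground truth for every other module, at desk scale.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' All randomness in the generators flows from `seed`; identical configs give
#' byte-identical outputs.
#'
#' @param seed Integer seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome, bp.
#' @param background Base composition of the i.i.d. background.
#' @param n_planted Number of motif instances written over the background.
#' @param spacer_probs Named numeric vector mapping spacer length to
#'   probability; default uniform over the pattern's spacer range.
#' @param planting `"consensus_sample"` draws each planted site uniformly
#'   from the degenerate consensus; `"pwm_sample"` draws half-sites from
#'   `pwm_pair` column frequencies.
#' @param pwm_pair A `PWMPair`, required for `planting = "pwm_sample"`.
#' @param n_genes Number of toy gene models.
#' @param repeat_fraction Approximate fraction of the genome covered by toy
#'   repeat intervals.
#' @param pattern The `IUPACPattern` being planted.
#' @return A `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 5e5,
                              background = uniform_background(),
                              n_planted = 25L, spacer_probs = NULL,
                              planting = c("consensus_sample", "pwm_sample"),
                              pwm_pair = NULL, n_genes = 50L,
                              repeat_fraction = 0.2,
                              pattern = compile_pattern()) {
  planting <- match.arg(planting)
  background <- as_background(background)
  if (is.null(spacer_probs)) {
    sp <- pattern$spacer_min:pattern$spacer_max
    spacer_probs <- stats::setNames(rep(1 / length(sp), length(sp)), sp)
  }
  if (abs(sum(spacer_probs) - 1) > 1e-9) {
    stop("spacer probabilities must sum to 1")
  }
  if (planting == "pwm_sample" && is.null(pwm_pair)) {
    stop("pwm_sample planting needs a pwm_pair")
  }
  stopifnot(repeat_fraction >= 0, repeat_fraction < 1)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 background = background, n_planted = as.integer(n_planted),
                 spacer_probs = spacer_probs, planting = planting,
                 pwm_pair = pwm_pair, n_genes = as.integer(n_genes),
                 repeat_fraction = repeat_fraction, pattern = pattern),
            class = "SimulationConfig")
}

#' Sample a sequence matching a bipartite IUPAC pattern
#'
#' Each degenerate half-site symbol is resolved uniformly over its base set;
#' spacer bases are uniform over A/C/G/T.  The result always satisfies the
#' pattern.  Uses the current RNG state.
#'
#' @param pattern An `IUPACPattern`.
#' @param spacer Spacer length within the pattern's bounds.
#' @return A single sequence of length `h1 + spacer + h2`.
#' @export
sample_from_pattern <- function(pattern, spacer) {
  stopifnot(spacer >= pattern$spacer_min, spacer <= pattern$spacer_max)
  draw <- function(sym) {
    set <- .IUPAC_BASES[[sym]]
    set[sample.int(length(set), 1L)]
  }
  h1 <- vapply(strsplit(pattern$half1, "")[[1]], draw, character(1))
  sp <- sample(.BASES, spacer, replace = TRUE)
  h2 <- if (nzchar(pattern$half2)) {
    vapply(strsplit(pattern$half2, "")[[1]], draw, character(1))
  } else character(0)
  paste(c(h1, sp, h2), collapse = "")
}

#' Sample a site from a half-site PWM pair
#'
#' Each half-site base is drawn from the PWM's column frequencies; spacer
#' bases are uniform over A/C/G/T.  Uses the current RNG state.
#'
#' @param pair A `PWMPair`.
#' @param spacer Spacer length within the pair's bounds.
#' @return A single sequence of length `w1 + spacer + w2`.
#' @export
sample_from_pwms <- function(pair, spacer) {
  stopifnot(spacer >= pair$spacer_min, spacer <= pair$spacer_max)
  draw_pwm <- function(p) {
    paste(vapply(seq_len(p$width), function(j) {
      sample(.BASES, 1L, prob = p$freqs[, j])
    }, character(1)), collapse = "")
  }
  paste0(draw_pwm(pair$left),
         paste(sample(.BASES, spacer, replace = TRUE), collapse = ""),
         draw_pwm(pair$right))
}

#' Analytic expected match count of a pattern in an i.i.d. background
#'
#' `sum over spacers s and valid positions of p(half1) * p(half2)` where
#' `p(half) = prod over positions of sum of background probabilities of the
#' symbol's base set`; edge effects are handled exactly (a chromosome
#' contributes `L - (h1 + h2 + s) + 1` positions for spacer `s`).
#'
#' @param length Chromosome length(s) in bp (vector = one entry per
#'   chromosome).
#' @param background A `Background`.
#' @param pattern An `IUPACPattern`.
#' @return Expected number of matches (double).
#' @export
expected_match_count <- function(length, background = uniform_background(),
                                 pattern = compile_pattern()) {
  background <- as_background(background)
  p_half <- function(half) {
    if (!nzchar(half)) return(1)
    prod(vapply(strsplit(half, "")[[1]], function(sym) {
      sum(unclass(background)[.IUPAC_BASES[[sym]]])
    }, numeric(1)))
  }
  p12 <- p_half(pattern$half1) * p_half(pattern$half2)
  w <- pattern_halves_width(pattern)
  total <- 0
  for (L in length) {
    for (s in pattern$spacer_min:pattern$spacer_max) {
      total <- total + max(0, L - (w + s) + 1) * p12
    }
  }
  total
}

#' Generate a background genome with planted motif instances
#'
#' Chromosome sequences are i.i.d. draws from the configured background;
#' planted sites are written over the background at recorded positions that
#' avoid each other and the chromosome edges by `h1 + spacer_max + h2` bp.
#' Deterministic given `config$seed`.
#'
#' @param config A `SimulationConfig`.
#' @return List with `genome` (a `Genome`) and `truth` (data.frame `chrom`,
#'   `start`, `end`, `spacer`, `sequence`; 1-based inclusive).
#' @export
gen_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .with_seed(config$seed, {
    pat <- config$pattern
    buffer <- pattern_halves_width(pat) + pat$spacer_max
    seqs <- lapply(seq_len(config$n_chroms), function(i) {
      sample(.BASES, config$chrom_length, replace = TRUE,
             prob = unclass(config$background))
    })
    names(seqs) <- sprintf("chr%d", seq_len(config$n_chroms))
    truth <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), spacer = integer(0),
                        sequence = character(0), stringsAsFactors = FALSE)
    if (config$n_planted > 0L) {
      chrom_of <- sort(sample.int(config$n_chroms, config$n_planted,
                                  replace = TRUE))
      occupied <- rep(list(data.frame(start = integer(0), end = integer(0))),
                      config$n_chroms)
      spacer_vals <- as.integer(names(config$spacer_probs))
      for (k in seq_len(config$n_planted)) {
        ci <- chrom_of[k]
        sp <- spacer_vals[sample.int(length(spacer_vals), 1L,
                                     prob = config$spacer_probs)]
        site <- if (config$planting == "consensus_sample") {
          sample_from_pattern(pat, sp)
        } else {
          sample_from_pwms(config$pwm_pair, sp)
        }
        len <- nchar(site)
        placed <- FALSE
        for (try in seq_len(1000L)) {
          start <- sample.int(config$chrom_length - len - 2L * buffer,
                              1L) + buffer
          end <- start + len - 1L
          occ <- occupied[[ci]]
          if (nrow(occ) == 0L ||
              all(pmax(start - buffer, occ$start) >
                    pmin(end + buffer, occ$end))) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("planting density too high: could not place site ", k,
               " without overlap")
        }
        occupied[[ci]] <- rbind(occupied[[ci]],
                                data.frame(start = start, end = end))
        seqs[[ci]][start:end] <- strsplit(site, "")[[1]]
        truth <- rbind(truth, data.frame(
          chrom = names(seqs)[ci], start = start, end = end, spacer = sp,
          sequence = site, stringsAsFactors = FALSE))
      }
      truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
      rownames(truth) <- NULL
    }
    g <- genome(vapply(seqs, paste, character(1), collapse = ""))
    list(genome = g, truth = truth)
  })
}

#' Generate toy gene models over a genome
#'
#' Non-overlapping genes with random strand, one transcript each, 2-8 exons
#' and a 5'UTR on the strandwise-first exon; valid GFF3 via [write_gff3()].
#' Deterministic given `seed`.
#'
#' @param g A `Genome` to place genes on.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param biotypes Biotype labels sampled per gene (default 95%
#'   protein_coding / 5% miRNA, echoing a vertebrate gene set).
#' @return A `GeneAnnotation`.
#' @export
gen_gene_models <- function(g, n_genes, seed = 1L,
                            biotypes = c(protein_coding = 0.95,
                                         miRNA = 0.05)) {
  lens <- genome_seqlengths(g)
  empty <- function(cols) {
    stats::setNames(data.frame(character(0), integer(0), integer(0),
                               stringsAsFactors = FALSE), cols)
  }
  feat_cols <- c("transcript_id", "start", "end")
  ann <- list(genes = data.frame(gene_id = character(0), symbol = character(0),
                                 biotype = character(0), chrom = character(0),
                                 strand = character(0), start = integer(0),
                                 end = integer(0), stringsAsFactors = FALSE),
              transcripts = data.frame(transcript_id = character(0),
                                       gene_id = character(0),
                                       chrom = character(0),
                                       strand = character(0),
                                       start = integer(0), end = integer(0),
                                       tss = integer(0),
                                       stringsAsFactors = FALSE),
              exons = empty(feat_cols), utr5 = empty(feat_cols),
              utr3 = empty(feat_cols), cds = empty(feat_cols))
  if (n_genes == 0L) return(structure(ann, class = "GeneAnnotation"))
  .with_seed(seed, {
    occupied <- rep(list(data.frame(start = integer(0), end = integer(0))),
                    length(lens))
    for (i in seq_len(n_genes)) {
      span <- sample(2000:10000, 1L)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        ci <- sample.int(length(lens), 1L)
        if (lens[ci] < span + 2L) next
        start <- sample.int(lens[ci] - span - 1L, 1L) + 1L
        end <- start + span - 1L
        occ <- occupied[[ci]]
        if (nrow(occ) == 0L ||
            all(pmax(start, occ$start) > pmin(end, occ$end))) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place gene ", i, " without overlap")
      occupied[[ci]] <- rbind(occupied[[ci]],
                              data.frame(start = start, end = end))
      strand <- sample(c("+", "-"), 1L)
      biotype <- sample(names(biotypes), 1L, prob = biotypes)
      gid <- sprintf("gene%03d", i)
      tid <- sprintf("tx%03d", i)
      n_exons <- sample(2:8, 1L)
      # interior breakpoints define alternating exon/intron blocks
      inner <- sort(sample(seq(start + 100L, end - 100L, by = 10L),
                           2L * (n_exons - 1L)))
      bounds <- matrix(c(start, inner, end), ncol = 2L, byrow = TRUE)
      exons <- data.frame(transcript_id = tid, start = bounds[, 1],
                          end = bounds[, 2], stringsAsFactors = FALSE)
      first_exon <- if (strand == "+") 1L else n_exons
      utr_len <- min(50L, exons$end[first_exon] - exons$start[first_exon])
      utr5 <- if (strand == "+") {
        data.frame(transcript_id = tid, start = exons$start[1],
                   end = exons$start[1] + utr_len - 1L,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(transcript_id = tid,
                   start = exons$end[n_exons] - utr_len + 1L,
                   end = exons$end[n_exons], stringsAsFactors = FALSE)
      }
      ann$genes <- rbind(ann$genes, data.frame(
        gene_id = gid, symbol = gid, biotype = biotype,
        chrom = names(lens)[ci], strand = strand, start = start, end = end,
        stringsAsFactors = FALSE))
      ann$transcripts <- rbind(ann$transcripts, data.frame(
        transcript_id = tid, gene_id = gid, chrom = names(lens)[ci],
        strand = strand, start = start, end = end,
        tss = if (strand == "-") end else start, stringsAsFactors = FALSE))
      ann$exons <- rbind(ann$exons, exons)
      ann$utr5 <- rbind(ann$utr5, utr5)
    }
    structure(ann, class = "GeneAnnotation")
  })
}

#' Generate toy repeat intervals covering a target genome fraction
#'
#' Non-overlapping intervals are drawn until each chromosome reaches the
#' target coverage; family labels are sampled from the given distribution
#' (labels only, not sequence models).  Deterministic given `seed`.
#'
#' @param g A `Genome`.
#' @param fraction Target covered fraction per chromosome.
#' @param seed Integer seed.
#' @param families Named probability vector of family labels.
#' @return Data.frame `chrom`, `start`, `end` (1-based inclusive), `family`.
#' @export
gen_repeats <- function(g, fraction = 0.2, seed = 1L,
                        families = c("hAT-AC" = 0.30, "DNA" = 0.14,
                                     "TE-X-4_DR" = 0.14, "LINE" = 0.21,
                                     "LTR" = 0.21)) {
  stopifnot(fraction >= 0, fraction < 1)
  lens <- genome_seqlengths(g)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), family = character(0),
                    stringsAsFactors = FALSE)
  if (fraction == 0) return(out)
  .with_seed(seed, {
    for (ci in seq_along(lens)) {
      L <- lens[ci]
      covered <- 0L
      occ <- data.frame(start = integer(0), end = integer(0))
      tries <- 0L
      while (covered < fraction * L && tries < 10000L) {
        tries <- tries + 1L
        len <- sample(500:3000, 1L)
        if (L <= len + 1L) break
        start <- sample.int(L - len, 1L)
        end <- start + len - 1L
        if (nrow(occ) > 0L &&
            any(pmax(start, occ$start) <= pmin(end, occ$end))) next
        occ <- rbind(occ, data.frame(start = start, end = end))
        covered <- covered + len
        out <- rbind(out, data.frame(
          chrom = names(lens)[ci], start = start, end = end,
          family = sample(names(families), 1L, prob = families),
          stringsAsFactors = FALSE))
      }
    }
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write repeat intervals as BED (0-based half-open, family in name column)
#' @param repeats Data.frame from [gen_repeats()] or [read_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeats_bed <- function(repeats, path) {
  bed <- data.frame(repeats$chrom, repeats$start - 1L, repeats$end,
                    repeats$family)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture to a directory
#'
#' FASTA genome, GFF3 gene models, truth BED of planted sites, repeats BED
#' and a JSON manifest (config plus md5 checksums of every file).
#'
#' @param config A `SimulationConfig`.
#' @param dir Output directory (created if needed).
#' @return List with the generated objects and `manifest` path, invisibly.
#' @export
write_fixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- gen_genome(config)
  ann <- gen_gene_models(sim$genome, config$n_genes, seed = config$seed + 1L)
  reps <- gen_repeats(sim$genome, config$repeat_fraction,
                      seed = config$seed + 2L)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gff3 = file.path(dir, "genes.gff3"),
                truth = file.path(dir, "planted.bed"),
                repeats = file.path(dir, "repeats.bed"),
                manifest = file.path(dir, "manifest.json"))
  write_fasta(sim$genome, paths$fasta)
  write_gff3(ann, paths$gff3)
  truth_bed <- data.frame(sim$truth$chrom, sim$truth$start - 1L,
                          sim$truth$end, sim$truth$sequence,
                          sim$truth$spacer, "+")
  utils::write.table(truth_bed, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_repeats_bed(reps, paths$repeats)
  cfg <- config
  cfg$background <- as.list(unclass(cfg$background))
  cfg$pattern <- cfg$pattern$spec
  cfg$pwm_pair <- if (is.null(cfg$pwm_pair)) NULL else "custom"
  manifest <- list(
    config = unclass(cfg),
    checksums = as.list(tools::md5sum(unlist(paths[names(paths) !=
                                                     "manifest"]))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(genome = sim$genome, truth = sim$truth, annotation = ann,
                 repeats = reps, paths = paths))
}
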