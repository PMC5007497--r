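# p53re

Discovery and annotation of p53 response elements (REs) in genome sequence,
and nomination of candidate p53 target genes.

## The problem

p53 regulates its targets through a bipartite DNA response element: two
decameric half-sites of the degenerate consensus

```
RRRCWWGYYY N{0,15} RRRCWWGYYY
```

(R = purine, Y = pyrimidine, W = A/T), separated by an unconstrained spacer
of 0–15 bp, with the `RCWWGY` core — in particular the invariant C and G at
half-site positions 4 and 7 — carrying the protein contacts. Cataloguing
every occurrence of this motif in a genome, placing each occurrence in its
gene context (±5 kb, TSS distance, gene region, strand, repeat overlap), and
then using a handful of experimentally validated REs to seed a
PWM-based similarity re-search is a standard route to new candidate target
genes in a non-mammalian model organism. `p53re` implements that whole
computational pipeline as a reusable R package:

* **Exact degenerate scanning** of the bipartite motif with variable spacer
  (`compile_pattern`, `scan_sequence`, `scan_genome`), forward strand only —
  the degenerate pattern class is self-reverse-complementary, so a
  minus-strand pass would only double-count.
* **Half-site PWMs** (`build_pwm`, `pwm_pair`, `pwm_scan`) with log2-odds
  scoring, *exact* score p-values by dynamic-programming convolution on a
  1e-3-bit grid (`score_pvalue`), and E-values `p × n` (`site_evalue`).
* **Gene-context annotation** (`load_annotation`, `associate_genes`,
  `classify_region`, `repeat_overlap`) and the standard summary roll-up
  (`summarize_matches`): totals, gene multiplicity, orientation, region
  composition, repeat overlap, spacer histogram, density per Mb.
* **PWM-seeded similarity search** (`align_res`, `build_halfsite_pwms`,
  `rank_candidates`, `consensus_candidates`, `pwm_robustness`): rank
  candidates by MAST-like E-value (cutoff 10) and matrix-scan-like p-value
  (α = 0.05), intersect the significant sets, and measure robustness to the
  seed RE set.
* **Prioritization bookkeeping** (`filter_candidates`, `join_orthologs`,
  `merge_rankings`) around external ranking tools, whose TSV outputs are
  consumed, never recomputed.
* **A synthetic-data module** (`simulation_config`, `gen_genome`,
  `gen_gene_models`, `gen_repeats`, `expected_match_count`) that generates
  seeded genomes with planted motifs, toy gene models and repeat intervals,
  so the entire pipeline is testable at desk scale with known truth.

File formats: FASTA in/out, GFF3/GTF annotation, BED and RepeatMasker `.out`
repeats, MEME minimal motif format for PWMs, plain TSV everywhere else.
A subcommand CLI (`run_cli`, shipped as `inst/scripts/p53re`) wires the
modules into `simulate / scan / annotate / summarize / pwm-build / pwm-scan /
simsearch / prioritize`, each run writing a JSON manifest.

## Worked example

```r
library(p53re)

## simulate a 1 Mb two-chromosome genome with 25 planted REs, 60 genes, repeats
cfg <- simulation_config(seed = 3, n_chroms = 2, chrom_length = 5e5,
                         n_planted = 25, n_genes = 60, repeat_fraction = 0.2)
sim  <- gen_genome(cfg)
ann  <- gen_gene_models(sim$genome, cfg$n_genes, seed = 4)
reps <- gen_repeats(sim$genome, cfg$repeat_fraction, seed = 5)

## scan for the canonical bipartite motif
ms <- scan_genome(sim$genome, compile_pattern("RRRCWWGYYYN{0,15}RRRCWWGYYY"))
ms
#> MatchSet: 27 match(es) of RRRCWWGYYYN{0,15}RRRCWWGYYY in 1e+06 bp
#>   chrom  start    end spacer strand                          sequence
#> 1  chr1   3158   3180      3      +           GAACTAGCTTCTAGGACATGCCT
#> 2  chr1  28293  28313      1      +             AAACTAGTTTTAAACATGTCC
#> ...
```

The 25 planted sites are all among the 27 matches (the other two are chance
hits of the degenerate motif — a 1 Mb uniform background expects about one
per Mb). Annotation and the summary:

```r
stats <- summarize_matches(associate_genes(ms, ann, window = 5000), ms,
                           repeat_overlap(ms, reps))
stats
#> General features of the scanned patterns
#>   Number of patterns                            27
#>   Number of gene-related patterns               19
#>   Number of unique gene-related patterns        9
#>   Patterns proximal to more than one gene       10
#>   Genes (grouped by biotype)                    24 protein_coding
#>   ...
#>   Pattern density                               27.00 per Mb
```

A match is *gene-related* when it overlaps a gene's ±5 kb neighbourhood;
one match near several genes contributes one annotation per gene, which is
why unique + multi-gene = gene-related. Seed PWMs from validated REs and
re-rank candidates:

```r
vs <- read.table(system.file("extdata", "validated_sites_zv9.tsv",
                             package = "p53re"),
                 header = TRUE, sep = "\t", comment.char = "#")
(spacers <- infer_spacer(vs$start, vs$end))
#>  [1] 14  2  0 11 13 12  0  1  2  6

set.seed(6)
res_seqs <- vapply(spacers, function(s)
  sample_from_pattern(compile_pattern(), s), character(1))
pair <- build_halfsite_pwms(align_res(res_seqs, spacers))

cand <- setNames(ms$matches$sequence[1:20], sprintf("m%02d", 1:20))
ranking <- rank_candidates(cand, pair)   # E-value + p-value gates
ranking
#> CandidateRanking: 20 candidates; 20 pass E<=10, 20 pass p<0.05, 20 consensus
head(ranking$table[c("id", "score", "pvalue", "evalue", "in_consensus")], 3)
#>    id    score       pvalue       evalue in_consensus
#> 1 m03 23.91907 4.768481e-09 9.536961e-08         TRUE
#> 2 m07 23.31793 7.634299e-09 1.526860e-07         TRUE
#> 3 m04 23.15739 9.868927e-09 1.973785e-07         TRUE
```

All twenty candidates pass both gates here because every one is a true
match of the degenerate pattern; on a mixed pool (see the test suite) the
consensus set separates pattern-derived candidates from background
sequences. The ten validated-site coordinates shipped in
`inst/extdata/validated_sites_zv9.tsv` are 1-based inclusive genomic
intervals; the underlying RE *sequences* are not redistributed, so the
example samples synthetic stand-ins from the consensus with the real
spacers.

The same workflow from a shell:

```sh
Rscript inst/scripts/p53re simulate --seed 3 --out-dir fx
Rscript inst/scripts/p53re scan --fasta fx/genome.fa --out matches.tsv
Rscript inst/scripts/p53re summarize --matches matches.tsv \
    --gff3 fx/genes.gff3 --fasta fx/genome.fa --repeats fx/repeats.bed \
    --out summary.tsv --hist spacers.tsv
```

## Scope notes

Wet-lab validation, pathway analysis, live Ensembl/Biomart or expression-
database queries, and the internals of external prioritization tools are
out of scope; the package consumes their tabular outputs. Approximate
matching with mismatches and minus-strand reporting are deliberate
non-goals (see the methods vignette in `vignettes/` for the rationale and
the full list of modelling decisions).
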