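---
title: "Scanning a genome for p53 response elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning a genome for p53 response elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53re)
```

## The binding-site model

The tumour suppressor p53 binds DNA as a tetramer at a bipartite response
element (RE): two decameric half-sites of the degenerate consensus
`RRRCWWGYYY` (R = purine, Y = pyrimidine, W = A/T) separated by an
unconstrained spacer of 0–15 bp. Crystallography places the protein–DNA
contacts on the central `RCWWGY` hexamer, so the C at half-site position 4
and the G at position 7 are effectively invariant while the flanks tolerate
substitution. `p53re` treats this motif in two complementary ways:

* **Exact degenerate matching** (`compile_pattern()`, `scan_sequence()`,
  `scan_genome()`): a position matches iff every half-site symbol is
  compatible with the genomic base. All `(start, spacer)` combinations are
  reported, so nested spacer variants at one start are distinct matches
  (a `collapse = "longest"` mode keeps only the widest variant per start).
* **Probabilistic scoring** (`build_pwm()`, `pwm_scan()`,
  `rank_candidates()`): one position weight matrix per decamer, scored in
  log~2~ odds ("bits") against an i.i.d. background; the spacer contributes
  no score, mirroring the unconstrained `N` run of the exact pattern.

Two conventions are worth stating up front. First, scanning is
**forward-strand only**: `RRRCWWGYYY` is its own reverse complement as a
degenerate class and the spacer is symmetric, so a minus-strand pass would
report every site a second time at mirrored coordinates. All matches carry
strand `+`, and "strand concordance" with a gene therefore reduces to the
gene lying on `+` — an explicit caveat written into the annotated output
headers. Second, a genomic `N` (assembly gap) satisfies **no** pattern
symbol, not even pattern `N`; spacer positions, which the scanner never
tests, may contain anything. This keeps gap runs from fabricating
half-sites while leaving genuine flanking half-sites usable. Soft-masked
(lowercase) sequence is scanned like any other: repeat-embedded sites are a
documented and substantial fraction of genome-wide hits, so repeats are
annotated rather than excluded.

## Coordinates

Internally everything is 1-based inclusive, the native convention of the
IRanges/GenomicRanges stack this package is built on. Tabular output is
likewise 1-based inclusive; BED export converts to 0-based half-open and
carries the spacer length in the score column. `infer_spacer()` recovers the
spacer of a published interval as `(end - start + 1) - 20`.

## Exact p-values by convolution

A PWM score's p-value is the probability that a random background word
scores at least as high. Scores are discretized to a grid (default
`resolution = 1e-3` bits, configurable) and the per-position score
distributions are convolved exactly by dynamic programming; the pair
distribution is the convolution of the two half distributions, because the
unscored spacer makes the halves independent under the i.i.d. background.
The discretization bounds the p-value error by construction and keeps the
DP table small; at width 5 the DP reproduces brute-force enumeration over
all 4^5 words to floating-point precision (this is asserted in the test
suite). p-values are monotone non-increasing in score, `p = 1` at or below
the minimum achievable score and `p = 0` above the maximum.

With `pseudocount = 0` a base absent from the training sites has model
frequency zero. Its log-odds cell is set to a large negative sentinel
(−10^9^) rather than −∞ so that sums of scores remain orderable; any word
touching such a cell is "impossible under the model" and its probability
mass is tracked separately in the score distribution. The default
pseudocount is 0.25 per cell — one uniform-background pseudo-observation
spread over the four bases — which keeps every log-odds finite.

## From validated sites to new candidates

The similarity re-search starts from a set of validated REs with assorted
spacers. `align_res()` lays them out in a fixed frame of width
`20 + max(spacer)`: half-site 1 left-justified in columns 1–10, half-site 2
right-justified in the last 10 columns, spacer immediately after the first
half-site, gaps filling the remainder. The two half-site blocks are
gap-free by construction, so `build_halfsite_pwms()` can take columns 1–10
and the last 10 columns directly; gap and spacer columns never enter the
counts. (With a maximum spacer of 14 the frame is 34 columns wide and the
second block occupies columns 25–34; the frame width follows the pattern's
spacer bounds, so it is configurable.)

Candidates are then scored **end-anchored**: an RE-sized candidate (length
between 20 and 20 + max spacer) has exactly one placement that uses the
whole sequence — first decamer at the 5′ end, second at the 3′ end, spacer
inferred from the length — and that placement is scored. Longer sequences
are scanned over all placements and the best reported. Two significance
calls follow:

* **E-value ranking** (MAST-like): `E = p × n` with `n` the number of
  candidates scored, retained at `E ≤ 10` (default), sorted ascending with
  ties broken by candidate id;
* **p-value gate** (matrix-scan-like): retained at `p < 0.05` (default),
  uncorrected — the conventional per-site gate for this kind of screen; a
  Benjamini–Hochberg flag exists but is off by default.

The **consensus** set is their intersection, ordered by E-value rank.
`pwm_robustness()` rebuilds the PWM pair from alternative seed sets and
reports the overlap of each seed set's significant sets with the first —
the generalized form of checking how stable the candidate list is to the
choice of seed REs.

## Gene context and the summary roll-up

A match is *gene-related* iff it overlaps `[gene_start − w, gene_end + w]`
with `w = 5000` bp by default. The window anchors on the **gene span**, not
the TSS alone, because functional REs occur deep inside introns and would
be lost by a TSS-centred window. A match inside several windows yields one annotation per gene.
Region labels are assigned against a **representative transcript** (the
longest; ties broken by lexicographically smallest transcript id — the
choice is not biologically canonical, but it is deterministic and stated)
with precedence `5′UTR > exon > intron > upstream > downstream`. "Promoter"
and "upstream" are deliberately collapsed into a single `upstream` label
(≤ w bp 5′ of the TSS): a separate promoter window would add an arbitrary
extra cutoff without changing any downstream decision. TSS
distances are measured from the match edge nearest the TSS, signed along
the gene strand (negative = upstream, 0 = spanning).

`summarize_matches()` produces the standard roll-up: totals, gene-related
and multi-gene counts (which must satisfy
`unique + multi = gene_related`), genes by biotype, orientation counts,
the region composition of same-orientation patterns (one representative
gene per pattern, first by gene id), repeat overlap (≥ 1 bp intersection;
partial overlaps count), the spacer histogram and the per-Mb density.
A schema test enforces that the full set of roll-up fields stays stable.

## Prioritization

`filter_candidates()` applies deterministic, order-preserving gates
(allowed regions — default upstream/5′UTR, the canonical RE locations;
maximum |TSS distance|; strand concordance; minimum patterns per gene).
`join_orthologs()` keeps one homology type from a user-supplied table
(default `one2one`, the type most likely to preserve function across
species) and errors on conflicting duplicate assignments.
`merge_rankings()` takes the top-k (default 50) of each external ranking
TSV and returns the union with provenance. The external prioritization
tools themselves, and the manual curation that followed them, are
deliberately out of scope: the package emits the filtered pool with
provenance columns for human review.

## The synthetic-data module

`simulation_config()` + `gen_genome()`, `gen_gene_models()` and
`gen_repeats()` generate desk-scale fixtures with known truth: an i.i.d.
order-0 background with configurable base frequencies (the same background
class the p-value machinery uses; a Markov-1 background would be an
extension, not the default), planted motif instances drawn either
uniformly from the degenerate consensus or from a PWM pair, toy gene
models (one transcript, 2–8 exons, 5′UTR on the strandwise-first exon,
random strand), and repeat **intervals** with family labels. Planted sites
avoid each other and chromosome edges by `h1 + max spacer + h2` bp, which
keeps truth bookkeeping exact. Everything is reproducible bit-for-bit from
the seed.

What the simulator does *not* emulate matters for interpreting green
tests: real repeat sequences (families here are labels on intervals, so
repeat-overlap fractions follow coverage by construction rather than from
sequence content), isochore/GC structure, conservation, chromatin, and the
long-tailed gene-length and exon-count distributions of a real vertebrate
annotation. Passing the planted-recovery and analytic-count checks
demonstrates that the algorithms are correct and internally consistent —
not that any particular biological hit list is right. Genome-scale counts
on a real assembly additionally depend on the assembly, annotation release
and repeat library used.

`expected_match_count()` provides the analytic oracle for scan tests:
under an i.i.d. background the expected hit count is
`sum over spacers and valid positions of p(half1) p(half2)` with
`p(half) = prod over positions of P(base in symbol set)`. For the
canonical pattern under a uniform background `p(half) = (1/2)^8 (1/4)^2 =
1/4096`, so 10 Mb expects about 9.5 matches — the observed count on a
pinned-seed uniform fixture is asserted to lie within the 3σ Poisson band.

## Numerical and statistical choices

* Log base 2 throughout; comparability with external PWM scanners is at
  the level of rank order (base-invariant), not raw scores, since their
  internal scaling is not reproduced.
* Score grid 10^−3^ bits; sentinel −10^9^ for zero-frequency cells.
* Ties: ranking ties by candidate id; representative-transcript ties by
  transcript id; duplicate (chrom, start, end) matches are impossible by
  construction and deduplication is a no-op safeguard.
* Degenerate inputs: empty genome → empty match set; zero matches → all-zero
  summary; `alpha = 0` → empty significant set; reversed spacer bounds,
  non-IUPAC symbols, width mismatches and conflicting one2one rows are
  errors.
* The test suite checks the 500-site PWM-recovery experiment with exact
  binomial bounds at a Šidák-adjusted per-cell level, so the **family** of
  80 simultaneous cell checks has 3σ coverage; a per-cell normal 3σ band
  would false-fail roughly one run in five by construction and the normal
  approximation is poor for pseudocount-only cells.
* Test problem sizes are the package's own desk-scale choices: 1 kb × 100
  sequences for oracle equivalence, a 1 Mb planted fixture for recovery
  and summary equality, 10 Mb for the analytic count, width-5 enumeration
  for p-values, 500 samples for parameter recovery, a 100-candidate pool
  for the similarity search.

## Known limitations

The exact scanner is linear in genome length times pattern width and
spacer count — ample for desk scale and a single vertebrate genome, but it
makes no attempt at the suffix-automaton tricks a multi-genome screen
would want. Approximate matching with mismatches is out of scope (the
exact-match catalogue is the object of study). PWM scanning reports all
supra-threshold sites without merging overlapping placements. The
annotation model assumes a well-formed gene → transcript → exon hierarchy;
orphan features are skipped with a warning rather than repaired.
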