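---
title: "Inferring sigma-54 regulons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sigma-54 regulons: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rponscan)
```

# The biological problem

σ⁵⁴ (RpoN) directs RNA polymerase to a bipartite promoter whose −24 and −12
elements (`TGGCAC` and `TGC`, 5–7 nt apart) are unusually well conserved, and
it transcribes nothing without an enhancer-binding protein (EBP) that
hydrolyses ATP to open the closed complex. Both halves of this system leave
strong sequence signatures — the promoter elements on DNA, and a conserved
ten-motif architecture with an invariant `GAFTGA` hexapeptide in the EBPs —
which makes the regulon unusually tractable for comparative sequence
analysis. `rponscan` packages that analysis: promoter discovery per taxonomic
class, operon-level regulon assembly, COG enrichment, EBP classification, and
an RpoN domain census.

This vignette explains the models, every tunable that matters, what the
synthetic-data generator does and does not emulate, and the design decisions
that were genuinely open.

# The promoter model and its scan statistics

A motif is a position weight matrix (PWM): per-column letter probabilities
with a pseudocount (0.25 per nucleotide; `0.01 ×` background per amino acid),
scored in bits as log₂-odds against an order-0 background. Scores convert to
p-values by exact dynamic-programming convolution of the per-column score
distributions on a grid of 100 bins per bit. Two numerical consequences are
worth knowing:

* the p-value of a score is exact *up to the grid*: per-column rounding can
  shift a score by up to `width/2` bins, so agreement with brute-force window
  enumeration is asserted within that bracket (the test suite does exactly
  this);
* scanning uses the order-0 stationary background even when sequence was
  emitted from an order-1 chain; this keeps the convolution exact and is the
  common approximation in motif scanners.

A scan keeps the best-scoring window per upstream region (one promoter per
transcription unit) and converts the p-value to an E-value by a per-scan
Bonferroni factor — the total number of scorable windows in the scanned set.
This approximates the database-wide E-value of alignment-search tools;
per-scan totals are reported in the hit-table attribute so the conversion is
auditable. Windows containing letters outside the alphabet (e.g. `N`) are
non-scorable and skipped.

The iterative search runs five pattern-finding / pattern-discovery cycles per
class: cycle 1 scans with the seed matrix; each later cycle re-estimates the
PWM from the previous cycle's hit windows by EM and rescans. Two discovered
motifs are extracted per cycle and the one whose consensus scores highest
against the *original* seed matrix is kept — this anchors the cycle against
drifting to a co-occurring non-σ⁵⁴ motif, a failure mode the iteration is
otherwise prone to. The cycle stops early, keeping the previous matrix, when
fewer than `min_hits = 10` sites are found: a PWM re-estimated from fewer
sites is too unstable to rescan with.

E-value cutoffs of 0.625, 1.25, 2.5 and 5 are evaluated and the one
maximising gene-level Matthews correlation (operon-expanded predictions
against the benchmark regulon, all genes of the benchmark genomes as the
universe) is selected; ties break toward the smaller cutoff, and MCC is
defined as 0 whenever a denominator factor vanishes.

# ZOOPS EM with model selection

Motif discovery uses the zero-or-one-occurrence-per-sequence likelihood: a
sequence either contains one motif window (prior λ, uniform over windows) or
is pure background. The E-step computes per-window occupancy posteriors; the
M-step re-estimates the PWM (with pseudocount) and λ. Starts are seeded from
over-represented anchor words (6-mers for DNA, 4-mers for proteins) aligned
at every admissible in-window offset — the offset sweep matters, because an
anchor placed mid-window otherwise converges to a shifted register of the
motif. Candidates are screened by one-iteration likelihood and EM runs to
convergence (relative log-likelihood change < 1e-6, at most 200 iterations;
non-convergence returns the best iterate with a flag) from the best screened
starts. The log likelihood is non-decreasing across iterations and the test
suite asserts this on every traced run.

Maximum-likelihood ZOOPS has a known pathology on pure noise: EM assembles a
family of coincidentally similar windows and reports a non-trivial λ. The
package therefore applies a BIC-style acceptance bound: the motif's
likelihood gain over the no-motif model must exceed
`((|A|−1)·w + 1)/2 · ln(total windows)`; otherwise the motif is reported with
λ = 0 and flagged non-significant. On background-only input this drives the
occurrence prior to zero, while planted signals exceed the bound by an order
of magnitude. Additional motifs are found after MEME-style probabilistic
erasure (per-position weights `1 − z` multiplied into subsequent window
likelihoods), which degrades gracefully when motifs overlap, unlike hard
masking.

# Operons, enrichment and its discreteness

Transcription units are predicted by a two-rule heuristic: adjacent
same-strand genes join when the intergenic distance is ≤ 45 nt, or ≤ 4 × 45
nt with a functional-link score ≥ 0.7 (overlapping genes count as distance
0). A neural-network predictor over the same two inputs exists in the
literature, but its weights are not reproducible from published material;
the declared heuristic exposes the same two inputs and is exactly testable.

Enrichment is the upper-tail hypergeometric probability per (class, COG)
pair, computed in log space via `stats::phyper`: N and K are per class by
default (a global-population mode is a flag, since "the entire gene pool"
can be read either way), genes with no COG label count in N but in no K, and
k counts operon-expanded genes, not operons. Raw p-values are what the
figures of record use; Benjamini–Hochberg within class is emitted alongside
because the analysis tests thousands of pairs.

One subtlety the tests make explicit: hypergeometric p-values are discrete.
Under a true null the fraction of pairs with p < 0.05 sits *below* 0.05 by
the local atom size, and with small K and n no achievable p-value may be
near 0.05 at all. The null-calibration tests therefore (a) use the
randomised probability integral transform, which is exactly uniform, for a
KS check, and (b) compare the raw fraction below 0.05 to the exact
Poisson-binomial expectation computed from each pair's (N, K, n) — with
class sizes chosen large enough (N ≈ 1200, K ≈ 100) that the expectation is
near 5% rather than degenerate.

# The EBP classifier

The six steps run in a fixed order: (1) PF00158 pre-filter at E ≤ 1e-51
(skippable, and logged, for purely synthetic runs without domain tables);
(2) greedy clustering at 60% identity — identity is defined as matching
positions of the best ungapped offset alignment divided by the shorter
length, with a shared-3-mer pre-screen; this is a reproducible, dependency-
free analogue of standard redundancy reduction and keeps the threshold
semantics; (3) EM discovery of ten width-12 motifs; (4) proteome scan at
per-protein E ≤ 0.1; (5) exact `GAFTGA` substring filter, anywhere in the
sequence (the hexapeptide is invariant, so no substitutions are tolerated);
(6) conserved-order verification: all ten best-hit positions must realise
the expected left-to-right permutation, strictly increasing, best hit per
motif being the lowest p-value with leftmost tie-break.

Because discovered motifs are numbered by likelihood rank — not by any fixed
catalogue — the expected order is re-derived empirically as the modal motif
order across the positive set (`ebp_reference_order()`); the canonical
architecture permutation in truth-motif numbering is exported as
`sigma54_ebp_motif_order`. The verdict is monotone by construction: removing
any single motif hit, or swapping any two, flips a bona fide call, and the
test suite checks this exhaustively.

# What the synthetic generator emulates — and what it does not

The generator plants exactly the structure the analysis assumes: background
sequence from an order-0 or order-1 chain at a chosen GC content; genes on
both strands grouped into operons (sizes 1–4 with probabilities 0.45 / 0.25 /
0.18 / 0.12, within-operon gaps 0–40 nt, between-unit gaps 130–400 nt, so the
within/between distributions do not overlap the 45-nt joining rule); a
promoter planted upstream of the leader of a `promoter_rate` fraction of
transcription units, 8–60 nt upstream of the start so it falls inside any
reasonable scan window; COG labels assigned independently of regulation
except for planted (class, COG) pairs, whose labels concentrate in regulated
genes; and EBP positives assembled from ten motif instances in architecture
order with random linkers, against decoys with `GAFTGA` rejected at
construction (rejection, not masking, preserves the decoy length
distribution). All randomness flows from one integer seed per spec, and
identical specs yield byte-identical output.

The ground-truth promoter PWM deserves its own paragraph, because it is the
study condition behind the parameter-recovery tests. The consensus used is
`TGGCACG` + spacer + `TTGCT` — the core boxes with their conserved flanking
letters, 12 conserved columns at 0.95 consensus probability, uniform spacer
columns, fixed 6-nt spacing between `TGGCAC` and `TGC` by default (5–7
optionally, which measurably lowers sensitivity against a fixed-spacer seed —
the mechanism behind false negatives at non-canonical promoters). The choice
is a power calculation, made before any test was run: scanning ~100,000
windows at E-value cutoffs up to 5 requires per-window p ≈ 5·10⁻⁵, i.e.
~14 bits of discrimination. A 9-column core at 85% conservation carries ~10
bits and caps achievable sensitivity at 0.23 — no pipeline could recover such
a regulon at MCC ≥ 0.9, and curated σ⁵⁴ alignments do conserve the longer
core at high per-position identity. With the 12-column/0.95 truth the exact
binomial calculation gives sensitivity 0.98 at cutoff 5, which the pipeline
attains.

What the generator does *not* emulate: codon structure or any coding signal
(genes are background sequence with coordinates), phylogenetic correlation
between genomes, COG frequency skew, promoter context (UP-elements, EBP
binding sites), or multi-promoter transcription units. Passing recovery
tests therefore demonstrate that the machinery is correct and calibrated on
data satisfying its assumptions — not that real-genome accuracy matches; on
real genomes, benchmark MCC against curated regulons is known to be far
lower, dominated by non-canonical promoters.

# Problem sizes and runtime

The shipped tests run the pipeline at deliberately modest scale: calibration
on one synthetic class of ~270 transcription units (2 genomes × 295 genes),
EM recovery on ~170 regions, EBP training on 60 positives, specificity on
10,000 decoys, and 20 seeded replicates of the enrichment rank-recovery
experiment. These sizes give each statistic comfortable margin (binomial
standard errors well inside the asserted bands) while keeping a full run in
minutes on a single core; all of them are plain parameters of the specs and
scale up directly.

# Known limitations

* The E-value is a per-scan Bonferroni approximation, not the QFAST
  multi-motif combined statistic; multi-motif evidence is used only through
  the per-motif presence/order logic of the EBP branch.
* Score p-values assume the order-0 background; strongly autocorrelated
  genomes will make them slightly liberal.
* The operon heuristic ignores transcription-factor context and expression
  data; its two thresholds are exposed but not learned.
* `consensus()` reports ties by alphabet order; downstream string matching on
  consensus sequences should treat spacer columns as arbitrary.
* Clustering identity is ungapped; highly divergent EBPs with indels inside
  motif cores would cluster less than CD-HIT would, which only makes the
  discovery set more redundant, never smaller.
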