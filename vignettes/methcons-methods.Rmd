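---
title: "Methods: cross-species conservation of tissue-specific methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species conservation of tissue-specific methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methcons)
```

# The problem and the model

DNA methylation at CpG dinucleotides is bimodal in mammalian genomes: most
CpGs are heavily methylated, while regulatory regions active in a given
tissue are locally hypomethylated in that tissue. `methcons` operationalizes
"tissue-specific regulatory region" as a **tsDMR**: a fixed 500-bp genomic
window whose mean CpG methylation is low in exactly one of three tissues and
high in the other two. The comparative question — is the *pattern* (not the
sequence) conserved across species? — is answered by mapping each window to
orthologous coordinates in two other genomes and re-evaluating the same
categorical pattern there.

The pipeline is deliberately categorical. Methylation state is discretized
into unmethylated (0), intermediate (1), methylated (2) with thresholds 0.3
and 0.7, and conservation is defined on states, not on level differences.
This makes every call reproducible, robust to modest level noise, and
directly comparable across assays with different dynamic ranges
(methylCRF-style predictions vs. WGBS ratios). The cost is resolution near
the thresholds; see *Numerical choices*.

## tsDMR calling

Windows are left-aligned 500-bp tiles per contig (trailing partial windows
dropped, so every window has identical length). For a candidate target
tissue with window mean $\bar m_t$ and the two other tissues
$\bar m_{o_1}, \bar m_{o_2}$:

* criterion 1 (hypo vs non-hypo): $\bar m_t < 0.3$ and both
  $\bar m_{o_i} \ge 0.3$;
* criterion 2 (intermediate vs hyper): $0.3 \le \bar m_t \le 0.7$ and both
  $\bar m_{o_i} > 0.7$.

The criteria are mutually exclusive across target tissues, so per-tissue
call sets are disjoint by construction (asserted at run time). An optional
per-window q-value from an upstream differential-methylation caller gates
calls at $q < 10^{-5}$; when q-values are absent the score criteria alone
define tsDMRs, which keeps the pipeline self-contained. Only hypomethylated
tsDMRs are called; hypermethylated ones are out of scope. Both criteria are
retained and flagged in the output (`criterion` column) so either subset
can be tabulated separately — whether intermediate windows belong in
headline totals is a reporting decision, not a calling decision.

## Orthology mapping

Coordinate mapping uses UCSC chain files. Three rules define "has an
ortholog":

1. **single best chain** — among chains whose target span overlaps the
   window, the highest-scoring one is chosen (ties: lowest chain id). This
   mirrors score-greedy liftover deterministically; split mapping across
   several chains is not attempted.
2. **coverage** — at least 50% of the window's bases must lie in aligned
   blocks of that chain (boundary inclusive: exactly 50% maps).
3. **span** — the target-side envelope (smallest interval containing all
   mapped bases, on forward-strand coordinates) may span at most 1000 bp.

Negative-strand query chains are normalized to forward-strand coordinates
at parse time; one internal convention prevents sign errors, and the
original fields are kept for round-trip writing. Failing any rule yields an
"unmapped" result, never an error.

Three-way orthologs reconcile two paths into the third species: the direct
image and the image composed through the middle species must overlap by at
least 90%. The overlap denominator is the **shorter** of the two intervals —
a symmetric choice, lenient in the intended regime where the two images are
near-identical; rearranged segments produce disjoint images and fail
cleanly.

## Conservation calls

An ortholog is classified only if it contains at least one CpG in every
tissue track of the comparison species (otherwise `NO_CPG`; windows with no
ortholog are `NO_ORTHOLOG`). With target-tissue state $s_t$ and other-tissue
states $s_{o_1}, s_{o_2}$:

$$\mathrm{EC} \iff (s_t = 0 \wedge s_{o_1}, s_{o_2} \in \{1,2\}) \vee
(s_t = 1 \wedge s_{o_1} = s_{o_2} = 2),$$

else ENC. Percentages in conservation tables keep **all** tsDMRs in the
denominator (regions lost to `NO_ORTHOLOG`/`NO_CPG` count against
conservation), rounded to the nearest integer percent.

Enrichment of EC among tsDMRs is tested against a random-region background
classified by the same machinery, with an upper-tail hypergeometric test.
The urn is the pooled set: population $N = n_{bg} + n_{tsDMR}$, successes
$K = EC_{bg} + EC_{obs}$, draws $n = n_{tsDMR}$, p-value
$P[X \ge EC_{obs}]$. The sampling scheme determines the test only up to the
urn construction; this pooled parameterization makes the test exact under
the stated resampling and is the package's fixed choice.

## Genetic conservation and the score-bin curve

A tsDMR is genetically conserved when ≥ 20% of its bases (inclusive) overlap
a conserved-element track. The quantitative curve divides each 500-bp window
into ten 50-bp subwindows, maps each through the same liftover rules (the
50%/1000-bp thresholds are reused rather than inventing subwindow-specific
ones), averages the comparison species' per-base conservation score over the
orthologous bases, sorts subwindows by mean score (ties broken by genomic
order, making the binning deterministic), and partitions them into equal-
sized bins — a remainder is assigned one-per-bin starting from the lowest
bins. Each bin reports its EC fraction.

Whether EC should be evaluated per subwindow or inherited from the parent
window is genuinely ambiguous; the package implements **subwindow-level EC
as the default** (each 50-bp ortholog is classified on its own CpGs;
CpG-free subwindows are dropped, mirroring the classifier's CpG rule) and
offers `level = "parent"` to inherit the parent window's call. At desk
scale the two agree closely because conservation status is coherent within
a window.

## Enrichment statistics

Feature labels follow the strict >50% coverage rule. Because promoter, CGI,
UTR, exon and repeat tracks overlap, more than one label can exceed 50%;
a fixed precedence (promoter > CGI > 5'UTR > exon > 3'UTR > TE > intron,
configurable) makes labeling deterministic. Windows with no qualifying
label are `intergenic` outside gene loci and `other` inside. Matched
backgrounds sample uniformly without replacement within each label stratum
(or GC-content bin of width 0.05 for motif backgrounds), deterministically
for a given seed. All 2×2 tests are Pearson χ² without continuity
correction — the intended regime is large counts, and the uncorrected
statistic matches the closed form $n(ad-bc)^2/(r_1 r_2 c_1 c_2)$ exactly,
which is what the test suite asserts. Multiple testing uses
Benjamini–Hochberg throughout. Histone-mark overlap requires the peak
*summit* to fall inside the (half-open) region — a peak merely overlapping
the region does not count. Signal profiles average track density in 50-bp
bins over ±5 kb around window midpoints, with data-free bases contributing
zero.

## Motif scanning and turnover

Consensus matching is exact under IUPAC classes (Hamming distance 0): every
sequence base must satisfy its consensus position, `N` in the sequence never
matches a non-`N` consensus position, and both strands are scanned. This
matches how binding-site case analyses reason ("a single substitution
destroyed the motif"); an optional PWM mode scores log-odds against a
threshold expressed as a fraction (default 0.8) of the maximum achievable
score. For an ortholog pair, each source hit is mapped through the chains
(≥ 50% of the hit's bases); the pair is `CONSERVED_IN_PLACE` if any mapped
hit shares ≥ 1 bp with a destination hit, else `TURNOVER` when both regions
have hits, `LOSS`/`GAIN` when only one does, `ABSENT_BOTH` otherwise. The
1-bp overlap requirement is the most permissive "in place" definition;
stricter offsets can be imposed downstream. Known-motif lists are supplied
by the user; de-novo discovery is out of scope.

# The synthetic world

The generator states one fixed world (all values configurable, none tuned
to test outcomes):

* **genomes** — 2 contigs × 1 Mb per species; comparison genomes derive
  from the reference by a block-evolution walk: ancestral blocks of mean
  1 kb are retained with probability 0.9 per species (blocks holding a
  planted tsDMR use a joint scheme: both species with probability
  `p_ortholog_retained`, otherwise exactly one — so three-way recovery
  estimates that parameter directly), substitutions at 0.01/bp, junction
  insertions (rate 0.2, mean 50 bp). Chains are emitted for all three
  pairs and are mutually consistent by construction; optional
  rearrangements relocate whole blocks in the composed pair only.
* **methylomes** — CpGs at ~1/100 bp (windows carrying planted tsDMRs get a
  fixed grid of 10 CpGs); per-CpG levels are clipped normals around
  hypomethylated 0.1 / intermediate 0.5 / hypermethylated 0.85 with
  sd 0.05, reproducing the bimodal genome-wide distribution. 300 tsDMRs
  per tissue are planted (10% intermediate, criterion 2).
* **conservation coupling** — each retained window draws a standard-normal
  latent conservation score $z$; it is epigenetically conserved with
  probability $\mathrm{logit}^{-1}(a + b z)$ where $b$ is
  `score_coupling` (default 2) and $a$ is calibrated numerically so the
  marginal EC rate equals `p_ec` (0.3 mouse, 0.15 human). The same $z$ is
  added to the 50-bp score track over the window's image. Treating the
  coupling as a graded slope (rather than a binary EC bonus) is what makes
  the score-bin EC curve smoothly increasing rather than a tie-ridden
  step.
* **contrasts** — conserved elements cover a 250-bp core of planted windows
  at rate 0.6 (EC) vs 0.2 (ENC); peak summits fall in window images at 0.5
  vs 0.1; motifs are planted in 80% of EC vs 10% of ENC windows, with
  fates conserved/turnover/loss at 0.6/0.2/0.2 given a motif and gains at
  0.05 without one. Motif instances are written after sequence evolution
  at orthologous offsets chosen to avoid the planted CpG grid, so fates
  are exact ground truth.

**What a green test does and does not establish.** The world is
rearrangement-free by default, has one chain per contig pair, no
strand-flipped orthology (negative-strand chains are exercised by the
random-chain oracle suite instead), no non-CG methylation, no read-level
noise, cell-type homogeneity, and independent EC draws across windows.
Green recovery therefore validates the *computational* contract — calling,
mapping, classification and scoring do what they claim on data whose truth
is known — not the biological effect sizes of any real trio.

# Numerical choices

* Boundary means of exactly 0.3 or 0.7 are *intermediate* (strict
  inequalities on both sides).
* Coverage ≥ 0.5 and element overlap ≥ 0.2 are boundary-inclusive ("at
  least").
* Feature assignment is boundary-exclusive ("> 50%").
* Integer percentages use `round()`; ties at .5 follow R's rounding and do
  not occur in any published table reproduced by the tests.
* Liftover of an interval overlapping no chain, or failing a rule, is a
  result (`mapped = FALSE`), not an error; malformed files (bad
  coordinates, inconsistent chain block sums) are errors naming the line
  or chain id.
* Chain score ties break by lowest id (numeric when possible, else
  lexicographic).
* Empty strata are dropped with a warning in motif enrichment; zero
  backgrounds yield `Inf` (present only in target) or `NA` (absent in
  both) folds.
* The χ² kernel returns `NA` for tables with an empty margin.
* Region means over zero CpGs are `NA`, never 0.

# Known limitations

* Single-best-chain mapping can miss orthologs recoverable by split
  mapping; the published mappability of real genomes is not reproducible
  at desk scale and is not an acceptance quantity.
* The hypergeometric urn choice (pooled background + observed) is one of
  several defensible parameterizations; alternatives shift p-values
  slightly but not the extreme significance levels the tables show.
* Subwindow-level EC discards CpG-free 50-bp orthologs, which biases the
  curve toward CpG-dense sequence; parent-level inheritance avoids this at
  the cost of intra-window resolution.
* PWM mode approximates log-odds scanners with a fixed fraction-of-maximum
  threshold; published per-motif thresholds of known-motif libraries are
  not reproduced.
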