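# methcons

Cross-species conservation analysis of tissue-specific DNA methylation.

Tissue identity is written into the methylome: regulatory regions that are
hypomethylated in exactly one tissue (tissue-specific differentially
methylated regions, **tsDMRs**) mark enhancers and promoters active in that
tissue. `methcons` implements a comparative-epigenomics pipeline that asks,
for a reference species and two comparison species, *how often is that
tissue-specific methylation pattern conserved at orthologous loci* — and
whether the conservation is explained by DNA sequence conservation or by
conserved transcription-factor binding sites. It is aimed at computational
epigenomics groups who have per-CpG methylation tracks for matched tissues
in several species and the standard UCSC annotation stack (chain files,
genePred gene tables, conserved-element BEDs, per-base conservation-score
wigs, ChIP-seq peaks).

## What the pipeline computes

1. **tsDMR calling.** The genome is tiled into 500-bp windows. A window is a
   tsDMR for tissue *t* when its mean methylation
   m̄ = (1/n) Σᵢ mᵢ over the n CpGs in the window satisfies either
   criterion 1: m̄ₜ < 0.3 and m̄ₒ ≥ 0.3 for both other tissues, or
   criterion 2: 0.3 ≤ m̄ₜ ≤ 0.7 and m̄ₒ > 0.7 for both others —
   optionally gated by an upstream differential-methylation q-value
   (< 10⁻⁵).
2. **Orthology mapping.** Each tsDMR is mapped through UCSC chain files:
   the highest-scoring overlapping chain wins, at least 50% of the window's
   bases must fall in aligned blocks, and the target envelope may span at
   most 1000 bp. Three-way orthologs additionally require the direct image
   in species C and the image composed through species B to overlap by
   ≥ 90% of the shorter interval.
3. **Epigenetic conservation (EC/ENC).** Region means are categorized
   (unmethylated = 0 below 0.3, intermediate = 1, methylated = 2 above
   0.7, strict inequalities). An ortholog is **EC** iff its target tissue
   is state 0 with both other tissues in {1, 2}, or state 1 with both
   others at 2; otherwise **ENC**. Orthologs without CpGs are excluded.
   Enrichment over a random-region background is tested with an upper-tail
   hypergeometric probability, BH-corrected.
4. **Genetic conservation.** A tsDMR is genetically conserved when ≥ 20% of
   its bases overlap conserved elements (phastCons-style). The quantitative
   relation is measured by splitting windows into 50-bp subwindows, ranking
   their orthologs by mean conservation score (phyloP-style), partitioning
   into equal-sized bins and plotting the EC fraction per bin.
5. **Enrichment statistics.** Feature labels by the >50% rule with a fixed
   precedence, genomic-distribution-matched and GC-matched background
   sampling, nearest-TSS distances, fold enrichments with Pearson χ²
   (no continuity correction) and Benjamini–Hochberg correction, histone
   peak *summit* overlap, and 50-bp signal profiles over 10-kb windows.
6. **Motif turnover.** IUPAC-consensus (or PWM) scanning on both strands;
   per ortholog pair a motif is CONSERVED_IN_PLACE (a mapped source hit
   overlaps a destination hit), TURNOVER (hits on both sides, none in
   place), LOSS, GAIN, or ABSENT_BOTH.
7. **Synthetic benchmark.** A seeded generator emits a complete
   three-species trio — genomes related by block alignments, methylomes
   with planted tsDMRs, mutually consistent chain files, conserved
   elements, score tracks, peaks and motif fates — together with a truth
   table, so every stage can be scored (precision/recall, parameter
   recovery, contrast tests).

## Worked example

```r
library(methcons)

cfg    <- simulation_config(seed = 42, n_contigs = 1L,
                            contig_length = 300000L, n_dmrs = 60L)
bundle <- simulate_trio(cfg, file.path(tempdir(), "trio"))
pipe   <- run_trio_pipeline(bundle$dir)

table(pipe$dmrs$target_tissue)
#> blood brain sperm
#>    60    60    60

counts <- do.call(rbind, lapply(c("blood", "brain", "sperm"), function(t) {
  st <- pipe$cons_mouse$status[pipe$cons_mouse$target_tissue == t]
  data.frame(tissue = t, n_ec = sum(st == "EC"),
             n_enc = sum(st == "ENC"), n = length(st))
}))
tabulate_conservation(counts$tissue, counts$n_ec, counts$n_enc, counts$n,
                      background_ec = 2, background_n = 4000)
#>   tissue n_tsdmr n_ec n_enc percent_ec      p_value      q_value
#> 1  blood      60   19    40         32 1.465131e-34 2.197697e-34
#> 2  brain      60   18    42         30 1.275199e-32 1.275199e-32
#> 3  sperm      60   23    37         38 1.913860e-42 5.741579e-42
```

All 180 planted tsDMRs are recalled; 19/60 blood tsDMRs (32%) are
epigenetically conserved in the mouse-like genome, far above the ~0%
background EC rate of random regions (hypergeometric p ≈ 10⁻³⁴). Scoring
the whole run against the generator's truth table:

```r
rep <- recovery_report(pipe, bundle, n_bins = 10)
#> recall 1.00, EC err 0.035, threeway 0.92, turnover recall 0.96, rho 0.99
```

i.e. the estimated EC fraction is within 0.035 of the planted probability,
92% of tsDMRs are recovered as three-way orthologs (planted retention 0.9),
96% of planted motif-turnover events are called correctly, and the EC
fraction rises monotonically across conservation-score bins (Spearman
ρ = 0.99).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main result from scratch: it simulates the default
synthetic trio from the given seed, runs the full pipeline (tsDMR calling,
pairwise and three-way liftover, EC/ENC classification, genetic
conservation, score-bin curve, motif turnover), prints the recovery
metrics, and writes the JSON result object to `--out`.
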