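# cisgrammar

Integrative cistrome–transcriptome analysis for hormone-responsive plant
transcription-factor networks, with a deterministic synthetic-data
generator that makes every statistic verifiable at desk scale.

## The problem

Hypocotyl growth in Arabidopsis is steered by several hormone and light
pathways converging on a small set of transcription factors — an auxin
response factor (ARF6), the brassinosteroid effector BZR1, and the
phytochrome-interacting factor PIF4. Dissecting that convergence from
ChIP-seq and RNA-seq data requires a chain of small, precise analyses:

* **Target calling** — gene *g* is a direct target of a factor iff a peak
  summit lies in the strand-aware union
  `[TSS − 3 kb, TSS) ∪ gene body ∪ (3′ end, 3′ end + 1 kb]`.
* **Cis-element grammar** — exact-string scanning of the core AuxRE
  (`TGTC`), canonical AuxRE (`TGTCTC`), `TGTCGG`, G-box (`CACGTG`) and HUD
  (`CACATG`) within ±100 bp of summits; co-occurrence classes
  {both, AuxRE-only, E-box-only, neither}; enrichment against genomic
  background (two-sided Fisher exact); edge-to-edge E-box↔AuxRE spacing;
  association with hormone-activated targets; peak-score comparisons by
  Mann–Whitney.
* **Co-binding** — target-set overlaps with the hypergeometric expectation
  `E[|A ∩ B|] = |A|·|B| / N` and upper-tail p-value
  `P(X ≥ k), X ~ Hypergeom(N, |A|, |B|)`, plus summit-to-summit distance
  distributions on common targets, and the ChIP-qPCR ratio
  `(target_test/ref_test) / (target_ctrl/ref_ctrl)`.
* **Expression integration** — differential expression by the
  `|FC| ≥ 1.5 and p < 0.01` rule (Welch's *t* on log2 normalised counts),
  fold-change correlation between contrasts, sign-pattern co-regulation
  across three regulators, and retention of responses in a signalling
  mutant (`100 · n_retained / n_wt`).

Each layer is an exported, unit-tested function; a pipeline runner wires
them together and writes one TSV per summary panel. A synthetic-data
module generates toy genomes with planted motifs at configurable spacing,
Venn-structured multi-factor peak sets, and negative-binomial expression
bundles with planted retention, fold-change correlation and sign-pattern
mixes — every planted quantity is emitted as ground truth and recovered by
the analysis modules in the test suite.

## Worked example

```r
library(cisgrammar)

cfg <- synthetic_config(seed = 1)       # the default desk-scale world
b   <- simulate_bundle(cfg)             # genome + peaks + expression + truth

links <- assign_peaks_to_genes(b$peaks, b$genes)   # the -3kb/body/+1kb rule
tg    <- target_genes(links)
target_overlap(tg$ARF6, tg$BZR1, tg$PIF4, universe_size = 200,
               set_names = c("ARF6", "BZR1", "PIF4"))
```

```
Target-set overlap (universe N = 200 )
Set sizes: ARF6=88, BZR1=69, PIF4=78
 first second n_first n_second n_overlap pct_of_first pct_of_second expected            p
  ARF6   BZR1      88       69        50     56.81818      72.46377    30.36 3.529730e-09
  ARF6   PIF4      88       78        62     70.45455      79.48718    34.32 2.114758e-16
  BZR1   PIF4      69       78        46     66.66667      58.97436    26.91 6.953737e-09
Triple overlap:
 n_overlap pct_of_ARF6 pct_of_BZR1 pct_of_PIF4
        40    45.45455    57.97101    51.28205
```

88 of 200 genes are ARF6 targets; 50 of them (57 %) are also BZR1 targets
against a random expectation of 30.4, with p ≈ 3.5e-9 — strongly
non-random co-binding, as planted by the generator's Venn fractions.

```r
pa <- b$peaks[b$peaks$factor == "ARF6", ]
pr <- peak_motif_profiles(b$genome, pa)   # scan ±100 bp around summits
classify_cooccurrence(pr)
```

```
                class count   fraction
both             both    44 0.50000000
auxre_only auxre_only    38 0.43181818
ebox_only   ebox_only     3 0.03409091
neither       neither     3 0.03409091
```

Half of the ARF6 windows carry both a core AuxRE and an E-box — exactly
the planted class mix — and all planted E-box↔AuxRE gaps fall within
20 bp (`spacing_distribution(pr)$frac_le_20` is `1`).

```r
ex     <- simulate_expression(cfg, n_genes = 2000)
de_wt  <- call_differential(ex$counts, ex$design, "WT_BL:WT_mock")
de_mut <- call_differential(ex$counts, ex$design, "mut_BL:mut_mock")
de_gen <- call_differential(ex$counts, ex$design, "mut_mock:WT_mock")
fc_correlation(de_wt, de_gen, subset = "all")     # r = -0.59, n = 2000
response_retention(de_wt, de_mut, "up")           # 51 of 380 (13.4%)
```

The measured fold-change correlation (−0.59) recovers the planted −0.6
(slight attenuation from count noise), and 13.4 % of BL-activated genes
stay activated in the mutant against a planted retention of 17 %
(conditional on detection in both genotypes).

The orchestrated run writes all eleven report tables plus a manifest:

```r
run_pipeline(run_config(out_dir = "report", seed = 1))
```

A command-line wrapper lives at `inst/scripts/pipeline.R`
(`run`, `validate`, `simulate`, `link`, `express` subcommands, DCF config
files).

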