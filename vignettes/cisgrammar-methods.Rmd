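---
title: "Methods: cistrome-transcriptome integration with cisgrammar"
author: "cisgrammar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cistrome-transcriptome integration with cisgrammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cisgrammar` re-implements, as a tested and reusable pipeline, the style of
integrative analysis used to dissect how growth-promoting transcription
factors (an ARF-family auxin response factor, the brassinosteroid effector
BZR1, and the light-regulated bHLH PIF4) converge on a shared target-gene
network in the Arabidopsis hypocotyl. The pipeline has five analysis layers,
each an independent module with a file-level contract:

1. **Target calling** — a gene is a direct target of a factor when at least
   one binding peak summit falls in its promoter (default −3 kb from the
   TSS), its gene body, or 1 kb downstream of the 3′ end. Membership is
   judged by the summit, the best single-base estimate of the binding site;
   this keeps every peak–gene link unambiguous where "any overlap"
   conventions can straddle boundaries. Windows are half-open at the TSS
   and at the far downstream edge so no base is counted twice.
2. **Cis-element grammar** — exact-string motif scanning (core AuxRE
   `TGTC`, canonical AuxRE `TGTCTC`, variant `TGTCGG`, G-box `CACGTG`, HUD
   `CACATG`, and `GATCG` as a negative control) within ±100 bp of each
   summit; per-window co-occurrence classes (both / AuxRE-only / E-box-only
   / neither); enrichment against genome-sampled background windows
   (two-sided Fisher exact test on presence/absence); edge-to-edge spacing
   between the nearest E-box and core-AuxRE footprints; association of
   co-occurrence with hormone-activated targets; and peak-score (binding
   affinity proxy) comparisons between classes by two-sided Mann–Whitney.
3. **Co-binding** — overlap of per-factor target-gene sets with all
   pairwise and triple intersections, the hypergeometric expectation
   |A||B|/N, and an upper-tail hypergeometric p-value. The universe size N
   is an explicit, required argument: published "expected overlap" figures
   presuppose an unstated gene universe, and making N explicit surfaces
   that assumption instead of burying it in a default.
4. **Expression integration** — differential expression by the printed
   rule (≥1.5-fold and raw p < 0.01, Welch's t on log2-normalised replicate
   values), fold-change correlation between contrasts, sign-pattern
   co-regulation across three regulators, and retention of the response in
   a signalling mutant.
5. **Reporting** — a single orchestrated run that writes one TSV per
   figure-style panel plus a manifest; every number in a report table is
   produced by exactly one module call.

# Key parameter choices

| parameter | default | unit | rationale |
|---|---|---|---|
| promoter window | 3000 | bp | the target-definition rule |
| downstream window | 1000 | bp | the target-definition rule |
| scan half-width | 100 | bp | element search radius around summits |
| E-box set | G-box, HUD | — | the two E-boxes named by the analysis; generic CANNTG would change all class fractions, so the set is explicit and configurable |
| fold threshold | 1.5 | fold | printed DE rule |
| alpha | 0.01 | — | printed DE rule, raw p (no multiple-testing correction, matching the reported procedure) |
| background windows | 10× peaks | — | genome-sampled, fixed seed; stable low-variance null |
| peak FDR filter | 0.01 | — | peaks with an FDR column are kept when FDR < 0.01 |

Spacing is measured edge-to-edge between match footprints (adjacent
footprints have gap 0, overlapping footprints are clamped to 0): with
elements 4–6 bp long and biologically meaningful spacings mostly under
20 bp, edge distance is the only convention in which adjacency reads as
zero. Where one window holds several elements, the nearest pair defines
the gap.

# Differential-expression normalisation

The printed rule names a fold change and a p-value but no test; the
simplest procedure consistent with it is Welch's t on log2(normalised
count + 1) replicate values with the fold threshold applied to normalised
condition means. One deliberate deviation from naive counts-per-million was
forced by implementation experience: when a large share of genes responds
strongly in one direction (the hormone-treatment contrasts simulated here
have ~40 % responders at ~5-fold), raw library totals absorb the response
and total-count normalisation shifts every null gene's apparent log2 fold
change by the composition factor (≈0.8 log2 units in the default world) —
mass-producing spurious calls in the opposite direction. The default
normalisation is therefore median-of-ratios size factors (each library's
median ratio to the per-gene geometric mean over fully detected genes),
which anchors the null at zero as long as most genes are unchanged;
`normalization = "cpm"` restores the textbook behaviour. Rows where both
replicate groups have zero variance (exact ties, in practice only
low-count artifacts such as (0,0,0) vs (1,1,1)) get p = 1: replication
that shows no variation carries no evidence for a mean difference.

# The synthetic world

The generator exists so that every downstream statistic can be verified by
parameter recovery at desk scale. Its defaults describe one fixed world,
stated here with reasons; they are not tuning knobs.

* **Genome**: one 2-Mb contig, i.i.d. bases at GC 0.36 (Arabidopsis-like),
  200 genes of 0.8–1.5 kb on random strands with ≥4 kb clear flanks. The
  flank guarantee makes planted target links exactly recoverable (no
  window of one gene reaches another gene's peak).
* **Venn structure**: per-gene membership in the three factors' target
  sets is multinomial over the seven Venn regions plus "none", with
  default fractions chosen so the first factor's overlap percentages
  reproduce the published overlap geometry (≈51 % with factor B, ≈71 %
  with C, ≈42 % with both).
* **Peaks**: one peak per (factor, target gene); summits uniform in the
  1 kb upstream of the TSS, with co-bound factors jittered ≤100 bp around
  a shared anchor so co-bound summits sit within 200 bp, giving the
  peak-distance module signal to recover.
* **Planted grammar**: each first-factor scan window is first scrubbed of
  incidental core-AuxRE/E-box matches (a 201-bp window at GC 0.36 contains
  ~1.3 chance `TGTC` hits, which would otherwise make the "E-box-only" and
  "neither" classes unreachable), then planted according to the class
  probabilities, with the E-box↔AuxRE gap drawn uniformly from 0–20 bp.
  Scrubbing and planting overwrite bases in place, so coordinates never
  shift. Class-"both" windows plant the bare core so the planted gap is
  exactly the footprint gap the scanner measures.
* **Expression**: negative-binomial replicate counts (3 replicates,
  dispersion 0.02, log-normal baselines around 300). 40 % of genes respond
  to the hormone with signed log2 effects N(2.5, 0.5²); 17 % of responses
  are retained in the mutant; the mutant-genotype contrast's true effects
  are built by Gram–Schmidt so their sample correlation with the
  treatment-response effects is exactly −0.6. Effect-size and dispersion
  defaults come from an a-priori power analysis: Welch's t at α = 0.01
  with 3 replicates needs |log2 effect| / SE ≳ 8 for ≥80 % sensitivity, a
  condition the stated recovery invariants presuppose. Dispersion 0.02 is
  realistic for pooled-seedling biological replicates; the calibration
  tests that explicitly prescribe dispersion 0.05 use it.
* **Regulator panel**: the 0.7 concordant-opposing sign-pattern mix lives
  in a separate three-contrast bundle (two regulators agreeing, the third
  opposing, in 70 % of co-regulated genes) because the four-condition
  hormone design is already fully constrained by the retention and
  correlation parameters.

What the generator does **not** emulate: chromatin background and peak
shape (peaks are intervals with planted summits, not read pileups), linked
genes and operonic structure, realistic motif clustering outside scan
windows, isoform-level expression, and batch effects. A green recovery
test therefore establishes correctness of the statistics on their stated
inputs — not robustness to alignment or peak-calling artifacts, which are
upstream of this package's contract (peaks arrive pre-called, with their
FDR column consumed as a filter).

# Numerical and degenerate-case decisions

* All internal coordinates are 0-based half-open; GFF3's 1-based inclusive
  convention is converted only at I/O, and round-trips are exact.
* `N` bases never match any motif; palindromic patterns yield one hit per
  position; reverse-complement hits are reported at forward coordinates.
* Enrichment folds use a 0.5-count continuity correction on both the peak
  and background fractions, so motifs absent from one side stay finite.
* Fisher and Mann–Whitney tests are two-sided throughout; no
  multiple-testing correction is applied within a panel (the reported
  procedure uses raw per-test stars).
* Association with activated genes returns a defined result (p = 1 plus a
  warning flag) when a co-occurrence class is empty; score comparisons
  skip the test when a class has fewer than two peaks.
* Retention percentages are rounded to one decimal; a zero-denominator
  retention is flagged undefined rather than NaN.
* Ties for "nearest gene" in the descriptive position distribution break
  toward the lexicographically smaller gene identifier, making the
  histogram deterministic.
* Every stochastic stage draws from a sub-seed derived deterministically
  from the run seed, so identical configurations produce byte-identical
  output bundles; library code saves and restores the caller's RNG state.

# Known limitations

* The exact test behind the published "p < 0.01" DE rule is unstated
  upstream; published correlation values may therefore not be exactly
  reproducible from deposited data with any particular test choice,
  including this one.
* The published random expectation for motif co-occurrence could have been
  computed from genome-wide windows or shuffled sequence; this package
  uses genome-sampled windows.
* Whether element spacing was measured per occurrence or per window is
  unstated; the nearest pair per window is implemented.
* The hypergeometric overlap test treats gene sets as uniform draws from
  an exchangeable universe; gene-length or expression-level biases in
  target calling are not modelled.
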