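---
title: "Methods: co-occupancy, composite motifs and reporter synergy"
author: "comotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy, composite motifs and reporter synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comotif)
```

# Scope and model

`comotif` analyses how two transcription factors share cis-regulatory
modules (CRMs).  The motivating biology is the cooperation of a Gli zinc
finger factor with a bHLH factor (Hand2) in craniofacial neural crest: the
Gli factor binds a canonical Gli-binding motif (cGBM, consensus `GACCACCC`),
but at CRMs co-occupied with the bHLH factor the binding site frequently
degenerates to a low-affinity "divergent" variant (dGBM, `GACCTCCC`,
operationally any `CCTCC` core) positioned near an E-box (`CANNTG`).  The
package quantifies five aspects of this situation, each implemented as an
independent stage:

1. **Peak co-occupancy.**  Given two peak sets $A$ and $B$, the observed
   statistic is the number of $A$ peaks overlapping $B$ by at least 1 bp
   (each $A$ peak counted once).  Significance comes from a permutation
   null that relocates every $A$ peak uniformly within its own chromosome,
   preserving its length.  We report fold enrichment
   $\mathrm{obs}/\bar{x}_{null}$, a $z$ score, the empirical p-value
   $(1 + \#\{null \ge obs\})/(1 + n_{perm})$ and the upper normal tail at
   $z$.  The normal tail is reported because genuinely extreme enrichments
   are far beyond any feasible Monte-Carlo floor; the JSON output labels the
   two p-values distinctly.  The null is deliberately simple — uniform
   relocation, no GC or accessibility matching — and measures co-occupancy
   against genomic chance only.

2. **Motif content.**  PWM matches are called at a fraction-of-maximum
   threshold: a window's summed log-odds $s$ (against a uniform background,
   pseudocount $10^{-3}$) is normalised to
   $(s - s_{min})/(s_{max} - s_{min})$ and called at $\ge 0.8$, the
   conventional "80% match".  Scoring conventions differ between motif
   databases; min–max normalisation was chosen because it is
   self-contained — it needs no background model beyond the matrix itself —
   and makes the threshold interpretable as a fraction of the best possible
   site.  A degenerate matrix with $s_{min} = s_{max}$ scores every window
   1 by definition.  Peaks are then classified exhaustively and mutually
   exclusively: *cGBM* if any PWM hit at threshold, else *dGBM* if any
   `CCTCC` core on either strand, else *neither*.

3. **8-mer census.**  Each window of each peak sequence contributes one
   count to its canonical 8-mer (the lexicographic minimum of the word and
   its reverse complement), so occurrences are counted on either strand
   while palindromic windows are counted once.  There are
   $(4^8 - 4^4)/2 + 4^4 = 32{,}896$ canonical 8-mers.  Ranking is
   competition order by descending count with lexicographic tie-break; a
   census also supports per-peak incidence (the fraction of peaks containing
   a word at least once), since occurrence counts and peak fractions answer
   different questions and both are useful.

4. **Composite-site grammar.**  Within each peak, every (PWM hit, E-box)
   pair with signed edge-to-edge gap within a 100 bp window forms one
   configuration; the gap is positive when the E-box starts after the GBM
   ends.  Because `CANNTG` is its own reverse-complement pattern, the E-box
   contributes no strand and orientations reduce to two states (`GBM+`,
   `GBM-`).  Configurations are tabulated on a 2 × 201 grid and tested
   per cell against a uniform multinomial null conditioned on the total,
   with Benjamini–Hochberg adjustment across cells.  The uniform null
   formalises the qualitative question "is any spacing preferred?"; it is
   not a model of sequence composition.

5. **Expression integration and reporter synergy.**  DE tables are
   filtered at strictly $|FC| > 1.5$ and adjusted $p < 0.05$; overlap of DE
   sets is tested with the exact hypergeometric upper tail over the genes
   present in both tables; direction concordance partitions shared DE genes
   into up/up, down/down and discordant.  Dual-luciferase wells are
   normalised per construct as firefly/renilla divided by the mean control
   ratio.  On that scale the additive null for co-transfection is
   $E[AB] = \bar A + \bar B - 1$: effects are measured above a shared
   baseline of 1, which must be subtracted once.  Synergy is a one-sided
   test of $\bar{AB} - (\bar A + \bar B - 1) > 0$, by default a Welch-type
   delta-method statistic whose variance propagates the replicate variances
   of all four condition means (with Welch–Satterthwaite degrees of
   freedom); a stratified bootstrap (resampling replicates within
   conditions) is available as an alternative.

# Nearest-gene assignment

Peaks are assigned the gene with the nearest TSS at or left of the peak
start and the nearest TSS at or right of the peak end; a TSS inside the
peak fills both slots at distance 0.  The TSS (not the gene body) anchors
the assignment because regulatory-target bookkeeping here is
promoter-oriented; distances are edge-to-TSS base pairs, and ties break to
the lexicographically smaller gene id for determinism.  All coordinates are
BED-convention 0-based half-open at the package boundary and `GRanges`
1-based internally.

# The synthetic-data generator

Every input the pipeline consumes can be generated under a single master
seed (`simConfig()` / `simulateStudy()`), with sub-seeds derived per stage
so each generator is individually reproducible.  The defaults encode the
study conditions the package is designed around:

* genome: 2 chromosomes × 2.5 Mb, i.i.d. bases at GC 0.42 (a typical
  mammalian genome-wide value);
* peaks: 500 per factor, lengths ~N(300, 50²) bp truncated at 50; 60% of
  A peaks planted to overlap a B peak by ≥ 1 bp, the remainder placed
  avoiding B, and A peaks mutually non-overlapping so each owns its
  sequence footprint;
* motif classes: overlapping peaks 9% cGBM / 85% dGBM / 6% neither;
  A-only peaks 16% cGBM; an E-box co-planted with probability 0.7 at a
  signed gap drawn uniformly within ±100 bp (or fixed via `eboxGap`);
* replicates: two per factor, edges jittered ±20 bp plus 5%
  replicate-private noise peaks, so replicate merging at support ≥ 2 is
  exercised non-trivially;
* expression: 1000 genes with non-overlapping bodies; 200 DE genes per
  condition, half shared, all shared genes concordant with 58% down in
  both (the generator parameterises `sharedFrac`, `concordantFrac` and
  `downFrac` separately so discordance can be planted at will); planted DE
  genes strictly clear the 1.5-fold/0.05 thresholds and all other genes
  fail the fold-change threshold, so threshold filtering recovers the
  planted sets exactly;
* reporter: control-relative means 1, 2, 2 and (2+2−1)×interaction, with
  mean-preserving multiplicative log-normal noise at CV 0.1 and 6
  replicate wells; the default pairs a synergistic dGBM+E-box construct
  (interaction 2) with an additive cGBM+E-box construct (interaction 1).

Two generator choices deserve emphasis.  First, **backgrounds are
scrubbed**: before motifs are planted, chance PWM hits (and, for
*neither*-class peaks, chance `CCTCC` cores) in the peak footprint plus a
50 bp margin are removed by point mutation, and each placement is verified
with the classifier and retried (≤ 100 attempts) if an insertion junction
recreates a motif.  A 300 bp random sequence contains a `CCTCC`/`GGAGG`
match with probability ≈ 0.44, so without scrubbing a planted "neither"
peak would usually classify as dGBM and planted class fractions would not
be recoverable.  This makes class recovery a sharp test of the classifier,
at the cost of realism: real peaks do contain incidental cores, and the
package's class fractions on real data inherit that ambiguity.  Second,
the **additive reporter null is exact in expectation**: with the
interaction multiplier at 1 and CV 0, the combined condition equals
$A + B - 1$ to machine precision, which pins the synergy statistic's null
case by construction.

What the generator does *not* emulate: read-level noise, peak-calling
artefacts, chromatin state, GC heterogeneity, correlated gene placement,
and any realistic noise model for the assays (none is published for them);
all noise choices are parameterised stand-ins.  Passing the recovery suite
therefore demonstrates correctness of the estimators under their own
assumptions, not robustness to real-data violations of those assumptions.

# The bundled PWM

No canonical Gli matrix is shipped with its database provenance; instead
`gbmMatrix()` loads a synthetic stand-in built to reproduce the one feature
that matters for the cGBM/dGBM distinction: position 5 (the highly
constrained 'A') is near-one-hot (0.97) while all other positions are soft
(0.70 on the consensus base).  Under the 0.8 threshold the consensus scores
exactly 1, any single soft-position mismatch still scores ≈ 0.89 (a
tolerant match, as for a real informative matrix), and the divergent
`GACCTCCC` scores ≈ 0.75 — below threshold, so divergent sites are *not*
canonical matches and fall through to the core rule.  All score-dependent
tests use this matrix; analyses of real data should substitute a database
matrix via `readPWM()`.

# Numerical and design choices

* **Permutation resolution.**  The empirical p-value is floored at
  $1/(1+n_{perm})$.  For the per-cell spacing test this interacts with
  multiplicity: after BH adjustment across the 402 grid cells the smallest
  achievable adjusted p is $402/(1+n_{perm})$, so the pipeline uses 20,000
  null draws for that stage (floor ≈ 0.02) while 1,000 permutations
  suffice for the single overlap and marker-set tests.
* **Tie-breaks.**  K-mer ranks break count ties lexicographically; the
  modal spacing configuration breaks ties by orientation order (`GBM+`
  first), then smaller |gap|, then positive gap; nearest-gene ties take
  the smaller gene id.  All are arbitrary but fixed, so outputs are
  byte-stable.
* **Degenerate inputs.**  Empty peak sets error in classification and
  census ranking rather than returning silent zeros; a zero-variance
  Welch comparison reports p = 1 (equal means) or p = 0 with a warning;
  an empty spacing grid tabulates to all-zero counts with total 0 and
  refuses `maxConfigFraction`.
* **Welch over pooled variance.**  All pairwise reporter comparisons use
  unequal-variance t tests; significance tiers use strict 0.05/0.01/0.001
  thresholds.  No multiple-testing correction is applied across constructs
  by default (stars are reported per construct); the spacing grid, where
  hundreds of cells are tested jointly, is BH-adjusted.
* **Laxer spacing threshold.**  Composite-site pairing defaults to a PWM
  threshold of 0.7 rather than 0.8 so that divergent GBMs (≈ 0.75 under
  the bundled matrix) anchor pairs; the classification threshold is
  unaffected.
* **Problem sizes in the test-suite.**  The calibration checks use a
  10 Mb single-chromosome genome with 2,000 reference and 600 query peaks
  over 200 replicate datasets (399 permutations each), and 2,000
  simulated reporter datasets; these sizes keep the discrete empirical-p
  grid fine enough for a Kolmogorov–Smirnov uniformity check while the
  whole suite completes in a few minutes.

# Known limitations

* The relocation null ignores sequence composition and accessibility; on
  real data, fold enrichments against it overstate biological specificity.
* Classification is presence/absence per peak; motif counts and affinities
  within a peak are recorded but not modelled.
* The E-box is matched as `CANNTG` only; factor-specific E-box preferences
  (e.g. Hand-type) are not distinguished.
* The delta-method synergy test relies on approximate normality of
  condition means; at very small replicate numbers (n = 2–3) or heavy
  tails the bootstrap option is preferable, at the price of a coarser
  p-value floor.
* `sharedFrac`/`concordantFrac` act on planted DE sets; the generator does
  not model the correlation structure of real transcriptomes.

# Reproducibility

Every stochastic function takes an explicit seed; `simulateStudy()` +
`runPipeline()` under fixed seeds are byte-identical across runs, which
the test-suite asserts file-by-file.  `scripts/acceptance.R` re-runs the
whole analysis from scratch under a caller-supplied seed and writes the
headline quantities as JSON.
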