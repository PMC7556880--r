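# comotif

Quantifying how two transcription factors share cis-regulatory modules
(CRMs), for regulatory genomicists working from ChIP-seq peak sets.  The
motivating system is the cooperation of a Gli zinc-finger factor with the
bHLH factor Hand2 in craniofacial neural crest, where co-occupied CRMs tend
to carry a low-affinity *divergent* Gli-binding motif (dGBM, `GACCTCCC`;
operationally a `CCTCC` core without a full canonical match) next to an
E-box (`CANNTG`) instead of the canonical `GACCACCC` (cGBM) — and where the
two factors activate reporters synergistically rather than additively.

The package implements the complete analysis as reusable, seeded stages:

* **Co-occupancy enrichment** — observed overlap of peak set *A* with *B*
  (each *A* peak counted once) against a permutation null that relocates
  every *A* peak uniformly within its own chromosome, preserving length.
  Reports fold = obs/E[null], z, the empirical p
  `(1 + #{null ≥ obs})/(1 + n_perm)` and the upper normal tail at z.
* **Motif classification** — PWM scanning with min–max-normalised
  log-odds, `(s − s_min)/(s_max − s_min) ≥ 0.8` ("80% match"); peaks split
  exhaustively into cGBM / dGBM / neither.
* **Canonical 8-mer census** — every window counted once toward the
  lexicographic minimum of word and reverse complement (palindromes never
  double-counted; there are (4⁸−4⁴)/2+4⁴ = 32,896 canonical 8-mers), with
  competition ranking and per-peak incidence.
* **Composite-site grammar** — signed edge-to-edge gaps and orientations
  of GBM/E-box pairs within 100 bp, tabulated on a 2 × 201 grid and tested
  per cell against a uniform multinomial null (BH-adjusted).
* **Expression integration** — DE filtering at |FC| > 1.5 and adjusted
  p < 0.05, exact hypergeometric overlap of DE sets, direction
  concordance, DE-gene counts per peak category, and marker-gene-set
  proximity enrichment.
* **Reporter synergy** — dual-luciferase normalisation
  (firefly/renilla, control-relative) and a one-sided test of
  `mean(AB) − (mean(A) + mean(B) − 1) > 0` (delta-method Welch statistic,
  or a stratified bootstrap).
* **Synthetic data** — `simulateStudy()` generates a genome, peak sets
  with a planted overlap fraction, motif-embedded peak sequences with
  known classes and spacings, replicate BED files, a gene annotation, DE
  tables with planted sharing/concordance, marker sets and reporter
  replicates, all byte-reproducible under one seed, so the entire pipeline
  runs without any download.

Built Bioconductor-style on GenomicRanges/Biostrings: peaks are `GRanges`,
genomes are `DNAStringSet`, results are small S4 classes (`EnrichResult`,
`KmerCensus`, `PairGrid`, `SynergyStat`) with accessors.

## Worked example

```r
library(comotif)

cfg <- simConfig(seed = 42, nChrom = 1L, chromLen = 1e6, nPeaksA = 200L,
    nPeaksB = 200L, nGenes = 400L, nDE = 100L)
simulateStudy(cfg, "demo_sim")
res <- runPipeline("demo_sim", "demo_out", seed = 7L)
```

Selected numbers this run prints (from `demo_out/summary.json`):

```
frac_a: 0.597                      # planted overlap fraction was 0.6
fold 4.96  p_emp 0.000999  p_normal 8.19e-95
cGBM 0.085  dGBM 0.846  neither 0.068   # planted 0.09 / 0.85 / 0.06
cGBM peak fraction: a-only 0.228, overlap 0.085
cGBM rank: a-only 2, overlap 16
max spacing config fraction 0.0537
DE overlap p_hyper 1.73e-10, concordant 1.00
dGBM+Ebox: AB 6.75 vs additive 3.58, excess 3.17, p 4.16e-05
cGBM+Ebox: AB 2.93 vs additive 2.73, excess 0.19, p 0.0776
```

Reading them: 59.7% of factor-A peaks overlap factor B (the planted 60%),
five-fold enriched over uniform relocation; overlapping peaks are
dominated by the divergent motif class while the canonical 8-mer is both
rarer in them (8.5% vs 22.8% of A-only peaks) and lower-ranked in their
8-mer census (16th vs 2nd); no single GBM/E-box spacing dominates the
planted-uniform grammar (modal configuration 5.4% of pairs); the two DE
tables share far more genes than chance with fully concordant directions;
and only the dGBM+E-box reporter construct shows super-additive
(synergistic) activation.

Individual stages work standalone, e.g.

```r
chroms <- readChromSizes("demo_sim/chrom_sizes.tsv")
a <- readPeaks("demo_sim/peaks_a.bed", chroms)
b <- readPeaks("demo_sim/peaks_b.bed", chroms)
permutationOverlapTest(a, b, chroms, nPerm = 1000, seed = 1)

seqs <- peakSequences(a, readGenome("demo_sim/genome.fa", chroms))
classifyPeakSet(seqs)$fractions
kmerRank(countKmers(seqs, k = 8), "GACCACCC")
```

A thin command-line front end over the same functions is provided at
`inst/scripts/comotif.R` (subcommands `simulate`, `pipeline`, `enrich`,
`classify`, `kmers`, `spacing`, `synergy`).

## Documentation

See the methods vignette (`vignettes/comotif-methods.Rmd`) for the models,
their assumptions, all tunable parameters with defaults and rationale, what
the synthetic-data generator does and does not emulate, and known
limitations.
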