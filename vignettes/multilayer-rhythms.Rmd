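---
title: "Dissecting diurnal rhythms across regulatory layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting diurnal rhythms across regulatory layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmlayers)
library(dplyr)
```

## The problem

Entrained tissues cycle with the light–dark schedule, but the cycling of a
gene is layer-specific: its transcription rate, mature RNA level, protein
abundance and — for transcription factors — DNA-binding activity can each
gain or lose rhythmicity relative to the layer upstream. Dissecting where a
rhythm is created, propagated or buffered requires (i) a rhythm detector
that behaves identically across layers with very different noise
characteristics, (ii) layer-appropriate quantification, and (iii) a
classification of each gene's rhythmicity change between adjacent layers,
with mechanistic side channels (translation rate, phosphorylation,
enhancer activity) to explain the layer-specific cases.

`rhythmlayers` implements that pipeline for time courses sampled across one
24 h cycle — by default 8 timepoints every 3 h, ZT0–ZT21, one replicate,
the only even arrangement of eight samples over a day — together with a
fully seeded synthetic generator so every stage is testable without
external data.

## The oscillation model

Each feature follows a cosinor curve
$x(t) = M + A\cos\!\big(2\pi (t-\varphi)/\tau\big) + \varepsilon$, with
baseline $M > 0$ (abundance units), half-amplitude $0 \le A \le M$ (so the
expected signal stays positive), acrophase $\varphi \in [0, 24)$ ZT hours,
period $\tau \in [20, 28]$ h, and additive Gaussian noise truncated at
zero. Truncation at zero mirrors the abundance scale; because detection is
rank-based, the noise family matters little — Gaussian is enough for the
operating characteristics the tests measure.

## Rhythm detection

Detection is a from-scratch JTK_CYCLE. Reference cosines are evaluated at
the actual sample times on a period grid of 20–28 h in 1 h steps and a
phase grid in 1 h steps (`lag_step`), so test periods need not be multiples
of the sampling interval. Many (period, lag) pairs induce the same ranking
of the 8 sample times; references are deduplicated by rank pattern and only
the distinct patterns (121 for the default design and grid) count as tests.

For each reference the statistic is the Kendall numerator
$S=\sum_{i<j}\mathrm{sign}(x_j-x_i)\,\mathrm{sign}(r_j-r_i)$; pairs tied in
either ranking, or involving a missing value, contribute zero. The null
distribution of $S$ is exact and conditional on both tie patterns:

* one ranking untied — $S = 2J - T$ where $J$ is the Jonckheere–Terpstra
  count, which factorises into independent Mann–Whitney counts between each
  reference tie group and its predecessors; each factor is a
  Gaussian-binomial polynomial and the null is their convolution;
* both rankings tied — a dynamic programme over the multiset of data
  values, filling reference tie groups one at a time and tracking how many
  copies of each distinct value have been placed.

Exhaustive permutation enumeration exists only in the test suite, as the
independent oracle the two in-package routes are checked against (all grid
tie patterns, $n = 4..8$, agreement to $10^{-10}$ per mass point). Above
`exact_limit = 25` samples a normal tail with the tie-corrected Kendall
variance and a 0.5 continuity correction is used and flagged `approx`.

The per-feature p is the minimum one-sided upper tail across distinct
references, Bonferroni-multiplied by their number. Choices worth making
explicit:

* **One-sided tails.** Antiphase alternatives are covered by the phase
  grid, so a two-sided test would be redundant and cost power.
* **Bonferroni scope.** The adjustment is per feature across the distinct
  references — the convention of the original JTK_CYCLE, whose "adjusted p"
  is corrected for the period/phase family, not across genes. An additional
  across-feature Bonferroni is available (`feature_adjust = "bonferroni"`).
* **Best reference.** Among references attaining the minimal p, ties go to
  the longer period, then the smaller lag. With 8 samples, a noiseless grid
  cosine is perfectly concordant with several references at once, so the
  reported period can be a neighbouring one; the reported peak stays within
  one grid step of the truth, and the tests assert exactly that.
* **Amplitude and phase.** The reported phase is the best reference's lag in
  ZT hours; the amplitude is the least-squares cosinor half-amplitude at the
  best (period, lag) — the rank test itself estimates neither.
* **Ties and rounding.** Data and reference values are rounded to 9 decimal
  places before ranking so analytically tied values (exact cosines,
  repeated measurements) compare equal; without this, floating-point
  asymmetries of `cos` can split a tie and move $S$ outside the conditional
  null's support.
* **Missing values.** A feature's observed timepoints define its own
  reference grid, tie patterns and Bonferroni count; fewer than 4 observed
  values yields p = 1 with a message.
* **Thresholds.** `rhythmic` means adjusted p strictly below the layer
  threshold: 0.05 for transcription, mature RNA, eRNA and translation rate;
  0.1 for the mass-spectrometry layers (protein, DBP), where detection is
  sparser.

### Power at single-cycle designs

Eight samples of one cycle bound the exact null's resolution: the smallest
raw p any reference can reach is $1/8! \approx 2.5\times10^{-5}$ (times a
tie factor), so after multiplying by 121 distinct references the smallest
attainable adjusted p is about $3\times10^{-3}$ — detection requires
near-perfect rank concordance. The test suite quantifies the consequence:
detection power rises monotonically along an amplitude grid, recovery of
planted period-24 rhythms reaches only about 43 % at amplitude/noise = 3,
and per-gene cross-layer category recovery exceeds 90 % at
amplitude/noise = 10, where the cross-layer property tests operate. This is a property of rank tests on 8-point single-cycle data,
not of the implementation; designs with two sampled cycles or replicates
escape it. The synthetic study's default amplitude/noise of 3 was kept
deliberately at the harder, realistic end, and the acceptance suite
reports recovery under exactly those conditions.

## Layer quantification

* **Gene-body windows** for run-on (nascent transcription) signal avoid the
  promoter-proximal pause: genes longer than 12 kb use +2 kb…+12 kb
  downstream of the TSS; 2–12 kb genes use +2 kb…TES; genes under 2 kb use
  the whole body; minus-strand genes mirror all offsets 5′→3′. Both 2 kb
  and 12 kb boundaries fall in the middle branch (closed interval); a gene
  of exactly 2 kb therefore gets a zero-width window and zero signal — the
  one case where the interval invariant start < end is relaxed to ≤.
* **Densities**: RPKTM (reads per kb per 10⁷ mapped) for gene bodies and
  eRNA loci; RPKM (per 10⁶, exonic length) for mRNA layers.
* **Reads** are counted by 5′-end position within the window, matching
  run-on tag semantics; coverage tracks store 5′-end counts per base, so a
  window's read count is the coverage sum.
* **eRNA loci**: peaks with FDR < 0.001 and fold change > 3, strictly more
  than 300 bp from every annotated TSS, quantified over [center−500,
  center+500). Peak calling itself is consumed as input (a BED6+2 table):
  the callers are mature external tools, and the package's contribution is
  the filtering and quantification around them.
* **Translation rate**: footprint RPKM over mRNA RPKM on the shared ZT
  labels (a 12-point Ribo-seq grid intersects an 8-point RNA grid on the
  common hours; no interpolation). Denominators below `floor = 0.1` RPKM
  make the ratio missing rather than explosive; genes with more than 25 %
  missing timepoints are flagged unusable. Both cutoffs are conventions,
  configurable, and recorded in the output metadata.
* **Coordinates**: 0-based half-open internally; GTF (1-based closed)
  converted on read; BED native. Overlapping bedGraph intervals are split
  and summed on read.

## Cross-layer integration

Genes detected in both adjacent layers are partitioned into conserved /
disrupted / enhanced / neither (the partition is asserted as an invariant);
"enhanced" and "disrupted" are oriented downstream-relative along
transcription → mature RNA → protein → DBP. The conserved fraction's
denominator is the upstream-rhythmic genes in the detected-in-both set.
Proteins must be detected in all three independent datasets before the
protein comparisons (the `detection_filter` intersection); rhythm detection
then runs on the primary dataset. Mechanism attribution:

* translation-rate dependence = the gene's TE series is itself rhythmic at
  adjusted p < 0.05 (the RNA-layer convention; configurable). Genes without
  usable TE stay in the analyzed table with `dependent = NA` and leave the
  denominator.
* phosphorylation dependence = binary presence of a detected phosphosite; a
  stricter rhythmic-phospho mode can be emulated by passing a rhythm-called
  detection table, but presence is the default because phosphosite
  detection, not phosphosite rhythmicity, is what time-resolved
  phosphoproteomes report most robustly.
* triads = (DBP, enhancer, gene) with both links present in the pairing
  maps and all three series rhythmic. How specific DBPs find specific
  enhancers is not derivable from expression data alone, so the pairing map
  is an explicit input — ground truth in synthetic mode, or e.g.
  `pair_enhancers_to_genes()` (nearest TSS within 100 kb) for real data.

## The synthetic study

`simulate_study()` plants, for each adjacent layer pair, cohorts of
conserved (rhythmic in both layers), disrupted (upstream only) and enhanced
(downstream only) genes — 200/100/100 by default, plus 100 all-flat genes —
with uniform random phases. Coupling follows the cascade: an inherited
mature-RNA rhythm copies the transcription phase (plus a configurable
processing delay, default 0 h — unmodelled otherwise); an inherited protein
is the product of the noiseless mature-RNA and translation-rate curves plus
its own noise, so a rhythmic TE alone drives a protein rhythm and a flat TE
transmits the RNA rhythm; an inherited DBP activity copies the protein
phase. A planted fraction (0.45) of the protein-specific genes is
translation-driven and a planted fraction (0.62) of the DBP-specific genes
carries a phosphosite — the fractions the attribution stage should recover;
planted triads wire rhythmic DBPs through rhythmic eRNA loci to rhythmic
transcription, next to non-rhythmic decoy pairings. Because a cohort
planted for one pair is flat elsewhere, it contributes categories to the
other pairs too; the per-gene `truth_table()` is therefore the reference
for recovery checks, not the nominal cohort sizes.

Default strength is amplitude/noise = 3 (baseline 20, amplitude 6, noise
sd 2; the TE layer scales to ratio units). Three protein datasets are drawn
(shared truth, independent noise) to exercise the detection filter.

What the generator does **not** emulate: count-distribution effects
(over-dispersion, zeros), read-level artifacts, unequal detection across
layers, correlated noise between layers, phase-dependent amplitudes, or
mass-spectrometry peptide-level missingness. Passing tests therefore show
the pipeline's logic and its statistical operating characteristics under a
clean oscillator model — not performance on any particular real dataset.

The emitted toy coverage (single 10 Mb chromosome `chrT`) places
`round(expression × reads_per_unit)` reads uniformly over each gene's
quantification window, which makes hand-computed RPKTM values exact test
oracles.

## Sanity reporting

`pca_report()` projects samples of the rhythmic-feature submatrix onto the
first two principal components and scores whether the unsupervised layout
recovers the diurnal order: the fraction of ZT-adjacent sample pairs
(cyclic) that are also adjacent in the circular order of the samples'
angles around the projection centroid. Strong rhythms score 1; duplicated
samples or fewer than two variable features are flagged degenerate rather
than scored.

## Reproducibility and problem sizes

Every random step takes an explicit seed (`withr::with_seed`, never the
global RNG state); `run_pipeline()` writes a manifest with per-file
checksums, and rerunning a configuration reproduces all outputs byte for
byte. The test suite runs the exact-null oracle at $n \le 8$ (8! = 40 320
permutations), type-I calibration on 2 000 null series, power curves at 200
genes per amplitude, cross-layer recovery on bundles of a few hundred to
1 300 genes, and the end-to-end pipeline at its default 1 300-gene study —
sizes chosen so the whole suite completes in about a minute while keeping
Monte-Carlo error well below the asserted margins. In the power-
monotonicity check the same 200 genes (identical phases and noise draws)
are re-scored at every amplitude with noise sd 0.5, so consecutive levels
differ in true power by more than the Monte-Carlo error and the comparison
is paired.

## Known limitations

* Single-cycle 8-point designs cap power as described above; the detector
  is honest about it rather than anticonservative (type-I stays below the
  nominal level by construction and by measurement).
* The Bonferroni-over-references convention is conservative when references
  are correlated; an exact joint null over the whole grid would be more
  powerful but is no longer the standard JTK_CYCLE statistic.
* Period estimation at 8 points is coarse: equal-evidence ties across
  neighbouring periods are systematic, and only the peak time should be
  interpreted finely.
* Real-data mode trusts the supplied annotation, peak table and pairing
  maps; no motif- or ChIP-based DBP-to-enhancer assignment is attempted.
* Enrichment analysis, browser-track export and read processing upstream of
  coverage are out of scope.
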