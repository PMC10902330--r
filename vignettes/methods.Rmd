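---
title: "Methods: rhythm detection, phase binning and cis-element enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm detection, phase binning and cis-element enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmscan)
```

## Scope and model

`rhythmscan` analyses log2 expression time courses for periodicity in
a configurable period window, estimates phase and amplitude by
cosinor fitting, clusters rhythmic waveforms, and tests whether
degenerate cis-elements (notably the ROR response element,
`WAWNTRGGTCA`) are enriched in the regulatory regions of genes peaking
in particular phases. The two windows we care about in practice are
20–28 h (adult circadian rhythms after temperature entrainment) and
8–10 h (the larval molting-cycle oscillator), but nothing in the code
is specific to those values.

The core model is the single-component cosinor,

$$y(t) = m + a\cos(2\pi t/T) + b\sin(2\pi t/T) + \varepsilon,$$

fit by the exact normal-equation solution at each period $T$ on a
grid; no iterative optimizer is involved, so fits are deterministic
and fast enough to sit inside a permutation loop. Replicates enter as
independent observations. We report:

* **mesor** $m$ — the rhythm-adjusted mean (log2 units);
* **amplitude** $A = 2\sqrt{a^2+b^2}$ — *peak-to-trough*, so on log2
  data $A = 1$ corresponds to a ~2-fold swing. An alternative
  amplitude convention (relative variance of the cosine component,
  i.e. the statistic below) exists in the literature; we expose the
  variance-explained statistic in the output so either convention can
  be thresholded, but "amplitude" in all tables means peak-to-trough;
* **phase** $\varphi = \operatorname{atan2}(b, a) \bmod 2\pi$ — the
  peak position in radians. The time origin is the first sample of
  the analysed segment; the peak falls at $t = \varphi T / 2\pi$
  hours after it. Published analyses of this kind rarely state their
  phase origin; ours is explicit and all synthetic truth uses the
  same convention, so phase errors are measured consistently.

### Periodicity test

The statistic is variance explained at the best grid period,
$R^2 = 1 - \mathrm{RSS}_{\text{best}}/\mathrm{RSS}_{\text{null}}$,
with the intercept-only model as null. Significance comes from an
empirical null: timepoint labels are permuted with replicate blocks
kept intact (all replicates of a timepoint move together, preserving
replicate correlation), the same permutations are applied to every
gene, and $p = (1 + \#\{R^2_{\text{perm}} \ge R^2_{\text{obs}}\}) /
(1 + n_{\text{perm}})$. Benjamini–Hochberg q-values are computed per
analysis run (per condition), never pooled across conditions. This
test replaces classifier-based periodicity callers: it uses the same
cosine machinery as the parameter estimates, has an exactly valid
permutation null, and needs no training data. No detrending is
applied beyond the mesor term, and no other periodicity algorithms
(JTK_CYCLE, Lomb–Scargle, ...) are included.

When a matrix holds several conditions, `rhythm_test()` requires an
explicit `condition` argument; testing a mixed-condition matrix is
refused rather than silently pooled. At least 8 distinct timepoints
are required — below that the permutation space and the period grid
are too poor for the test to mean much.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| period window | 20–28 or 8–10 | h | the two biological regimes targeted |
| `period_step` | 0.5 | h | window endpoints are the only published constraint; 0.5 h resolves the grid finer than the phase/amplitude error at realistic noise |
| `n_perm` | 999 (tests), 199 (pipelines) | — | minimum attainable p is $1/(n_{\text{perm}}+1)$; 199 suffices once BH operates on hundreds of genes |
| `q_threshold`, `amplitude_threshold` | 0.10, 1 | —, log2 | the joint "clearly rhythmic" criterion; both cuts are strict inequalities (amplitude must exceed 1). Stricter (0.05) and looser (0.30, no amplitude cut) tiers are used for clustering and weak-rhythm comparisons respectively |
| `upstream_length` | 4000 | bases | regulatory region = 4 kb upstream of the first exon plus all introns |

## Synthetic data: what it emulates and what it does not

`simulate_expression()` draws genes-by-samples matrices under three
canonical designs: circadian (12 timepoints × 4 h × 3 replicates),
developmental (16 × 1 h × 1 replicate), and knockdown (12 × 2 h × 2
replicates × 2 conditions). Rhythmic genes follow
$m + (A/2)\cos(2\pi t/T - \varphi)$ plus i.i.d. Gaussian noise on the
log2 scale; the defaults are mesor $\sim N(6, 1.5)$, amplitude
$\sim N(1.5, 0.5)$ truncated (clipped) at zero — truncation rather
than re-drawing keeps the draw sequence reproducible — and a
three-component wrapped phase mixture centred at $\pi/3$, $2\pi/3$
and $3\pi/2$ with SD 0.15 rad, matching the three peak-phase bins
used downstream (`magenta` $[\pi/6, \pi/2)$, `navy` $[\pi/2, 5\pi/6)$,
`gray` $[4\pi/3, 5\pi/3)$). The residual SD defaults to 0.25 log2
units; the noise level of real array/TPM datasets is not something we
estimate here, so this is a configuration value chosen to give a
signal-to-noise regime where an amplitude-1 gene is clearly but not
trivially detectable, not a claim about any real dataset.

`simulate_knockdown()` regenerates the matrix with the oscillatory
component scaled in one condition only, reusing the identical noise
stream derived from the stored seed — so `amplitude_scale = 1`
returns a bitwise-identical matrix and any difference at other scales
is purely the planted signal change. `simulate_dual_period()` adds an
independent short-period time course for the same genes, with
per-phase-component probabilities of being rhythmic at the second
period, emulating partial overlap between circadian output and the
molting-cycle program.

`simulate_genome()` writes one contig per gene (background bases
i.i.d., uniform by default), lays out exons/introns per a spec table,
and — with a per-cluster probability — plants exactly one concrete
expansion of the IUPAC motif at a position uniform over the
regulatory region, on a uniform strand, never crossing an exon
boundary. Everything is emitted as FASTA (60-column) + GFF3 (1-based
inclusive, `gene`/`mRNA`/`exon`, `ID=`/`Parent=`).

What the generator does **not** emulate: read-level sampling noise
(no FASTQ/counting model), microarray probe effects, batch structure
(a per-replicate additive effect is available but off by default),
temperature-entrainment transients, non-sinusoidal waveforms, and
correlated co-regulation beyond the shared phase components. Passing
recovery tests on this generator therefore demonstrates correctness
of the analysis chain under its stated model, not performance on any
particular real dataset.

## Sequence handling and numerical choices

* Coordinates are 0-based half-open internally; GFF3 I/O converts
  from/to 1-based inclusive at the boundary, and a round-trip
  preserves every interval exactly.
* The upstream window is measured from the gene model's first exon
  (5′-most exon; no per-transcript TSS resolution) and truncated at
  contig boundaries only — overlap with neighbouring genes is not
  trimmed, since no such rule is defensible without expression-aware
  annotation.
* Motif scanning interprets degenerate IUPAC codes in the pattern
  but treats genome bases literally, so an `N` in the assembly
  matches only the motif code `N`. Both strands are scanned by
  default (the RORE is not palindromic; single-strand scanning is a
  switch). Overlapping matches are all counted; because enrichment
  uses binarised presence, the overlap-counting choice cannot change
  enrichment results. Scanning is implemented on Biostrings
  `matchPattern`, and the test suite checks it against an independent
  regex-expansion matcher.
* Fisher's exact test uses the probability-mass definition of
  two-sidedness (sum hypergeometric probabilities of all tables at
  least as extreme as observed); other definitions exist and differ
  in edge cases. The odds ratio reported is the sample $ad/bc$
  ($\infty$ when $bc = 0 < ad$, NaN when both products vanish), not
  the conditional MLE. A zero margin makes only one table possible:
  $p = 1$, odds ratio flagged undefined.
* The Holm family defaults to all bin × motif pairs tested in one
  call; a per-motif family is selectable since the appropriate family
  is genuinely ambiguous in this kind of analysis.
* The enrichment background for a focal bin defaults to every other
  universe gene (other peaks, unbinned rhythmic and arrhythmic
  genes); a strict arrhythmic-only background is selectable. Note a
  consequence used by the end-to-end tests: when one bin is heavily
  planted, the default background of the *other* bins is inflated,
  so those bins can show significant *depletion*; "enrichment in bin
  X" therefore always means Holm-significant **and** odds ratio > 1.
* Clustering is agglomerative with average linkage (standard for
  cosine distance; complete/single selectable) on replicate-averaged
  timepoint profiles after amplitude normalization (mean-centred,
  unit Euclidean norm). Whether to average replicates first is an
  open choice; averaging matches the one-row-per-gene heatmap view
  and reduces noise at the cost of hiding replicate disagreement.
  Tie-breaking follows `stats::hclust` (lowest-index merge), so
  results are deterministic given input order, and label sets are
  invariant to row permutation up to renaming.
* Constant series: amplitude-normalization refuses them (no waveform
  to compare); min–max normalization maps them to all-zeros; the
  cosinor reports amplitude 0 with phase 0 by convention.
* Phase bins are half-open $[\ell, u)$; genes outside every bin get
  the total label `"other"`, so bin assignment never drops genes.
  Peak detection in phase histograms is deliberately *not*
  automated — bins are configuration, mirroring how such peaks are
  identified by inspection.

## Problem sizes used by the test suite

The validation suite exercises the chain at sizes chosen to give
stable statistics while keeping a full run in minutes on one CPU: 500
genes × 999 permutations for null calibration, 500 genes × 499
permutations for parameter recovery on both designs, 10 independent
seeds of a 400-gene end-to-end enrichment run (RORE planted in 80% of
magenta-component genes versus 20% elsewhere, ~100 genes per phase
component), a 400-gene knockdown comparison against a 20-shuffle
time-shuffled null, and a 600-gene dual-period overlap recovery. The
brute-force oracles (grid-search cosinor, regex motif matching,
hypergeometric enumeration over all 46,376 tables with total ≤ 30)
are computed independently of the implementation paths they check.

## Known limitations

* One harmonic only: strongly non-sinusoidal rhythms (sharp pulses)
  lose power and their peak-to-trough amplitude is underestimated.
* The permutation null assumes exchangeability of timepoint blocks;
  strong autocorrelated trends (e.g. developmental drift) would need
  detrending that the package intentionally does not apply.
* Overlap proportions measured through detection are biased slightly
  below planted rates, by one minus the detector's recall at the
  chosen thresholds; comparisons against planted values must budget
  for that (the tests use 3-binomial-SE bands, which absorb it at
  the sizes above).
* Regulatory regions ignore distal enhancers and UTR structure;
  "upstream + introns" is the whole search space.
* The q < 0.30 tier used for weak-rhythm datasets accepts a high
  false-discovery rate by construction; it is meant for set-level
  contrasts against a shuffled null, not for calling individual
  genes.
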