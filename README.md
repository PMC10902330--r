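# rhythmscan

Rhythm detection and phase-binned cis-element enrichment for gene
expression time courses.

Adult *C. elegans* shows weak but real circadian transcriptional
rhythms after temperature entrainment, while larvae run a ~8-h
"developmental" (molting) oscillator built from homologs of the
mammalian clock genes. Asking which genes oscillate at which period,
in which phase, and whether a regulatory element such as the ROR
response element (RORE, consensus `WAWNTRGGTCA`) is enriched near
genes peaking in a particular phase requires a chain of analyses:
periodicity testing over a period window, phase/amplitude estimation,
waveform clustering, regulatory-sequence extraction, degenerate motif
scanning, and contingency-table enrichment statistics. `rhythmscan`
implements that chain as composable R functions, for anyone analysing
rhythmic bulk expression time courses — circadian, ultradian, or both
— and wanting every step testable against planted ground truth.

## The model

For a gene's log2 expression series *y(t)* and candidate period *T*,
the package fits the cosinor model by exact least squares:

y(t) = m + a·cos(2πt/T) + b·sin(2πt/T) + ε

with mesor *m*, peak-to-trough amplitude *A* = 2√(a² + b²) (on log2
data, *A* = 1 ≈ 2-fold change), and peak phase φ = atan2(b, a) mod 2π,
so the peak falls at *t* = φT/2π after the first sample. The period is
chosen on a grid over a window (20–28 h for circadian analyses, 8–10 h
for the larval molting clock; step 0.5 h), minimising the residual sum
of squares. The periodicity statistic is the variance explained at the
best grid period, R² = 1 − RSS_best/RSS_null, tested against an
empirical null obtained by permuting timepoint labels with replicate
blocks kept intact (identical permutations for all genes), and
converted to q-values by Benjamini–Hochberg. Downstream, rhythmic
genes are clustered by cosine distance after amplitude normalization,
assigned to peak-phase bins, and tested for cis-element enrichment
(binarised motif presence in 4-kb-upstream + intron regions) with a
two-sided Fisher exact test and Holm correction.

A synthetic-data module generates expression matrices and toy genomes
(FASTA + GFF3) with known per-gene rhythm parameters and planted motif
instances, so recall, phase error, type-I calibration and enrichment
specificity can all be measured against ground truth.

## Worked example

```r
library(rhythmscan)

sim <- simulate_expression(design_circadian(seed = 1), n_genes = 200,
                           frac_rhythmic = 0.3)
tab <- rhythm_test(sim, period_min = 20, period_max = 28,
                   n_perm = 199, seed = 1)
tab
#> Rhythm table: 200 genes, period window 20-28 h, 199 permutations
#>   rhythmic (q < 0.1, amplitude > 1): 46
#>   gene_id period_h mesor amplitude_log2 phase_rad statistic p_raw       q
#> 1   g0001     20.0 5.314         0.1324    2.6654   0.03896 0.660 0.88079
#> 2   g0002     28.0 4.673         0.1797    3.3816   0.05971 0.380 0.67826
#> ...
```

60 genes were planted rhythmic; 46 pass the joint criterion q < 0.10
with amplitude > 1 (the planted amplitudes are drawn from N(1.5, 0.5),
so a share sits below the amplitude cut by design). Each gene's row
gives the best-fit period in hours, the mesor and peak-to-trough
amplitude in log2 units, and the peak phase in radians. Inspecting one
rhythmic gene:

```r
g <- classify_rhythmic(tab, q_threshold = 0.10, amplitude_threshold = 1)
scan_periods(sim$expr[g[1], ], sim$samples$time_h, 20, 28)
#> Cosinor fit (period 24 h)
#>   mesor:     7.229
#>   amplitude: 1.963 (peak-to-trough)
#>   phase:     2.109 rad (peak at t = 8.057 h)
#>   RSS: 2.349 on 33 residual df (null RSS 19.69)
```

The fitted peak-to-trough amplitude of 1.963 log2 units means this
gene swings almost four-fold, peaking about 8 h after the first
sample. Motif scanning works on any sequence:

```r
scan_motif("AATTTAGGTCA", "WAWNTRGGTCA")$count
#> [1] 1
```

`run_pipeline(pipeline_config(...))` chains the full synthetic
analysis — simulation, rhythm detection, clustering, phase binning,
toy-genome generation with phase-cluster-dependent RORE planting,
motif scanning and Fisher/Holm enrichment — and writes stamped TSV
outputs.

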