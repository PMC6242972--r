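# crcprior

Prioritization of super-enhancer-marked, dosage-sensitive transcription
factors on a gained chromosome arm.

High-risk neuroblastoma almost universally carries a segmental gain of
chromosome arm 17q, and the tumor's identity is maintained by a core
regulatory circuitry (CRC) of super-enhancer (SE)-driven master
transcription factors. `crcprior` implements an integrative screen for the
dosage-sensitive CRC candidates that such a gain selects for: it takes
per-sample H3K27ac super-enhancer calls, an expression matrix, survival
follow-up and copy-number segments for a tumor cohort, and returns a ranked
table of candidate oncogenes. Around that screen it bundles the bespoke
statistics the analysis needs: a sliding-window z-score interaction caller
for 4C-seq fragment coverage, focal-amplification and dosage-ANOVA rules for
copy-number data, Excess-over-Bliss synergy scoring for drug checkerboards,
and rank-based expression signature scoring. A seeded synthetic-data module
generates every input class so the full pipeline can be exercised,
calibrated and benchmarked without any external download.

## The method

**SE prioritization.** Per-sample SE calls are merged across samples into
clusters: two calls belong to the same cluster iff they are connected by a
chain of calls that pairwise overlap or lie within 500 bp (transitive
closure, computed exactly by a sorted sweep and verified against an O(n²)
closure oracle). Each cluster is scored by the median of its members'
within-sample SE ranks (1 = strongest SE of a sample); the top 500 clusters
are kept, then those recurrent in ≥ 20 samples. Genes with a TSS within
500 kb of a retained cluster are annotated to it, and the candidate list is
reduced to transcription factors with an H3K27ac peak at the TSS
(± 1 kb) in *every* sample harboring the SE.

**Candidate scoring.** Each candidate is scored by (i) Kaplan–Meier
stratification of the tumor cohort at the median expression cut-off with a
two-group log-rank test, χ² = (Σ(O − E))²/ΣV on 1 df, and (ii) the
copy-number dosage effect on its expression — per-tumor arm-gain status is
the length-weighted mean log2 ratio over the arm (> 0.3 ⇒ gained), and a
two-way fixed-effects ANOVA `expression ~ stage * gain` (type-II SS) is
reported together with the headline one-way gain effect within the
high-stage stratum. Focal amplifications over a locus are segments with
log2 ratio ≥ 0.3 and size ≤ 5 Mb. The final report ranks by raw log-rank p
with BH-adjusted values alongside.

**4C interaction calling.** Fragment coverage is binarized (covered ⇔ ≥ 1
read) and, for each fragment, the covered fraction p_w in a centered small
window (w = 100 fragments) is compared with the local background fraction
p_W in a centered large window (W = 3000) via

    z = (p_w − p_W) / sqrt(p_W (1 − p_W) / n_w)

with n_w the actual (edge-truncated) window size. One-sided normal
p-values are BH-adjusted across the track; calls are significant at FDR 1%
(cis) or 0.5% (trans), with the viewpoint neighborhood masked in cis.
Display tracks are smoothed over 21 fragments and normalized per million
reads; domainograms tabulate covered fractions across window sizes.

**Drug synergy.** Checkerboard viabilities (% of vehicle control, values
above 100% clamped to 100%) are converted to inhibitions i = 1 − v/100;
the Bliss-independence expectation for a combination is
e = i_a + i_b − i_a·i_b and the Excess over Bliss is i_observed − e
(> 0 synergy, < 0 antagonism). The same arithmetic scores fixed-dose
confluency time courses at a chosen time point.

**Signature scoring.** Per sample, all genes are ranked (average ranks for
ties), ranks rescaled to [0, 1], and the score is the mean rescaled rank of
the up genes minus that of the down genes — invariant under any monotone
transform of a sample's expression. `correlate()` applies the parametric
Pearson test when a Breusch–Pagan test does not reject homoscedasticity,
and Spearman otherwise.

## Worked example

All inputs below are simulated; every number shown is actual package
output.

```r
library(crcprior)

land <- simulate_se_landscape(seed = 101)                  # 26 cell lines
coh  <- simulate_cohort(n_tumors = 200, hr = 2.5, seed = 102)
cfg  <- prioritization_config(
  region = tibble::tibble(chrom = "chr17", start = 38.1e6, end = 81e6))

report <- run_prioritization(land$se_calls, land$genes, coh$expression,
                             coh$survival, coh$segments, coh$stage,
                             land$tss_peaks, config = cfg)
report
#> SE-driven candidate prioritization report
#>   clusters: 31 total, 9 recurrent; candidates: 10 annotated, 5 active TFs
#> # A tibble: 5 × 11
#>   gene_id   symbol    chrom      tss is_tf n_clusters recurrence median_rank
#> 1 DRIVER_TF DRIVER_TF chr17 39170000 TRUE           1         24           1
#> 2 DECOY27   DECOY27   chr17 66170000 TRUE           1         24          17
#> ...
#>     survival_p survival_padj dosage_p
#> 1 0.0000000237   0.000000119 0.000255
#> 2 0.275          0.567       0.162
```

Of 31 SE clusters on the simulated arm, 9 recur in ≥ 20 of the 26 cell
lines; 5 annotated transcription factors have an active TSS in all
harboring samples, and the planted driver ranks first with a median-split
log-rank p of 2.4e−8 and a within-high-stage gain effect p of 2.6e−4.

Focal-amplification detection on a printed segment:

```r
seg <- tibble::tibble(chrom = "chr17", start = 58654000, end = 59730000,
                      log2_ratio = 2.78)
detect_focal_gains(seg, list(chrom = "chr17", start = 59477257,
                             end = 59486827))
#>   chrom    start      end log2_ratio size_bp
#> 1 chr17 58654000 59730000       2.78 1076000
```

Excess over Bliss on a 2 × 2 toy (margins 60% and 50%, combination 20%):

```r
cb <- tibble::tibble(dose_a = c(0, 1, 0, 1), dose_b = c(0, 0, 1, 1),
                     viability = c(100, 60, 50, 20))
excess_over_bliss(cb)
#>   dose_a dose_b viability inhibition expected_inhibition   eob
#> 4      1      1        20        0.8                 0.7 0.100
```

Result objects have broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()` methods (`km_logrank`, `bliss_surface`) plus
`plot_domainogram()` for 4C tracks.

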