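---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcprior)
```

`crcprior` screens a recurrently gained chromosome arm for super-enhancer
(SE)-marked, dosage-sensitive transcription factors, the candidates a core
regulatory circuitry analysis would nominate as lineage dependencies. This
vignette records the statistical model behind each stage, the tunable
parameters and their defaults, the numerical conventions, and the design
choices that were genuinely open — together with what the synthetic-data
module does and does not emulate.

## Coordinates and input validation

All genomic intervals are 0-based half-open (`[start, end)`), the BED
convention, both in memory and on disk; 1-based inputs must be declared at
read time (`one_based = TRUE`) and are shifted on ingestion. Chromosome
names are compared literally: `"chr17"` and `"17"` are different sequences
unless the caller explicitly normalizes the prefix. Strand is ignored
everywhere except to derive a gene's TSS (interval start for `+`, `end − 1`
for `-`). Readers validate every row and fail with the offending line
number rather than dropping records silently, so row count in equals
records out whenever a file parses.

## SE clustering and prioritization

Two SE calls belong to the same cluster iff they are connected by a chain
of calls that pairwise overlap or lie within `max_gap` bp (default 500,
inclusive: a gap of exactly 500 merges). This is the transitive closure of
the pairwise predicate; on a single chromosome it is computed exactly by
one sorted sweep over starts with a running maximum of ends, which the test
suite verifies against a brute-force O(n²) closure oracle on a thousand
random instances. Calls on different chromosomes never merge.

Cluster strength is the *median within-sample rank* of its members. Ranks
are per sample (1 = that sample's strongest SE); when the input carries no
explicit ranks they are assigned by descending signal, ties broken by
leftmost start. Three conventions needed fixing where the procedure is
usually left informal:

* the median is taken over *harboring samples only* — a cluster absent
  from a sample has no rank there; when one sample contributes several
  calls to a cluster, its strongest (minimum) rank represents it;
* the `top_n` cut (default 500) is applied to *clusters*, not to raw
  per-sample SEs; the parameter is exposed so either reading can be
  tested;
* ties at the cut are broken by higher recurrence, then leftmost
  interval, making the output fully deterministic.

Recurrence filtering keeps clusters present in at least `min_recurrence`
samples (default 20, inclusive). Gene annotation attaches every gene whose
TSS lies within `gene_window` bp (default 500 kb, inclusive at the bound)
of a retained cluster span, distance 0 inside the span. The final filter
keeps transcription factors whose TSS carries an H3K27ac peak — overlap
with TSS ± `tss_window` (default 1 kb; the underlying peak-caller cut-off
is upstream of this package) — in **all** samples harboring the SE. For a
gene annotated to several clusters, "harboring samples" is the *union* of
the clusters' member samples; a per-cluster reading is available via
`per_cluster = TRUE`, and a sample that harbors an SE but has no peak
table is a loud error rather than a silent fail.

Candidates are ranked by the raw median-split log-rank p-value, matching
the screen's original intent of a per-gene survival readout;
Benjamini–Hochberg adjusted values are reported alongside rather than used
for ranking. Candidates without expression data are retained, flagged
`survival_p = NA`, and sorted last.

## Survival scoring

`median_split()` labels samples strictly above the median "high" and the
rest "low"; ties sit at the boundary and deterministically go low, and a
constant vector is an error rather than an arbitrary split. The two-group
log-rank statistic (Σ(O − E))²/ΣV with a χ²(1) reference and the
product-limit curves are computed by the `survival` package
(`survdiff`/`survfit`); the suite cross-checks the statistic against an
explicit O − E/V hand computation to 1e−10 and the no-censoring KM curve
against the empirical survival function. Ties between an event and a
censoring time follow the standard convention (events first). With no
events the statistic is undefined and the function says so.

## Copy-number dosage

Focal gains over a locus are segments overlapping it by ≥ 1 bp with
log2 ratio ≥ 0.3 (inclusive) and size ≤ 5 Mb (inclusive) — both printed
inequalities taken literally. Arm gain is the *length-weighted* mean log2
ratio over the arm region with a *strict* > 0.3 cut (again as printed for
that rule); a sample with no segment on the arm is "unknown" and excluded
downstream, not coerced to diploid.

`dosage_anova()` fits `expression ~ stage × gain` as a fixed-effects
two-way ANOVA with type-II sums of squares (each main effect adjusted for
the other; robust to the mild imbalance of observational cohorts, and
identical to the classical decomposition when the design is balanced — the
property the test oracle exploits). Because the motivating observation is
a gain effect *within high-stage disease*, the headline quantity is the
one-way gain effect in the high-stage stratum, returned by `glance()`.
A factor with a single observed level is a named error. Under Gaussian
noise the headline p is exactly F-distributed, which is what the 2,000
replicate null-calibration check relies on.

## 4C interaction calling

The caller works on the binarized signal — a fragment is covered iff at
least one read maps to it — because raw 4C counts are dominated by PCR
duplicates near the viewpoint. For each fragment the covered fraction
`p_w` of a centered small window (`w = 100` fragments) is tested against
the local background fraction `p_W` of a centered large window
(`W = 3000`) with the one-sample proportion z statistic

$$ z = \frac{p_w - p_W}{\sqrt{p_W(1-p_W)/n_w}} $$

where `n_w` is the actual, possibly edge-truncated, small-window size.
The exact statistic behind the published description is not spelled out
beyond "a z-score on the binarized signal using sliding windows"; this
proportion-test definition is the simplest statistic consistent with that
description, and it is validated *behaviorally* — false-call control on
null tracks and recovery of planted windows — rather than against any
original script. Two guards matter numerically: a degenerate background
(`p_W` of 0 or 1) forces z = 0 instead of ±∞, and window truncation at
track ends enters the variance through `n_w`.

p-values are one-sided upper-tail normal, Benjamini–Hochberg adjusted
across all tested windows of the track (the procedure itself is a package
choice; no specific FDR method is prescribed upstream), significant at
q ≤ 1% in cis and q ≤ 0.5% in trans — so trans calls on a given z vector
are always a subset of cis calls. In cis mode, 200 fragments (2w) on each
side of the viewpoint are masked before testing: under-digestion and
self-ligation artifacts concentrate there and would otherwise dominate the
BH family. Consecutive significant windows are merged into maximal runs
for reporting. The normal tail is anti-conservative against the exact
binomial for small backgrounds, which is why the empirical false-call
check is stated with slack (≤ 2% at nominal FDR 1%) rather than at the
nominal level.

Display tracks use a centered moving average over `smooth_k = 21`
fragments, shrinking at the ends, scaled by 1e6/library size — "normalized
to the total library size" operationalized as reads-per-million.
Domainograms tabulate the covered fraction over a ladder of window sizes;
the row at size `w` reproduces the caller's `p_w` exactly, so the heat map
is a faithful picture of the test's foreground term.

## Drug synergy

Viability is percent of the vehicle control; values above 100% are clamped
to 100 *before* scoring so inhibitions stay in [0, 1], and negative
viability is treated as an upstream normalization bug. Excess over Bliss
is `i_obs − (i_a + i_b − i_a·i_b)` per combination cell; margins score 0
identically, and the surface transposes with the checkerboard. For
confluency time courses the per-condition effect at the chosen time point
is `1 − confluency/control` floored at 0: growth stimulation above the
control is read as "no inhibition", the same logic as the viability clamp,
since a negative inhibition would make the Bliss expectation incoherent.

## Signature scores and correlation

Within each sample genes are ranked ascending with average ranks for ties,
rescaled to [0, 1] as `(r − 1)/(G − 1)`, and the score is mean(up) −
mean(down), or mean(up) − 0.5 when the signature has no down set so that
an uninformative signature centers at 0. The published screens cite a
rank-scoring algorithm whose exact normalization is not reproduced here;
this definition was chosen for two testable properties — invariance under
monotone per-sample transforms, and antisymmetry under swapping up and
down sets — and the package's property tests depend only on those, not on
the scaling. `correlate()` operationalizes "Pearson if the
homoscedasticity assumption is met" as a Breusch–Pagan test on the y ~ x
residuals at α = 0.05, falling back to Spearman on rejection; the chosen
method is always reported with the coefficient.

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical structure each stage assumes,
at the study's scale:

* `simulate_se_landscape()` — 26 samples; one planted driver cluster
  harbored by 24 of them, always its sample's top-ranked SE; 30 decoy
  clusters with recurrence 5–26 and weaker signals; clusters anchored
  1 Mb apart so sweep clustering at the 500 bp default provably recovers
  exactly the planted clusters. A matching gene table and per-sample TSS
  peaks are emitted; each decoy TSS is marked per sample with probability
  0.98, so most recurrent decoy TFs survive the active-TSS filter and
  genuinely compete with the driver in the final ranking.
* `simulate_cohort()` — defaults n = 200 tumors (218 in the acceptance
  script's worked example, the cohort size of the motivating ANOVA);
  driver expression = baseline + 1 log2 unit × gain + N(0, 1) noise;
  survival exponential with hazard `h₀·HR^z` (HR default 2.5) on the
  standardized driver expression, independent exponential censoring
  (rates 1/1500 and 1/4000 per day, giving a realistically censored
  cohort); whole-arm segments at log2 ≈ 0.5 (gained) vs ≈ 0.
* `simulate_fourc_track()` — 5,000 fragments of independent Bernoulli
  coverage, p = 0.05 background vs 0.5 in planted 100-fragment windows.
* `simulate_checkerboard()` — 10 × 10 three-fold dilution series (the
  screen's 5.1 nM–33.3 µM and 0.051–333 nM ranges) from Hill curves,
  combinations under exact Bliss independence plus an additive planted
  synergy term, noise on the inhibition scale, clamped to [0, 100].

They deliberately do **not** emulate: read-level data or peak calling
(SE calls and segments are consumed, not computed), correlated fragment
coverage or distance decay in 4C (so the false-call check exercises BH
behavior under independence, not under Hi-C-like correlation),
copy-number breakpoint structure, non-proportional hazards, or
inter-plate drift in checkerboards. Passing the recovery and calibration
suites therefore demonstrates correctness of the computations and error
control under the stated models — not robustness to every artifact of
real ChIP/4C/viability data.

Every generator takes a mandatory integer seed and uses one local RNG
stream (`withr::with_seed`), so identical calls are byte-identical and no
global state leaks between stages.

## Problem sizes and runtime choices

The shipped checks use sizes at which every asymptotic approximation is
comfortable while the whole suite stays interactive: 1,000 random
instances (n ≤ 200) for the clustering oracle, 200 null tracks and 100
planted tracks of 5,000 fragments for the 4C caller, 50 landscape+cohort
pairs for driver recovery, 2,000 replicates (cohorts of n = 100; balanced
40-sample designs) for the null-calibration KS tests, and 100 noisy
checkerboards for the Bliss identity. The log-rank χ² reference is
asymptotic, so per-replicate cohorts below ~50 with heavy censoring will
show KS deviations that are a property of the approximation, not of the
implementation.

## Known limitations

* The prioritization is single-arm and single-cohort by design; pan-cancer
  comparisons, differential expression and motif/enrichment analyses are
  out of scope.
* The 4C caller assumes one chromosome per track and fragment-resolution
  input; it does not model distance decay, so cis calls very far from the
  viewpoint are conservative at best.
* `correlate()`'s Breusch–Pagan gate is itself a test with error rates;
  near α = 0.05 the selected method can flip between runs on resampled
  data.
* The dosage ANOVA treats stage as binary (high = stages 3–4); ordinal
  stage models are not implemented.
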