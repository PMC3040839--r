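---
title: "Detecting bimodal transcript expression with trimmed cluster branch heights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bimodal transcript expression with trimmed cluster branch heights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimodr)
```

## The problem

In a cohort of unrelated individuals, most transcripts vary unimodally
around a common mean on the log scale.  A minority split into two distinct
abundance classes — typically because a common *cis*-regulatory variant
(promoter indel, enhancer SNP) segregates in the population, as with the
−1607 1G/2G polymorphism of the *MMP1* promoter, where the 2G insertion
creates an ETS transcription-factor binding site and acts as a dominant
high-expression allele.  `bimodr` screens a normalized, log-scale
expression matrix (transcripts × individuals, at least four individuals)
for such transcripts, one transcript at a time.

## The statistic

Each transcript's `n` values are agglomeratively clustered: starting from
`n` singletons, the pair of clusters whose merge least increases the total
within-cluster sum of squares (Ward's criterion; dissimilarity between
individuals is `|x_i − x_j|`) is merged until one cluster remains.  The
inter-cluster distance at each of the `n − 1` merges is its *branch
height*.  Two height conventions are supported and verified against
`stats::hclust`:

* `"D2"` (default) — the minimum-variance form: `h² = 2·ΔESS`, as in
  `hclust(method = "ward.D2")`;
* `"D"` — the classical form obtained by applying the same Lance–Williams
  recurrence to unsquared distances (`hclust(method = "ward.D")`).

Because the bootstrap null (below) uses the identical statistic, empirical
p-values are internally consistent under either convention; `"D2"` is the
default because it is the variant with the exact minimum-variance
interpretation.  Equal-cost candidate merges are resolved toward the
smallest pair of minimum member indices, so results are identical across
platforms and input orderings.

A genuinely bimodal transcript concentrates the between-class gap in one
tall merge whose children both contain several individuals.  A single
aberrant individual also produces one tall merge — but its child is a
*singleton at the sample extreme*.  The default trimming policy
(`trim_policy("extreme_singleton")`) therefore discards every merge one of
whose children is a singleton holding the sample minimum or maximum (ties
resolved to the lowest individual index); at most two merges are removed
and a true two-cluster split is never touched.  The alternative
`edge_leaves_k` policy removes merges attaching any of the `k`
outermost-valued individuals as singletons; `k = 0` disables trimming and
is useful for sensitivity analysis, and `k ≥ 1` generalizes the default to
multiple suspected outliers per side.  The **trimmed maximum branch
height** is the transcript's bimodality statistic; it is nonnegative,
translation-invariant, and scales exactly with the data
(`stat(a·x + b) = |a|·stat(x)`).

With `n ≤ 3` every two-cluster split has a singleton side, so the scan
requires `n ≥ 4`; if trimming leaves no merges (possible only for tiny `n`
or aggressive `k`) the statistic is 0 and the transcript is flagged
`degenerate`.

## The bootstrap null and its calibration

The null hypothesis is a single normal population on the log scale.  For
each transcript a normal distribution is fitted by maximum likelihood
(mean = sample mean, sd with denominator `n`; the `n − 1` denominator is a
config switch), `B` datasets of size `n` are simulated from the fit, each
is clustered and trimmed identically, and

    p = #( null statistic ≥ observed statistic ) / B

Constant transcripts (`sd = 0`) cannot be bimodal: they are skipped with
`p = 1` and `degenerate = TRUE`.  A `(count + 1)/(B + 1)` correction that
avoids exact zeros is available but off by default; for plotting,
`−log2(p)` uses `max(p, 1/B)` so zero p-values remain finite.

One subtlety decides whether the screen's p-values mean what they claim.
The branch-height statistic is (nearly) proportional to the sample's
spread, so `stat/σ̂` is almost pivotal.  If the null replicates are drawn
unconditionally from `N(μ̂, σ̂)` (the *raw* plug-in bootstrap), the
observed statistic — roughly `c·σ̂` — is compared against replicates whose
own spreads are random around `σ̂`; the sampling noise of σ̂ is counted
twice and the resulting p-values pile up in the middle of the unit
interval.  Measured at `n = 15`, the raw comparison declares 0% of
truly-null transcripts significant at `p ≤ 0.1` and halves the power
against a planted 100-fold two-component signal.  A p-value meant to serve
as "the type I error rate you accept" must be uniform under the null, so
by default (`comparison = "studentized"`) each simulated dataset is
rescaled to have MLE standard deviation exactly equal to the fitted σ̂ —
the null datasets match the fitted parameters exactly rather than in
expectation.  This is equivalent to comparing the studentized statistic
`stat/σ̂` between the observed and simulated datasets, and by the usual
Monte-Carlo pivot argument the resulting p-value is exactly uniform under
normality (up to the `1/B` discreteness).  The unconditional plug-in
comparison remains available as `comparison = "raw"` for sensitivity
analysis; it is conservative, never anticonservative.

A pleasant by-product of drawing the replicates as standard normals and
rescaling, with per-transcript substream seeds derived from the master
seed independently of the data, is exact affine invariance: rescaling or
shifting a transcript's values changes `max_height` by exactly `|a|` and
leaves `p_max_height` identical.

## The scan and downstream steps

`bimodality_scan()` applies the statistic and bootstrap to every row,
never aborts on degenerate rows, and returns a table sorted by ascending
`p_max_height` then descending `max_height`, with columns
`transcript_id, OGS, max_height, p_max_height, n_boot, degenerate`
(written/read losslessly by `write_results()` / `read_results()` at six
significant digits).  Defaults mirror the screen's standard operating
point: `B = 10000`, `alpha = 0.1` — an accepted type I error rate of 10% —
extreme-singleton trimming, Ward `"D2"`, MLE sd, plain p-values.

`intersect_hits()` implements the cross-condition rule: transcripts with
`p ≤ α` in *every* condition (e.g. untreated and cytokine-treated cohorts
scanned separately), reported alphabetically.  Benjamini–Hochberg
adjustment (`adjust_bh()`, via `stats::p.adjust`) is available but off by
default: it does not change the ranking, and at cohort sizes of 9–15
individuals it is stringent enough to mask experimentally confirmed
bimodal transcripts; when enabled, adjustment is applied within each
dataset before intersection.  `render_diagnostics()` writes the
per-transcript dendrogram, the bootstrap-null histogram with the observed
statistic marked, and the dataset-wide `max_height` versus `−log2 p`
scatter.

`concordance()` quantifies genotype–expression segregation: under the
dominant-high model every carrier of the high allele is predicted high,
and the misclassified count is the number of individuals whose observed
class disagrees (1 of 69 in the bundled *MMP1* promoter table);
`exact_association_p()` gives the two-sided Fisher exact p for the
carrier-collapsed 2×2 table.  Expression classes are caller-supplied:
in practice they come from an independent assay (e.g. qRT-PCR), not from
the clustering itself, though the midpoint of the two cluster means is a
reasonable threshold when no assay is available.

## What the synthetic generator emulates

`synthetic_truth()` / `simulate_matrix()` produce matrices with the
structure the method assumes, plus planted departures:

* **null** transcripts — i.i.d. normal, per-transcript mean drawn from
  U(4, 12) and sd from U(0.2, 1), spanning the moderate-abundance,
  moderate-noise regime of log2 microarray intensities;
* **bimodal** transcripts — two normal components separated by 6.64 log2
  units (just over 100-fold, the scale of the *MMP1* high/low contrast)
  with shared within-class sd 0.5; class membership by Bernoulli(π = 0.3),
  by Hardy–Weinberg genotypes with a dominant high allele (low class only
  for low-allele homozygotes, expected frequency `(1 − q)²`), or by a
  fixed class count for deterministic planting;
* **outlier** transcripts — null plus one individual displaced by 8 sd,
  the artifact the trimming policy exists to reject.

The default cohort size in examples and checks is `n = 15` individuals,
a realistic primary-cell cohort.  The generator does *not* emulate
probe-level noise, normalization artifacts, missing values, correlated
transcripts, or heavy-tailed within-class distributions — so passing
calibration tests on it demonstrates correctness of the statistic under
its own model, not robustness to every failure mode of real arrays.
`estimate_error_rates()` closes the loop: it scans simulated matrices and
reports the empirical type I error (null transcripts called at α), power
(bimodal transcripts called), and the single-outlier false-positive rate.

## Numerical and design choices

* Heights are computed by the Lance–Williams recurrence in compiled code
  (`O(n³)` per transcript, microseconds at cohort sizes); Ward
  reducibility guarantees non-decreasing heights, and the implementation
  is tested to numerical precision against both `stats::hclust` and an
  exhaustive greedy ΔESS agglomerator written independently in R.
* Per-transcript bootstrap substreams are pre-drawn from the master seed,
  so scans are reproducible, order-independent, and affine-invariant.
* Checks at scale used in this package's own validation: 2,000 null
  transcripts × 15 individuals at `B = 1000` for calibration (measured
  type I error 9.8–10.3% across seeds at the 10% operating point), 400
  planted bimodal transcripts for power (96.5% at `p ≤ 0.1`), and 500
  single-outlier transcripts for robustness (false-positive rate 0% with
  trimming versus 68% with trimming disabled under the calibrated
  comparison).
* Fisher's exact p delegates to `stats::fisher.test`; tables with an
  empty margin return `p = 1` by convention.

## Limitations

The null model is a single normal per transcript: heavy-tailed or skewed
unimodal transcripts can exceed the normal null and surface as hits, which
is why visual inspection of the flagged dendrograms and histograms remains
part of the workflow.  The screen tests each transcript marginally — it
does not model correlation between transcripts, and with raw p-values at
`α = 0.1` roughly 10% of truly-null transcripts are expected per
condition; requiring hits in two independently assayed conditions (the
intersection rule) is the screen's practical false-positive control.
Values must be pre-normalized and complete: the package applies no
normalization and rejects missing values rather than imputing them.
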