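---
title: "Detecting line-specific expression outliers behind inbreeding depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting line-specific expression outliers behind inbreeding depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slldscan)
```

## The scientific question

Inbreeding depression — the loss of fitness that follows mating between
relatives — is expected, under standard population-genetics models, to be
caused largely by homozygosity for rare, partially recessive deleterious
alleles. Because such alleles are rare, the alleles fixed in different
inbred lines of the same base population should be *different*: the first
genetic causes of depression are line-specific, while downstream
physiological responses are shared. On a transcriptome this predicts a
distinctive signature: a gene whose expression is extreme only in the
sublines of *one* line, and only at *one* depression level (most depressed
or least depressed), is a candidate cause; a gene that shifts in every
inbred sample is more likely a response.

`slldscan` implements this candidate screen for the classic design it was
conceived for: four inbred lines (`a`–`d`), each contributing its three
most depressed and three least depressed sublines, plus three outbred
control arrays — 27 samples in all, with 24 inbred sublines eligible for
testing.

## The procedure

1. **Sequential Grubbs scan** (`sequential_outlier_scan`). For every probe
   and direction (down- or up-regulation), the one-sided Grubbs (extreme
   studentized deviate) statistic \(G = (\bar x - x_{(1)})/s\) of the 24
   inbred sublines is compared with the critical value
   \[
   G_{crit}(n, \alpha) \;=\; \frac{n-1}{\sqrt n}
     \sqrt{\frac{t^2_{\alpha/n,\,n-2}}{\,n-2+t^2_{\alpha/n,\,n-2}\,}},
   \]
   the Bonferroni-t closed form. If significant, the extreme subline is
   recorded (order 1), removed, the mean and standard deviation are
   recomputed, and the test repeats — up to `max_outliers` (default 3)
   calls per probe and direction.
2. **SL-LD classification** (`classify_slld`). A probe is a
   *single line–level of depression* (SL-LD) outlier when its first
   `n_outliers` calls (2 by default) all fall in sublines of one
   (line, level) cell.
3. **Randomization significance** (`randomization_test`). The observed
   SL-LD count is contrasted with its null distribution obtained by
   shuffling the (line, level) codes of the 24 inbred sublines by a
   uniform permutation — identically for every probe, with controls never
   randomized, and with each probe's outlier *identities held fixed*.
   Shuffling codes rather than expression values conserves the
   between-probe correlation of the outlier list, which is the point of
   the Westfall–Young-style construction: co-regulated probes produce
   coincident outliers under the null too, and the replicate distribution
   inherits exactly that dependence.
4. **Ladder summary** (`alpha_ladder`) repeats 1–3 over a descending
   ladder of test levels (default 0.10, 0.05, 0.025, 0.01) and both
   directions.
5. **Candidate characterization** (`correlation_with_without`,
   `correlation_significance`, `hierarchical_cluster`,
   `bootstrap_support`). Candidate genes are correlated pairwise over all
   samples and again after removing their outlier sublines (evidence of
   common regulation beyond the outliers themselves), with two-sided
   Student-t tests (\(t = r\sqrt{(n-2)/(1-r^2)}\), df \(= n - 2\) in each
   sample set) corrected by Benjamini–Hochberg over the unordered pairs;
   and clustered by complete linkage on the distance \(1 - |r|\), with
   plain bootstrap proportions (column resampling, exact leaf-set
   identity) attached to each node.

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)            # the canonical 27-sample design
sim <- simulate_expression(cfg)
calls <- sequential_outlier_scan(sim$matrix, sim$sheet,
                                 alpha = 0.05, direction = "down")
sl <- classify_slld(calls, sim$sheet, n_outliers = 2)
randomization_test(calls, sim$sheet, n_outliers = 2,
                   n_replicates = 10000, seed = 1)
```

## Parameters that matter

* `alpha` (Grubbs level, default 0.05): the per-probe, per-step test
  level. The \(\alpha/n\) construction inside `grubbs_critical` already
  accounts for "which of the n values is extreme"; no further
  multiplicity correction is applied within a probe's sequential chain —
  family-wise control over probes is the randomization test's job.
  One-sided levels are the default since each direction is scanned
  separately; a two-sided reading is available via `sidedness = "two"`.
* `n_outliers` (2 or 3): how many coincident outlier sublines define an
  SL-LD probe. Three-outlier coincidences are rare; two is the workhorse.
  With the default `match = "at_least"`, a probe with three calls is
  still judged on its first two; `match = "exactly"` restricts to probes
  with exactly two.
* `max_outliers` (default 3): cap of the sequential chain.
* `n_replicates` (default 10000): randomization replicates; p-values are
  plain proportions of replicates with a count at least the observed
  (`plus_one = TRUE` switches to the (k+1)/(R+1) correction).
* `most_comparison`: the published bar-chart annotation compares the
  count observed in most-depressed cells against the *whole* expected
  class count; `"total"` (default) implements exactly that conservative
  reading, `"half"` compares against half the replicate total (the other
  defensible reading, since the two levels have equal expected
  frequency). The reading used is recorded in the result object.
* `f` (inbreeding coefficient, default 0.7): used only to scale
  depression rates, \(IDR = (W_O - W_I)/(F\,W_O)\). Eight generations of
  strict full-sib mating give \(F_8 = 0.826\) by the recurrence
  \(F_t = (1 + 2F_{t-1} + F_{t-2})/4\) (`sib_mating_F`), and relaxing to
  two pairs per vial after generation 4 gives ≈ 0.76; the package keeps
  0.7 as the default constant because that is the value the design is
  quoted with, and exposes the recurrence as a documented utility rather
  than deriving the default from it.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 9000 probes, the
4 × 2 × 3 + 3 design, and within-line expression variances of 0.028
(controls), 0.044 (least depressed) and 0.086 (most depressed) on the
log2 scale. Noise is Gaussian per probe (reasonable for RMA-summarized
intensities); probes are correlated in consecutive blocks of 50 with
exchangeable correlation 0.3 — the simplest structure that makes
"conserving the correlation structure" non-trivial. The magnitude 0.3 is
a free parameter: no between-probe correlation is published for these
data. Planted effects are additive log2 shifts applied to whole sublines
(a fixed genetic alteration, not per-array noise); the default plants 14
down-regulated probes at \(\delta = -2\) in most-depressed cells, 6/3/2/3
across lines b, c, d, a, each affecting 2 of the 3 sublines so the
two-outlier pathway is exercised.

Productivity: subline means are placed at variance-controlled normal
quantiles around \(W_I = 34.28\) (spread 15 pupae/female, so per-subline
depression rates span beyond [0.7, 1.3] per unit F) and assigned to
sublines at random; replicate vials add 10 % proportional noise; control
vials are drawn around \(W_O = 101.97\). The quantile placement keeps the
grand inbred mean exactly on target while guaranteeing realistic spread —
a deliberate trade of a little realism for test stability.

Not emulated: probe-level (CEL) intensities and normalization artifacts,
present/absent-call filtering, heavy-tailed or skewed expression noise,
pedigree structure across the 8 generations, and any dependence between a
subline's productivity and its expression values. Passing tests therefore
demonstrate the statistical machinery under its stated model, not
robustness to microarray preprocessing.

## Numerical choices

* Ties at the Grubbs extreme break by first sample order,
  deterministically; constant rows yield no calls rather than an error
  inside the scan (the scalar `grubbs_statistic` does error on zero
  variance, as a direct query should).
* Critical values use the Bonferroni-t closed form; at n = 20, two-sided
  5 %, this gives 2.708, while some classical exact tables print 2.709 —
  a third-decimal difference without practical effect at n = 24.
* Expression matrices must be complete; missing values are rejected, not
  imputed.
* TSV numerics are written with `%.17g`, so result tables round-trip
  bit-identically.
* Gene order is sorted lexicographically before clustering so hclust tie
  handling cannot depend on input order; bootstrap replicates in which a
  gene becomes constant are redrawn.
* All stochastic stages take explicit integer seeds and are
  bit-reproducible given them.

## Design choices where the design was genuinely open

* **Direction handling.** Up- and down-regulation are scanned separately
  with one-sided tests (the published summaries split the two
  directions); a single two-sided scan is deliberately not the default.
* **Clustering sample set.** Dendrograms use all 27 samples (the
  candidate expression plots include controls); restricting to inbred
  samples is possible by subsetting the matrix first.
* **Reduced-sample degrees of freedom.** With two outlier sublines
  removed, n = 25 and the correlation t-test has 23 df — the published
  note's "23 d.f." is read as describing the reduced half of the table;
  the full-sample test uses 25 df. The note's "P>0.05" annotation on the
  *bold* (clearly significant) values is read as a typo for P<0.05; raw
  p-values are always reported so either reading is auditable.
* **Bootstrap support.** Multiscale-bootstrap AU values are out of scope;
  plain bootstrap proportions with exact leaf-set matching are reported
  instead. BP is known to be conservative relative to AU for well-sized
  clusters.
* **Viability filter.** The "enough individuals to analyse" exclusion
  when picking most-depressed sublines is exposed as an explicit numeric
  threshold (`min_viable`), defaulting to no filter.

## Problem sizes used by the test suite

Unit tests run on matrices of 40–2000 probes; the end-to-end checks use
the full 9000-probe design with 10 000 randomization replicates once, ten
repeated simulations at 1000 replicates for the direction contrast, and
200 null simulations at 1000 replicates for calibration — sizes chosen so
the whole suite completes in a few minutes on one core while keeping
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

The most important one is a property of the *method*, faithfully
reproduced here: the code-shuffling randomization assumes the
(line, level) codes are exchangeable across the 24 inbred sublines. The
design's own variance structure violates this — most-depressed sublines
have roughly twice the within-line variance of least-depressed ones
(0.086 vs 0.044), so Grubbs extremes concentrate in most-depressed cells
even when no line-specific effect exists, and coincident pairs land in
the same cell more often than the shuffled codes predict. On null
simulations with the study's variances, the test suite's calibration
check measures a rejection rate of roughly 0.2 at nominal 0.05 (it is
exactly calibrated when the group variances are made equal, which the
unit suite also verifies). Consequently an excess of SL-LD outliers in
the *most-depressed* cells is partly expected from heteroscedasticity
alone, and up-direction "significance" appears in a sizable minority of
null-true data sets. Users comparing levels should treat the
most-depressed excess as a joint signal of effects *and* variance
inflation, or verify findings against a variance-matched null. Other
limitations: Gaussian-only noise, a single exchangeable-block correlation
model, no support for missing values, and no upstream normalization.
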