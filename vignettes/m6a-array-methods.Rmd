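---
title: "Quantifying and comparing m6A methylation on two-color epitranscriptomic arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing m6A methylation on two-color epitranscriptomic arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meriparray)
```

## The measurement

MeRIP-based epitranscriptomic microarrays split each RNA sample into two
fractions before hybridization: an anti-m6A immunoprecipitate ("IP",
Cy5-labelled) containing the methylated transcripts, and the supernatant
("Sup", Cy3-labelled) containing the unmethylated remainder. Both fractions
are hybridized to the same probe set, so each probe yields a pair of
intensities per sample. Exogenous spike-in RNAs of fixed abundance are added
to both fractions and set the between-array scale.

For a probe with normalized linear intensities $IP$ and $Sup$, the package
computes three statistics:

* **methylation level** ("% Modified"): $IP / (IP + Sup)$, the fraction of
  that transcript carrying m6A — a within-sample ratio in $[0, 1]$;
* **expression level**: $IP + Sup$, total transcript abundance;
* **m6A quantity**: expression $\times$ methylation level, the absolute
  amount of modified transcript.

The three are mutually consistent by construction
(`expression * meth_level == m6a_quantity`, exactly).

## Normalization chain

`quantify()` composes the stages in this order:

1. **Spike-in normalization** (`spikein_normalize()`): per sample and
   channel, $\log_2(\text{raw})$ minus the mean of the log2-scaled spike-in
   intensities — i.e. division by the spike-ins' geometric mean on the linear
   scale. Channel-specific means are the default; they cancel any
   per-sample, per-channel multiplicative dye effect, which is exactly the
   distortion the spike-ins exist to remove. A pooled two-channel mean is
   available (`shared_spikein_mean = TRUE`) for designs where the two
   channels share one spike-in cocktail measurement.
2. **Quantile normalization** (`quantile_normalize()`, backed by
   `limma::normalizeQuantiles`): applied to the linear expression
   ($IP + Sup$) matrix, before flag screening. Every sample is forced onto
   the common distribution (the row-wise mean of the sorted columns; ties
   averaged). The implied per-sample adjustments are deliberately **not**
   propagated into the methylation level, which stays a within-sample ratio:
   a between-sample distribution adjustment has no business inside a
   within-sample fraction. The m6A quantity is defined downstream of both:
   normalized expression times methylation level.
3. **Flag filter** (`filter_by_flags()`): a probe is kept when it is called
   Present or Marginal in at least `min_present` samples (default 1), both
   groups pooled — the "All Targets Value" rule, generalized from "1 in 10
   samples" to however many samples are loaded.

Degenerate inputs are handled explicitly rather than propagated as
surprises: a (probe, sample) whose total linear intensity falls at or below
$\varepsilon = 2^{-20}$ becomes `NA` (missing, not zero) and is excluded
pairwise from group comparisons; a single-column matrix passes through
quantile normalization unchanged with a warning; missing spike-ins are an
error, not a silent skip.

## Differential analysis

Fold changes are always T (patients) relative to N (controls), so a negative
log2 fold change means "lower in patients". Each probe carries both
conventions seen in published top-tables: the linear ratio of group-mean
methylation levels (`fc_meth_ratio`) and log2 group-mean differences for m6A
quantity and expression (`fc_m6a_log2`, `fc_ge_log2`). P-values come from
two-sided unpaired t-tests — pooled-variance Student by default, Welch
selectable — applied to the methylation level, log2 m6A quantity and log2
expression. Zero-variance groups take the documented limits ($p = 1$ for
equal means, $p = 0$ otherwise) instead of erroring.

The regulation class assesses two independent axes at level $\alpha$
(default 0.05, the conventional reporting level; fold-change cutoffs default
to sign-only because published tables rarely print theirs):
hyper-/hypo-methylation from the m6A axis and up-/down-regulation from the
expression axis. A probe significant on both gets one of `Hyper-up`,
`Hyper-down`, `Hypo-up`, `Hypo-down`; anything else is `ns`. The m6A
**quantity** is the default methylation axis — its log2 convention matches
the printed "Foldchange (log2-Scaled) m6A" columns — with the methylation
**level** ratio selectable (`axis = "meth"`), since published tables use
both conventions and never say which drives the class.

No multiple-testing correction is applied by default (published tables print
raw t-test p-values); `adjust = TRUE` appends Benjamini–Hochberg columns
without changing the classification.

`hierarchical_cluster()` sorts items by name before agglomeration so the
tree is invariant to input order (hclust's tie-breaking otherwise depends on
it), uses average linkage on Euclidean distances by default, and serializes
to Newick via `ape`.

## Association and enrichment statistics

Cohort tables print only group summaries, so `t_test_from_summary()`
implements the pooled-variance t-test from (mean, SD, n) alone; it is
constructively identical to the raw-data test on any sample with those
moments. The sex-ratio test is a Pearson chi-square without continuity
correction — on cohorts of ~15 per arm that is the statistic whose p-value
matches published cohort tables — with Yates correction and a t-test on
binary codes available. `pearson_correlation()` uses the exact t-transform
with $n - 2$ degrees of freedom rather than a normal approximation because
the correlations of interest are computed on as few as 10 + 10 samples.

`fisher_enrichment()` is one-sided (enrichment only): the hypergeometric
upper tail of the overlap between a hit list and each gene set, both
intersected with a declared background universe, scored as $-\log_{10} p$.
The recommended background is all flag-surviving probes collapsed to unique
gene symbols — the array defines what was measurable. No GO-graph
decorrelation is attempted; sets are tested as given in the GMT.

## What the simulator emulates — and what it does not

`generate_dataset()` draws per-probe baseline log2 expression
$\mathcal N(10, 1.5^2)$, a baseline methylation level uniform on
$[0.2, 0.8]$ (away from boundary saturation), and splits each probe's
abundance into IP and Sup so that the noiseless % Modified equals the
configured level exactly. Planted differential methylation adds a signed
log2 shift (default $-3$, the magnitude of published top hypo-methylated
transcripts) to the IP channel of `round(frac * n_probes)` seeded-sampled
probes in group T; differential expression shifts both channels. Defaults
mirror the study design this pipeline addresses: 5 + 5 samples, 8 spike-ins,
iid Gaussian log2 noise with SD 0.5 (arrays publish no noise model; 0.5 is a
realistic within-group spread for two-color arrays and is fully exposed in
the config), a 5% Absent-flag rate, and a 10% planted fraction each way.

The simulator is honest about what it omits: no probe-sequence or
GC-content effects, no spatial artifacts, no background signal, no
intensity-dependent (loess-shaped) dye bias, no correlated noise across
probes. Passing tests therefore demonstrate that the pipeline's arithmetic,
contracts and statistical calibration are right under a clean generative
model — not that it corrects artifacts it never models. One visible
consequence of the clean model plus quantile normalization: with a sizable
planted fraction, the normalization's common target distribution slightly
attenuates recovered log2 fold changes (a planted $-3$ comes back around
$-2.9$); the tests budget for this.

## Problem sizes and calibration checks

The test suite and the acceptance script run at desk scale, chosen so the
binomial arithmetic is meaningful: type-I calibration of the differential
m6A call uses a null simulation of 2 000 probes at 5 + 5 samples (the
observed rate at $\alpha = 0.05$ must sit inside the 99% binomial band);
power monotonicity uses 300 planted hypo-methylation effects at three effect
sizes and two group sizes. Worked examples from published tables (cohort
summaries, 20-row top-tables) are exact-arithmetic checks and run in
milliseconds.

## Known limitations

* Within-array spatial and intensity-dependent normalization
  (background subtraction, loess) are out of scope; inputs are assumed to be
  feature-extracted intensities.
* The flag filter treats P and M identically, as the "All Targets Value"
  rule does; no weighting by flag quality.
* Enrichment treats gene sets as flat lists; GO hierarchy handling belongs
  to dedicated tools.
* The classification thresholds are study choices, not estimates; the
  package exposes them and defaults to the least-assuming reading
  (sign-only fold change at $\alpha = 0.05$).
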