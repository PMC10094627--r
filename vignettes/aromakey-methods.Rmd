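---
title: "Methods: semi-quantification, PLS-DA and OAV screening of tea volatiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantification, PLS-DA and OAV screening of tea volatiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromakey)
library(dplyr)
```

aromakey analyses non-targeted GC–MS volatile flavor compound (VFC) surveys
of the kind used in tea aroma chemistry: many samples from a handful of
producing districts, each injected several times, each injection yielding a
peak area per identified compound. The pipeline answers three questions in
sequence. How much of each volatile is present (semi-quantification and
class profiling)? Which volatiles differ between districts (PLS-DA with VIP
selection, validated by permutation)? And which of those differences can a
human nose actually perceive (odor-activity-value screening)?

## Semi-quantification

Every extraction is spiked with a fixed amount of ethyl decanoate
(20 µL at 0.02 mg/mL, i.e. 400 ng). The relative concentration of compound
$c$ in injection $i$ is

$$\mathrm{conc}_{ic} \;=\; \frac{A_{ic}\, m_\mathrm{IS}}{A_{\mathrm{IS},i}\, m_i}
\quad [\mathrm{ng/g\ dry\ mass}],$$

with $A_{ic}$ the compound's peak area, $A_{\mathrm{IS},i}$ the
internal-standard area of that injection, $m_\mathrm{IS}$ the
internal-standard mass (ng) and $m_i$ the dry tea mass (g). The printed
layout of such formulas is occasionally ambiguous; this is the only
parenthesization with ng/g units, and it is what `semi_quantify()`
implements. It is a *semi*-quantification: one shared response factor, no
per-compound calibration curves, so values are comparable across samples
and compounds only in a relative sense.

Group-level concentrations (`group_mean_concentrations()`) average over all
injections carrying the group label, i.e. samples × replicates. With
balanced replicate counts this equals the mean of per-sample means; for
unbalanced input every injection still counts once, which slightly
up-weights samples with more injections. Class shares
(`class_proportions()`) are computed on these group means, matching the
convention of reporting "average relative concentration" per district,
rather than per-injection shares averaged afterwards; the difference is
second order.

## PLS-DA

`fit_plsda()` is a from-scratch NIPALS PLS2 on autoscaled data. Choices a
reader should know about:

* **Preprocessing.** Unit-variance scaling plus mean centering of both the
  predictor block and the dummy-coded response. Concentrations span four
  orders of magnitude across compounds; without autoscaling the model would
  only see the most abundant volatiles.
* **Observation unit.** Every replicate injection is a row (6 per sample),
  and the class is the district group. Replicates of one sample cluster
  tightly in score space, which is itself a useful repeatability check.
* **Initialization and convergence.** The starting $u$ is the response
  column with the largest variance; iteration stops when the weight vector
  changes by less than $10^{-10}$ (max 500 iterations). Each weight
  vector's largest-magnitude element is made positive, so score plots are
  reproducible down to sign.
* **Diagnostics.** $R^2X$ and $R^2Y$ are cumulative explained-variance
  fractions from the deflation; $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$ from
  7-fold interleaved (venetian-blind) cross-validation with scaling
  re-estimated inside each training fold. Interleaving matters because
  replicates are consecutive rows: contiguous folds would hold out whole
  samples, interleaved folds hold out single injections, which is the
  convention of the chemometrics software this emulates. A response class
  entirely absent from a training fold raises a warning and its held-out
  deviance counts against the model.
* **Component count.** With `ncomp = "auto"`, components are added while
  cross-validated $Q^2$ improves by more than 0.01, capped at
  $\min(10, n-1, p, G)$.

VIP scores follow the standard weighted form
$\mathrm{VIP}_j = \sqrt{p \sum_a s_a w_{aj}^2 / \sum_a s_a}$ with $s_a$ the
response sum of squares explained by component $a$; the identity
$\sum_j \mathrm{VIP}_j^2 = p$ is asserted in the tests. Compounds with
VIP > 1 are the differential set.

Permutation validation (`permutation_test()`) refits the model at fixed
component count under randomly permuted labels, recording permuted $R^2Y$
and $Q^2$ against the mean absolute column-wise correlation between the
permuted and original dummy response. The reported intercepts come from
least-squares lines through all permutations plus the original model at
correlation 1. A trustworthy model keeps every permuted $Q^2$ below the
original and drives the $Q^2$ intercept negative.

Hotelling's $T^2$ 95% region in the two-component score plot uses the
standard small-sample form: semi-axis
$s_k \sqrt{\tfrac{2(n-1)(n+1)}{n(n-2)} F_{0.95}(2, n-2)}$ along component
$k$. Coverage is verified by Monte Carlo at $n = 10^4$ in the tests.

## OAV screening

The odor activity value of compound $c$ in group $g$ is the group-mean
concentration divided by the compound's odor threshold in air (same ng/g
basis). OAV > 1 means perceptible. A *key active differential odorant*
must clear both gates strictly: VIP > 1 and maximum group OAV > 1. Group
means, not per-sample maxima, feed the OAV, matching the one-OAV-per-
district convention of the reference panel shipped in
`inst/extdata/key_odorant_oav.csv`. Compounds without a tabulated threshold
are excluded from OAV and reported, never imputed.

"Significantly higher in its top district than everywhere else" is not a
single standard test; `top_group_flags()` operationalizes it as one-sided
Welch t-tests of the top group against each other group with Holm
correction, `**` when all adjusted p-values fall below 0.01 and `*` below
0.05. Districts represented by a single sample still contribute six
replicate injections, but their within-group spread is technical rather
than biological; `screen_compounds()` lists such groups so the flags are
read with appropriate caution.

One-way ANOVA per compound uses the classical fixed-effects F test on
injection-level concentrations; the degenerate all-identical case returns
$F = 0$, $p = 1$ rather than an error.

## The synthetic survey generator

No public peak-level dataset accompanies the survey this package is built
around, so `simulate_peak_table()` generates one with the statistical
structure the analysis assumes: 31 samples in 8 district groups
(12/3/4/6/3/1/1/1), 6 replicate injections each, and 135 compounds in the
12 classes (24 alcohols, 25 heterocyclics, 9 aldehydes, 17 ketones, 10
alkenes, 6 acids, 9 aromatic hydrocarbons, 17 esters, 9 alkanes, 3 amino
acids, 5 phenols, 1 N-compound).

**Calibration.** Eleven published (compound, district, mean concentration)
triples anchor the marker field — e.g. linalool at 2066.04 ng/g in
YJ-Yingde, phenylethyl alcohol at 1621.01 ng/g in Heyuan, *p*-cresol at
3.66 ng/g in Chaozhou. Odor thresholds for the eight key odorants are
back-derived as anchored concentration ÷ published OAV (the thresholds
themselves are not published), so the screening stage reproduces the
published OAV panel by construction at its anchor cells. The published
record is internally inconsistent for geraniol (its Meizhou concentration
and the panel's Meizhou OAV cannot share one threshold with the Lianshan
pair); the threshold is anchored at the panel's row maximum (Lianshan) and
the printed Meizhou mean is kept, so its implied OAV exceeds the panel
value. Panel cells censored as "<1" are fixed at OAV 0.5. Remaining key
cells are filled as panel OAV × threshold. Background compounds receive
group-independent means drawn once (frozen internal seed, independent of
the simulation seed) from class-specific budgets chosen so that every
group's alcohol share lands mid-band in the published 31.40–44.43% range,
and the ester, aldehyde and ketone shares inside their published bands. A
few secondary compounds carry modest district elevations (e.g. D-limonene
in YJ-Yingde, benzyl alcohol in HY-Yingde) mirroring reported
district-specific clustering. Non-key thresholds default to 10× the
compound's across-group mean, keeping its OAV below 1 everywhere — so the
calibrated key-odorant set is exactly the published eight.

**Noise model.** Concentrations are positive and GC–MS intensities
classically log-normal, so noise is multiplicative lognormal at two
levels, each with unit mean: a between-sample factor with total CV 0.25 and
an injection-level factor with CV 0.08. The between-sample factor is
itself the product of a shared per-sample extraction-efficiency factor
(CV ≈ 0.23) and a compound-specific factor (CV 0.10), combining to the
stated total. The shared part models the dominant real-world source of
sample-to-sample variation (extraction and injection efficiency scale all
compounds together) and cancels in composition shares, which is why class
shares are stable across seeds while individual concentrations vary with
the full 25% CV. The source survey states no noise model; these are this
package's choices.

Peak areas are emitted by inverting the semi-quantification formula, with
a lognormal internal-standard area (CV 0.05) per injection that cancels
exactly on quantification. In the noise-free limit (all CVs zero) the
pipeline recovers the configured concentration field to floating-point
accuracy — an identity the tests assert.

**What the generator does not emulate:** retention times, spectra and
co-elution; compound-compound correlations beyond class budgets;
non-detects and censoring; batch or run-order drift; heavier-than-lognormal
tails. Consequently, passing tests show the *pipeline* is correct and the
published pattern is recoverable under the stated design, not that the
method would behave identically on real chromatograms.

## Problem sizes and numerical choices

The default survey is 186 injections × 135 compounds; tests run the full
pipeline once (a few seconds) and the 200-permutation validation once
(about two minutes), with smaller randomized instances (n ≤ 60) for
property checks — sizes chosen to exercise the full design while keeping
the suite quick. Ties in hierarchical clustering are resolved by the
agglomeration backend's deterministic item-index ordering; Ward linkage
uses the squared-distance ("ward.D2") update. Correlation distance falls
back to euclidean, with a warning, when a constant vector makes it
undefined. Z-scored heat-map intensities are clipped at ±4, matching the
0–±4 intensity range conventional in published tea-volatile heat maps.

## Known limitations

* Semi-quantified ng/g values inherit the single-response-factor
  assumption; OAVs built on them are comparative screening indices, not
  sensory predictions.
* Single-sample districts make "significantly higher" claims rest on
  technical replicates alone.
* The auto component rule (ΔQ² > 0.01) is a heuristic; very small groups
  (6 injections) contribute little to PRESS and can be under-modeled.
* The generator's calibration reproduces published group means and class
  shares, not the full covariance of real tea volatilomes.
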