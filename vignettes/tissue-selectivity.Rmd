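---
title: "Integrating expression compendia and scoring tissue-selective genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating expression compendia and scoring tissue-selective genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tselex)
```

## The problem

Public repositories hold thousands of Affymetrix expression profiles of
normal human tissues, generated by different laboratories for different
purposes. Two obstacles stand between those profiles and a genome-wide view
of tissue-selective expression: the profiles are not on a common scale, and
profiles of the same tissue are not biological replicates — a
tissue-selective transcript may be detected in only a fraction of the
arrays of its own tissue (developmental stage, region, condition), while
microarray noise plants spurious detections elsewhere.

`tselex` implements a two-stage answer. First, heterogeneous profiles are
combined into a single *compendium*: arrays are normalized within
tissue-homogeneous groups by the invariant-set method, summarized (when
starting from probe-level data) with a multiplicative model-based index,
screened for outlier arrays, and placed on a common scale by dividing every
profile by its own median. Second, for a chosen target tissue, every probe
set is scored by a two-part *priority score* that uses both the
quantitative expression values and the qualitative detection calls, and the
score's significance is assessed by permutation.

## The scoring model

For a target tissue the samples split into an *experiment set* (size
$N_e$) and a *control set* of all other tissues (size $N_c$). A
measurement shows **significant expression** when its detection call is
Present *and* its relative expression value is at least a threshold
$\theta$ ($\theta \ge 0$; with $\theta = 0$ the predicate is purely
call-driven; $\theta = 1$ means "at least the array median" after the
median transformation). Per probe set, $S_e$ and $S_c$ count significant
expression in the two sets, and candidates must satisfy $S_e \ge min$ and
$S_c \le max$ (both inclusive).

The two score components are

$$Score_1 = \log_{10}\frac{(S_e + \alpha)/N_e}{(S_c + \alpha)/N_c},
\qquad
Score_2 = \log_{10}\frac{\bar E_e}{\bar E_c},$$

with the overall priority score $Score = w_1 Score_1 + w_2 Score_2$
(defaults $w_1 = w_2 = 1$). $\bar E_e$ is the mean expression over exactly
the $S_e$ experiment arrays with significant expression. $\bar E_c$ is the
mean of the *top* $S_e$ control arrays by expression — a deliberately
conservative comparison: the candidate must beat the controls where the
controls are strongest. Probe sets with $Score_2 \le 0$ are dropped.
Ranking is by descending score, ties broken by probe id.

The pseudocount $\alpha = 0.1$ keeps $Score_1$ finite when $S_c = 0$ (the
common case for a clean tissue-specific gene) and its placement is
symmetric in $S_e$ and $S_c$. This closed form reproduces published
reference scores for brain, liver and testis marker genes to the printed
two decimals (see `tests/testthat/test-acceptance.R`), which is how the
form was validated; at printed precision a pseudocount on $S_c$ alone is
indistinguishable, and the symmetric form was adopted.

Significance is a permutation test at the probe-set level: the per-sample
(value, call) *pairs* are permuted jointly — the pairing is what the score
consumes, so it must survive the shuffle — re-split into sets of the same
sizes, and fully re-scored (including the top-$S_e$ control mean).
Permutations with $S_e = 0$ or a non-positive fold score $-\infty$. The
p-value is the plain fraction of permutations at or above the actual score
(matching the published convention of reporting a zero count as a bound,
e.g. $p < 10^{-6}$ at one million permutations), not the $(k+1)/(N+1)$
estimator. The permutation kernel is compiled (Rcpp) with a self-contained
splitmix64 generator; each probe set's substream is derived from the user
seed and a hash of the probe id, so p-values are bit-reproducible and
independent of evaluation order or parallel scheduling.

## Normalization and integration choices

**Baseline selection.** Within a normalization group the baseline is the
array whose overall intensity (arithmetic mean) is the group median; for an
even group size the lower middle array is taken (deterministic, no
averaging of arrays). "Overall intensity" as the mean is the conventional
summary; the median refers to the selection among arrays.

**Invariant set.** Probes whose ranks agree between the target array and
the baseline are assumed non-differentially expressed. We iterate: rank
both arrays within the current candidate set, keep probes with relative
rank difference below the current fraction, shrink the fraction, and stop
on stabilization, at 30 iterations, or before the set would drop below the
minimum size (200 for full-length arrays, scaled down proportionally below
4,000 probes, floor 10). Defaults (`initial_fraction` 0.05,
`shrink_factor` 0.9) are reconstructions: the original tooling's exact
thresholds are not published, so they are documented as choices that
behave well on synthetic data, not asserted as faithful.

**Curve.** The normalization map is a running-median curve (window 101
pairs, or n/10 for small sets) through the invariant pairs, made monotone
by isotonic adjustment, interpolated piecewise-linearly, extrapolated
linearly beyond the end knots, and clamped at zero. Compared with the
original smoothing spline this is parameter-light and guarantees
monotonicity; remaining differences are absorbed by the rank-robust
downstream scoring.

**Summarization.** When probe-level PM/MM data are available, PM−MM
differences are fit to the rank-1 model $y_{ji} = \theta_i \phi_j$ by
alternating least squares under the convention $\sum_j \phi_j^2 = J$.
Negative differences are kept for fitting (flooring first would bias
$\theta$); expression values are floored at zero only on output. Outlier
cells are marked at 3 robust SDs against a *median-based* preliminary fit:
a grossly corrupted array has enough leverage on the least-squares factors
to hide its own residuals, while median updates follow the consensus of
the clean arrays. An array (or probe) with more than half of its cells
marked is excluded and the model refit once — once, not iteratively, to
bound runtime. Arrays flagged in more than 15% of probe sets
(strict inequality; exactly 15% is kept) are discarded from integration.

**Detection calls.** The upstream software's call algorithm is not
published; we use the closest documented convention, a one-sided Wilcoxon
signed-rank test of PM − MM > 0 with Present/Marginal cutoffs 0.04/0.06.
Zero differences are discarded; an all-zero probe set is Absent. In the
primary input path calls are supplied externally as a P/M/A matrix, so
this module is optional.

**Median transformation.** Each profile is divided by its own median;
with an odd probe count every integrated profile then has median exactly
1.00 (the even case is exact only up to one floating-point rounding of the
midpoint mean, which is why the simulator defaults to an odd probe count).
A profile with median ≤ 0 is an error, never silently shifted: real array
profiles have positive medians, and a shift would corrupt every fold
downstream.

## What the simulator states, and what a green test establishes

`simulate_compendium()` emulates the statistical structure the method
assumes, with defaults chosen once as the stated world of the validation
suite: 5 tissues × 20 samples, 2,001 probe sets (odd, see above), 20
planted selective genes per tissue with folds uniform in 10–50, Present
probability 0.9 in the target tissue and 0.005 leakage elsewhere,
lognormal(0, 1) background, per-study scale factors uniform in 0.5–2 with
two studies per tissue. Background calls are Present with logistic
probability in the log-ratio of the value to its sample median (slope 1.2),
calibrated so roughly half of background cells are Present, matching
realistic call rates; non-Present background cells are Marginal with
probability 0.1. The recovery tests use `min_se = 4` (20% of $N_e$,
mirroring the published small-tissue parameterizations) and `max_sc = 2`:
at $N_c = 80$ the published "~1% of controls" rule degenerates to zero and
would reject planted genes for a single binomial leak, so the cap is set a
priori at 2.5% of controls.

The simulator does not emulate probe-sequence effects, GC bias,
cross-hybridization structure, correlated tissues (e.g. brain regions), or
real probe-set annotations. A green recovery test therefore establishes
that the pipeline's logic is correct under its own model assumptions — not
that the method's published biological candidate lists are reproduced;
those require the original 2,968-profile compendium, which is out of
scope. The published per-gene scores *are* reproduced exactly from their
printed inputs, and the permutation machinery is checked against a
uniform-null calibration and an analytic hypergeometric bound.

## Numerical conventions

* Candidate filter bounds inclusive on both sides; `min`/`max` accept
  absolute counts or percentages of $N_e$/$N_c$ on the command line.
* Top-$S_e$ control selection breaks ties toward the lower sample index
  (stable `order()`), so results are seed-independent.
* Permutation tie comparison uses a `1e-9` absolute tolerance so that a
  permutation reproducing the actual configuration counts as a tie
  regardless of floating-point accumulation order (an exchangeable
  constant row yields p = 1 exactly).
* Default filter when unset: `min_se` = 10% of $N_e$ (floor 1), `max_sc` =
  1% of $N_c$, both rounded down — the published case studies' rules.
* TSV matrices round-trip bit-identically (values written at 17
  significant digits); duplicate probe ids are an error, never collapsed.

## Known limitations

* Cross-group batch effects beyond per-profile median scaling are not
  modelled (no empirical-Bayes batch correction); the method relies on the
  call-frequency contrast being robust to residual scale differences.
* The invariant-set defaults and the detection-call thresholds are
  reconstructions of unpublished settings (see above).
* p-values are per probe set; no multiplicity correction across the
  genome is applied, matching the published reporting.
* Probe-set-to-gene mapping is out of scope; rankings are per probe set.
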