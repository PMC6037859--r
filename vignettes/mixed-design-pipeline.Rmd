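---
title: "Simulating and analysing SJ/TOJ mixed block/event-related fMRI experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing SJ/TOJ mixed block/event-related fMRI experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synctoj)
```

## The scientific problem

Synchrony judgments (SJ: "were the audio and video in synch?") and temporal
order judgments (TOJ: "which came first?") are the two standard probes of
audiovisual temporal perception, and despite using identical stimuli they
measure partly different processes. Comparing their neural correlates
requires (i) per-subject psychometric modeling to derive the point of
subjective simultaneity (PSS) and temporal integration window (TIW) and to
identify subjects who simply cannot do the TOJ, (ii) an fMRI design that can
separate *sustained* (block/state-level) from *transient* (event-level)
BOLD responses, and (iii) a two-timescale GLM and group inference. This
package implements that full chain together with a synthetic-data generator,
so every stage can be validated against known ground truth on a laptop.

## Psychometric models and fitting

Responses at a signed cue onset asynchrony $x$ (ms; negative = audio leads)
follow

$$P_{SJ}(x) = A \exp\!\left(-\frac{(x-\mu)^2}{2\sigma^2}\right), \qquad
  P_{TOJ}(x) = \Phi\!\left(\frac{x-\mu}{\sigma}\right),$$

so the SJ PSS is the Gaussian peak, the TOJ PSS the 50% point, and the TIW
the standard deviation of either curve. The description of the original
fitting procedure mixes "least squares" with "maximum likelihood", which are
different objectives; we minimize the sum of squared errors between
per-level observed proportions and the model, the reading consistent with
fitting a Gaussian to response proportions. `optim(method = "L-BFGS-B")`
runs from 8 deterministic starts (4 PSS locations spanning the COA range
crossed with 2 window widths) with box constraints
$\sigma \ge 1$ ms and $A \in (0, 1]$; the best SSE wins.

Goodness of fit is $R^2 = 1 - SS_{res}/SS_{tot}$ over per-level
proportions, and TOJ ability is gated at $R^2 \ge 0.5$. Two choices matter
at the boundary: (1) constant response proportions (a completely biased
responder) make $SS_{tot} = 0$; we define $R^2 = 0$ there, so such data are
always unable — the conservative reading, since un-fittable data should
never pass the gate. (2) $R^2$ exactly 0.5 counts as able; the original rule
states only strict inequalities on both sides and the boundary has measure
zero. Note $R^2$ can be negative for data the model fits worse than a
constant (typical for coin-flip responders); the gate handles that
naturally.

PSS stimulus levels must be realizable in whole 60-Hz video frames. One
frame is $1000/60 = 16.\overline{6}$ ms (the conventional rounding "16 ms"
conflicts with "one frame"; we use the exact value and report milliseconds
rounded where needed), and quantization clips at $\pm 20$ frames
($\pm 333.33$ ms) with ties resolved toward zero. For TOJ-unable subjects,
whose own TOJ PSS is meaningless, `assign_fallback_pss()` substitutes either
a configured constant (e.g. a group mean from a prior study with the same
stimuli, which is not printed anywhere we can recover) or the mean PSS of
the able fits at hand.

## What the behavioral generator emulates

`make_cohort()` draws subject profiles from uniform ranges centred on the
group statistics typical for point-light drumming stimuli: SJ PSS in
[20, 120] ms (video-leading, mean ≈ +70), SJ TIW in [80, 180] ms
(≈ 127), TOJ PSS in [−200, 90] ms (audio-leading on average, ≈ −55), TOJ
TIW in [100, 300] ms (≈ 190), SJ amplitude in [0.7, 1]. Unable subjects
come in the two phenotypes seen empirically — random responding and
complete bias toward one response — split 50/50 because their relative
frequency is not reported anywhere; the split is configurable, not
inferred. Responder modes affect only the TOJ task: empirically, TOJ-unable
participants still produce orderly SJ data, and the generator follows that.

The generator emulates binomial trial-count noise at each COA level. It
does **not** emulate lapses, attention drift across blocks, learning, or
any dependence between trials, so a green recovery test establishes that
the estimator is consistent under the stated model — not that real data are
this clean.

## The mixed design and its optimization

A run is fully determined by combinatorial constraints plus randomization:
32 stimulation blocks of exactly 25 s (16 per task), each holding 5 stimuli
of 3 s separated by 4 fixations whose durations are a permutation of
{1, 2, 3, 4} s; a 4-s instruction precedes every block (the in-scanner
instruction duration is not stated; we mirror the behavioral session's
4 s); a 16-s fixation block follows every second stimulation block. Per
task and run each COA condition appears 20 times, distributed over the 16
same-task blocks as 0×4 / 1×6 / 2×4 / 3×2 — this within-block jittering of
condition composition is what decorrelates event-level from block-level
regressors. `assign_block_composition()` finds such an assignment by
randomized depth-first backtracking; the constraint system is satisfiable
(16 rows of sum 5 against column multisets summing to 20 each) and the
search succeeds in practice on every seed we have tried.

Design matrices are built at 0.1-s microtime: sustained regressors are
25-s boxcars, transient regressors unit-mass impulses at stimulus onsets
(an isolated event's column is exactly the HRF shifted to its onset), all
convolved with the canonical double-gamma HRF (delays 6/16 s, dispersions
1/1, peak:undershoot 6, 32-s support, peak-normalized — "canonical" is
otherwise underspecified, so we use the conventional parameterization) and
sampled at TR = 2 s at the start of each volume. Six zero-valued motion
placeholders and the constant bring the count to 18 columns, matching a
realignment-corrected session's layout.

`optimize_design()` scores each candidate by

- *efficiency*: mean over the 10 unit contrasts of interest of
  $1/(c^\top (X^\top X)^{-1} c)$, with the instruction and constant columns
  present as nuisance;
- *mean sustained–transient correlation*: the mean of the 8 absolute
  Pearson correlations between each transient column and its same-task
  sustained column, computed before high-pass filtering. Cross-task pairs
  are near zero by construction and would only dilute the metric.

The published procedure "balances" the two without stating how; we
standardize both across candidates and select
$\arg\max\, [z(\text{eff}) - z(\text{corr})]$, which is monotone in both
criteria. Selected designs land near 0.40–0.45 mean correlation, the range
in which both timescales remain estimable.

One subtlety the score table exposes (`efficiency_sustained`,
`efficiency_transient`): the pooled 10-contrast efficiency is dominated by
the two sustained contrasts, whose candidate-to-candidate variance has
little to do with block/event collinearity, so the pooled metric's negative
rank correlation with the sustained–transient correlation is real but weak
(≈ −0.05 over 1000 candidates). The transient-contrast efficiency shows the
trade-off clearly (≈ −0.33): collinearity with the block regressor is
precisely what inflates the variance of transient estimates.

## BOLD simulation and the first-level GLM

`simulate_bold_run()` generates each in-mask voxel as
baseline + (design columns × region amplitudes) + cosine drift + AR(1)
noise. Defaults state the world the analysis assumes: baseline 100 (so
percent signal change has a well-defined denominator), a single cosine
drift with a 300-s period (longer than the 128-s cutoff, so the high-pass
filter *must* remove it rather than getting it for free), stationary AR(1)
noise parameterized by its marginal standard deviation and lag-1
correlation. Volumes default to small grids (e.g. 12³) with voxel-index
coordinates standing in for MNI coordinates; no physiological noise, motion
or spatial autocorrelation is simulated, so cluster-level results on
synthetic data validate the inference machinery, not realistic smoothness.

The GLM implements high-pass filtering by residualizing both data and
design against the discrete-cosine drift basis
($K = \lfloor 2\,n\,TR / 128 \rfloor$ components; 18 at 600 scans) —
equivalent to adding drift columns but simpler to bookkeep. The constant
column is orthogonal to the basis and survives. Estimation is two-pass:
OLS, pooled lag-1 autocorrelation of the residuals across mask voxels (a
global AR(1), as SPM-era software pools it; per-voxel models are out of
scope), exact AR(1) prewhitening (first row scaled by $\sqrt{1-\rho^2}$),
refit. Degrees of freedom subtract both the regressors and the drift
dimensions. All-zero columns (the motion placeholders) are dropped from
estimation and reported with beta 0; genuine rank deficiency is an error
naming the dependent columns. Percent signal change follows the convention
$100 \cdot c^\top\hat\beta \cdot s / \hat\beta_{const}$ with the
reference-trial scaling $s = 0.132$ taken as a supplied constant — its
derivation (the peak of a convolved reference trial under a particular
microtime) is not recoverable here and is deliberately not re-estimated.

## Group inference

`mixed_anova()` computes balanced repeated-measures ANOVAs voxelwise by
sums-of-squares inclusion–exclusion, vectorized across voxels (per-voxel
calls to a model-fitting routine would make permutation inference
infeasible). Error terms follow the classical partitioned scheme:
between-group terms against subjects-within-group, any term with
within-subject part $W$ against the $W \times$ subject-within-group
stratum. `stats::aov` with `Error()` strata is the independent oracle in
the tests. No sphericity correction is applied (none is reported in the
procedure we mirror); with 2-level factors this is moot, for the 4-level
COA factor it is a known limitation. Zero-variance voxels get $F = 0$ so
they can never be suprathreshold.

Cluster inference forms clusters at voxel $p < 10^{-4}$ under
18-connectivity (faces + edges, the convention of the SPM software family)
with peak ties broken by lowest linear index. The original analysis used a
random-field-theory cluster-extent FDR; we substitute a permutation null of
the *maximum* cluster extent — same error criterion (FDR over clusters),
different null construction, and one that is exact-in-distribution for
synthetic data. Exchangeability schemes per term: group labels permuted
over subjects for between-only terms; within-subject cell labels of the
term's factors relabeled per subject (consistently across the remaining
within factors) otherwise. Cluster $p$-values use the add-one estimator
$(1 + \#\{M_b \ge k\})/(B+1)$ and Benjamini–Hochberg across the observed
clusters at $q = 0.05$; with $q = 0$ nothing can ever be significant.
`cluster_table()` reports peak coordinate, extent, peak statistic and the
probit equivalent $z$ of its upper-tail $p$, sorted by statistic.

## Numerical choices and degenerate inputs

- Convolution at $dt = 0.1$ s, sampled at volume onsets; microtime finer
  than 0.1 s changes nothing at TR = 2 s.
- Optimizer tolerance: `optim` defaults with 500 iterations; the 8-start
  grid makes the SSE landscape's local minima irrelevant in practice (the
  tests compare against a 1-ms/2-ms brute-force grid).
- Identical paired vectors give $t = 0, p = 1$; constant *nonzero*
  differences are an error (the statistic would be infinite).
- An empty events file is a valid zero-duration sequence; negative
  durations are a parse error naming the line.
- NIfTI output is little-endian float32 (uint8 for masks), single-file
  `.nii`/`.nii.gz`, written by a minimal built-in NIfTI-1 writer because no
  NIfTI package is available in the supported dependency set.

## Known limitations

- The generator's noise model (white-in-space AR(1), single cosine drift)
  is far simpler than scanner data; detection rates on synthetic volumes
  overstate real-world power.
- The pooled AR(1) and equal-weight session averaging are simplifications
  of what modern per-voxel noise models do.
- Permutation schemes for interaction terms use restricted relabeling; for
  small cohorts the discrete null support limits attainable $p$-values.
- The unable-phenotype mixture (random vs biased) and the fallback PSS are
  configurable assumptions, not estimates.
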