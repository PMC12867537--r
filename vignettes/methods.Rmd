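---
title: "Predicting upper-extremity motor recovery from resting-state EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting upper-extremity motor recovery from resting-state EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StrokeRecovNet)
```

## The prediction problem

After a stroke, upper-extremity motor function — measured by the
Fugl-Meyer Assessment, Upper Extremity subscale (FMA-UE, 0–66 points,
higher is better) — recovers along trajectories that are only partly
predictable from the baseline score. The *proportional recovery rule*
(PRR) captures the dominant pattern: over the subacute months,
patients regain roughly 70% of their lost points,

$$\Delta \mathrm{FMAUE}_{prop} = \beta\,(66 - \mathrm{FMAUE}_{T0}) + C,
\qquad \beta = 0.7,\; C = 0.4 .$$

A substantial minority ("non-recoverers", defined here by a PRR
absolute error of at least 20 points) deviates from this rule, and
identifying them early is the clinically valuable part of the
problem. This package implements an EEG-based machine-learning
pipeline for that task: from each patient's resting-state EEG at
baseline it extracts 221 candidate biomarkers across four domains
(spectral power, brain symmetry, node connectivity, network
topology), joins three clinical inputs (baseline FMA-UE, days since
stroke, days to follow-up), and trains a small feed-forward
regression network to predict the follow-up FMA-UE score. The PRR is
the benchmark the network must beat.

Because no EEG recordings are publicly deposited for this design, the
package ships (a) the two printed clinical cohort tables (23 acute
and 17 subacute patients) as fixtures, which reproduce the PRR
benchmarks exactly, and (b) a synthetic cohort generator that plants
known electrophysiological structure, so every stage of the pipeline
can be validated end to end without patient data.

## Signal processing and the 221-feature inventory

The pipeline analyses the temporally central 180 s of the
artifact-free recording (inputs are assumed cleaned; artifact
removal is out of scope). Signals are cut into 10-s epochs with a
configurable overlap (0, 25%, 50%, 75% — the overlap is a
hyperparameter of the outer model search). To make lesion laterality
comparable across patients, homologous left/right channels are
swapped for left-hemisphere lesions, so the right side of the
montage always carries the *affected* hemisphere (AH). Homologous
pairs are derived from 10-10 label digit parity (odd = left), which
is robust to T3/T7-style nomenclature variants; "central" is taken
relative to the supplied artifact-free signal, since the package
never sees the raw recording.

Per epoch, Welch's averaged periodogram (2-s Hamming-tapered
segments, no overlap; 0.5 Hz resolution) gives a one-sided power
spectral density per channel. Six lateral regions of interest (ROIs)
with 7/11/7 channels per hemisphere (frontal, central, occipital),
their bilateral unions F/C/O, and the two hemisphere sets AH/UH
define the spatial scopes. The five canonical bands are delta 1–4,
theta 4–8, alpha 8–13, beta 13–30 and gamma 30–48 Hz (capped at
48 Hz to avoid line-noise residue). The 141 spectral features are:

* relative band power (trapezoid-integrated, normalized by 1–48 Hz
  power): 5 bands × {average, 9 ROIs, AH, UH} = 60;
* delta/alpha ratio (DAR): 12 scopes; DTABR
  ((delta+theta)/(alpha+beta)): average, the six lateral ROIs, AH,
  UH = 9;
* pairwise-derived brain symmetry index
  $\mathrm{pdBSI} = \frac{1}{K}\sum_n \left|\frac{L_n - R_n}{L_n + R_n}\right|$
  and its directional variant (absolute value dropped; positive =
  unaffected-hemisphere excess): 6 bands × {F, C, O, average} = 48;
* individual alpha frequency (IAF), the alpha-band spectral
  centroid: 12 scopes.

Numerical conventions worth stating: band *power* integrates the
piecewise-linear density over contiguous intervals, so the five
bands tile 1–48 Hz exactly and relative powers sum to one; the
*bin sets* used by pdBSI are lower-closed/upper-open (48 Hz closes
gamma) to avoid double counting; the IAF centroid uses the closed
interval [8, 13] so that a flat alpha spectrum yields the band
midpoint 10.5 Hz. Degenerate denominators (an epoch with zero alpha
power, say) raise flagged errors rather than emitting infinities, so
feature tables stay finite.

Connectivity is computed between the six lateral ROI signals (plain
channel means) as the imaginary part of coherency,
$\mathrm{Coh}_{ij}(f) = \Im\!\left(S_{ij}(f) / \sqrt{S_{ii}(f) S_{jj}(f)}\right)$,
from Welch cross-spectra with the same segmentation. The imaginary
part discards zero-lag coupling, the component most contaminated by
volume conduction. Edge weights are the band-mean of the *rectified*
imaginary coherency (signed averaging can cancel; graphs need
nonnegative weights). Each band's 6-node graph is pruned with a
proportional threshold: the largest percentile (1% steps, ties kept)
of the 15 off-diagonal weights that leaves the graph connected.
Metrics follow Brain Connectivity Toolbox conventions: path length
on 1/w distances, Onnela geometric-mean clustering, small-world
omega $\omega = L_r/L_w - C_w/C_l$ (with $L_r$ from 10 seeded
degree-preserving rewirings and $C_l$ from a deterministic
weight-preserving ring lattice), a rich-club coefficient (edges to
nodes above the 75th strength percentile, normalized by own
strength), and nodal metrics of the two central/motor ROI nodes (CR
= affected, CL = unaffected): degree, strength, path length,
clustering, local efficiency. That is 6 global + 10 nodal metrics ×
5 bands = 80 features; 221 EEG features in all, 224 with the
clinical triple.

Two degenerate regimes deserve mention. Sparsest-connected pruning
frequently lands on spanning trees; a tree (and a ≤6-edge ring
lattice) has no triangles, so both $C_w$ and $C_l$ vanish and the
clustering ratio is taken as 0, keeping omega finite. And at six
nodes the classical "lattice ω < 0 < random ω" contrast is not
meaningfully realizable — dense 6-node lattices and their
degree-preserving randomizations are nearly isomorphic — so the test
suite checks the decidable endpoints instead (a lattice-ordered
arrangement pins the clustering ratio at 1; a triangle-free hub
graph pins it at 0); omega should be read as a descriptive feature,
not a calibrated small-world classifier, at this graph size.

## Feature selection, the network, and nested cross-validation

Within each training fold the 221 EEG candidates are ranked either
by RReliefF (the regression form of ReliefF: k = 10 nearest
neighbours, Manhattan distance on min–max-scaled features, all
instances visited, uniform neighbour weighting) or by mRMR (greedy
difference criterion; relevance = |Pearson r| with the target,
redundancy = mean |Pearson r| with the already-selected set —
discretization-free choices suited to continuous features). All 15
non-empty subsets of the top four features are hyperparameter
candidates; the clinical triple is always appended.

The regressor is a fully connected feed-forward network (ReLU hidden
units from the grid {8; 16; 32; 16-8; 32-16; 32-16-8}, linear
output) trained for exactly 20 epochs with Adam at learning rate
0.01, MSE loss, He-normal initialization, batch size from {64, 128,
full}. Inputs *and targets* are standardized by training-set
mean/sd, with predictions mapped back to the raw scale. Target
standardization is a deliberate design choice: Adam moves each
parameter by roughly the learning rate per step, so within the fixed
20-epoch budget an unstandardized output head could never travel the
~40 points from initialization to the FMA-UE range; the linear-fit
oracle in the test suite documents the effect. Everything is
deterministic given the seed.

Evaluation is nested leave-one-subject-out (LOSO). For each outer
test subject, an inner LOSO over the remaining subjects scores every
grid point — features re-ranked per inner fold, the held-out
subject predicted as the *median of its epoch-level predictions*,
clipped to [0, 66] — by the subject-level validation RMSE. The best
grid point (ties broken in canonical grid order: less overlap,
selector, smaller subset, smaller network, smaller batch) is refit
on all non-test subjects and predicts the test subject. Patients at
the score ceiling (baseline 66; for the subacute cohort also
follow-up 66) are kept for training but never tested, because their
censored recovery distorts error estimates. Performance is the
median (IQR) of absolute errors, compared with the PRR by a paired
sign-flip permutation test (10 000 permutations). The permuted
statistic is the mean difference — the median is degenerate under
sign flips whenever differences share a magnitude — while the
reported effect size is the median difference. The leakage contract
(no test-subject epoch ever touches ranking, standardization, or
training for its own fold) is asserted directly by an audit test
that injects the true outcome into test rows and verifies the inner
validation profile is bit-identical.

Consistency of what different models learn is summarized two ways:
domain consistency, $1 - \sum_d w_d |f^A_d - f^B_d| / \sum_d w_d$
over the four EEG domains with weights equal to the mean domain
selection frequency across the compared datasets (the simplest
normalization achieving the stated [0, 1] bound); and cluster
consistency, the Jaccard similarity of the feature *clusters*
touched by two selections, with clusters from complete-linkage
hierarchical clustering of $1 - |\rho_{Spearman}|$ cut at 0.7
(members correlate at |ρ| ≥ 0.3). When two datasets are compared,
the reference clustering is computed on the first-named dataset's
feature matrix.

## What the synthetic cohorts emulate — and what they do not

`simulateCohort()` builds 50-channel recordings as sums of per-ROI
narrowband stochastic rhythms (band-limited Gaussian noise; delta 6,
theta 4, alpha 10, beta 3, gamma 1.2 rms units by default — an
alpha-dominant, eyes-closed-like profile with slowing), a 1/f
background (exponent 1, scale 4) per channel, and lagged inter-ROI
couplings (an alpha backbone including a CR–CL link at 6 samples
lag), which give nonzero imaginary coherency exactly where planted.
Band-limited *noise* rather than sinusoids matters: it lets
hemispheric amplitude asymmetries reach every bin of the symmetry
features while keeping uncoupled ROIs incoherent. Subject-level
structure comes from a continuous hemispheric-asymmetry trait
(log-amplitude ±0.3 per SD on the central ROIs) and a non-recoverer
subgroup (30%) with doubled affected-hemisphere delta.

Outcomes follow either `prr_only`
($\Delta = \beta(66-T0)+C+\varepsilon$, $\varepsilon \sim N(0,3)$)
or `prr_plus_eeg`, which adds a planted effect (default 10 FMA-UE
points per SD) acting through the *measured* central broadband
directional pdBSI — the generator runs the package's own extractor
on the generated EEG and z-scores the epoch-averaged feature across
the cohort, so the planted signal is by construction recoverable by
the pipeline and sized in honest feature-SD units. Baseline scores
are drawn from a severe/moderate mixture over 0–45: stopping short
of the ceiling keeps $T0 + \Delta$ on-scale, because outcomes
censored at 66 would erase the very signal the planted-effect
experiments must recover (the clinical cohorts handle the same
problem by excluding ceiling patients from testing).

What passing these experiments shows: the feature extractor
faithfully measures planted spectral asymmetries and lagged
couplings; the nested search finds an informative EEG feature when
one exists and does not hallucinate one under the null. What it does
not show: performance on real EEG, whose artifacts, non-stationarity,
volume-conduction structure, electrode-impedance drift and
inter-centre differences the generator deliberately does not model.
Headline model errors on the original recordings therefore cannot
be — and are not — reproduced here; the clinical-table PRR
benchmarks are the only numbers anchored to the published cohorts.

## Problem sizes and other fixed choices

The desk-scale experiments use cohorts of 20 subjects, 184-s
recordings at 256 Hz, no-overlap epochs (18 per subject), and the
reduced hyperparameter grid `reducedGrid()`: mRMR ranking, all 15
top-4 subsets, one 8-unit hidden layer, batch 64. Batch 64 (rather
than full batch) is part of that study condition because the fixed
20-epoch budget then provides ~120 optimizer steps instead of 20,
which the linear-oracle check shows is the difference between
fitting and not fitting a few hundred rows. Five seeded planted
cohorts and one null cohort make up the recovery experiment; the
planted effect must win in at least four of five, and the null must
stay non-significant.

Other fixed numerical choices: omega surrogates, 10 rewirings at 2
swaps per edge with swap-and-revert connectivity preservation
(retry-until-connected is hopeless for tree-shaped pruned graphs);
percentiles and quantiles use R's default type-7 linear
interpolation; medians of even counts use midpoint interpolation;
grid ties break canonically; all seeds derive from one root via a
fixed integer stream. Known limitations: six-node graphs make
several network metrics coarse (see the omega discussion above); the
REC/NO-REC boundary is sharp at 20 points, so patients near it carry
label noise; and with 17–23 subjects per cohort, selection
frequencies and consistency scores are descriptive rather than
inferential quantities.
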