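---
title: "Motion-based cardiomyocyte drug screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based cardiomyocyte drug screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioflow)
```

## The measurement model

A field of beating cardiomyocytes imaged in brightfield produces coherent,
periodic motion: tissue converges toward a contraction centre during the
upstroke and relaxes back. `cardioflow` quantifies that motion in three
stages.

**Optical flow.** For consecutive frames $I_t, I_{t+1}$ we estimate a dense
displacement field $(u, v)$ with a coarse-to-fine Horn–Schunck solver:
minimise $\int (I_x u + I_y v + I_t)^2 + \alpha^2(\|\nabla u\|^2 +
\|\nabla v\|^2)$ per pyramid level, warping the second frame by the current
estimate between levels and between a few outer refinement sweeps. The
axes convention is fixed: $u > 0$ rightward, $v > 0$ downward, pixel (1,1)
top-left; flipping an image vertically negates $v$ only. The solver is
deliberately generic — any dense flow method meeting the translation-recovery
contract (mean recovered shift within 10% of a known integer translation,
which the tests enforce against an FFT cross-correlation oracle) could be
substituted without touching downstream stages.

**PCA contractile profile.** The per-frame-pair block-averaged fields
(default 20 px blocks) are flattened into a $(T{-}1) \times 2 H_b W_b$
matrix — each block's $u$, then each block's $v$ — and column-centred. The
score on the first principal axis is the contractile profile. Using signed
components rather than vector norms is essential: contraction and
relaxation have (nearly) opposite vector fields, so one signed spatial mode
captures both phases with opposite score signs, and the
variance-explained diagnostic tells you how coherent the motion is (a
single synchronous cluster gives $\ge 0.9$; rank-one motion gives exactly
1). The principal-axis sign is arbitrary, so the profile is oriented
deterministically: a user-supplied anchor (time of the first contraction
start) makes the first following extremum positive; without an anchor the
larger-magnitude extremum class becomes positive, which is correct whenever
contraction is faster than relaxation (true for cardiomyocytes and for the
generator's kinematics, where rise time < relaxation time). The
auto-anchor keeps batch screening headless.

**Beats and the 12 parameters.** Peaks above a prominence threshold —
10% of the acquisition's maximum |score|, a scale-free choice so that
amplitude-suppressing drugs do not change the beat count — are reduced to an
alternating +/− sequence; each positive peak with its following trough is a
beat. Phase boundaries sit at zero crossings of the score, interpolated
sub-frame; sign wiggles inside the noise floor (half the prominence
threshold) are not treated as crossings, so boundaries are the points where
the score actually leaves its lobe. Per beat: p1/p2 peak amplitudes, p3/p4
contraction/relaxation durations, p5 rest to next beat, p6 total beat
duration, p7/p8 phase areas (trapezoidal, between crossings), p9
peak-to-peak interval, p10/p11 up/downstroke slopes, p12 frequency
$= 1/\Delta t$ between consecutive contraction peaks. p5, p6 and p12 need a
subsequent beat, so the last beat of each acquisition is flagged and
excluded from classification tables. The exact composition of a beat-shape parameter set varies between
implementations of this kind of assay; this package's dozen is chosen to
cover the families that carry pharmacological signal — amplitudes,
durations, areas, slopes and frequency — and each is named for what it
measures.

## The screening protocol

Each beat is one sample with 12 features. For baseline versus one
condition: condition rows of $\lceil W/3 \rceil$ wells and baseline rows of
$\lceil W/9 \rceil$ wells form the test set (baseline acquisitions outnumber
condition acquisitions three to one, so the smaller baseline fraction
roughly balances the test classes); everything else trains. Features are
z-scored by training statistics; an RBF-kernel SVM is tuned over cost
$\in \{0.1, 1, 10, 100\}$ and $\gamma \in 10^{\{-3,\dots,1\}}$ (5 log-spaced
values) by row-level 5-fold CV accuracy, refit, and scored on the test set.
The reported index is the mean ± SEM over 50 independent splits. Ceiling
rounding guarantees a non-empty test set at small well counts; the grid is a
standard coarse RBF grid;
standardisation is required because the 12 parameters live on very
different scales.

One protocol subtlety is reproduced deliberately: a well whose *condition*
rows are tested may keep its *baseline* rows in training. With highly
well-identifiable features this lets the classifier memorise wells and
produces slightly *below*-chance null accuracy (≈46–50% across master seeds
in the package's own null-cohort checks) — an anti-learning artifact of the
overlap policy, not a bug. `strict = TRUE` opts into full well-level
disjointness, which removes the artifact at the cost of deviating from the default
split policy.

## The calcium pipeline

Fluorescence traces are the mean of a square ROI (default 240×240 px) per
frame. Transients are detected on a 5-sample moving average *in the log
domain*, where multiplicative photobleach becomes a gentle additive slope
and every transient has the same log-height regardless of bleach progress: a
start is the last sub-threshold sample before a sustained positive-derivative
run (threshold: 25% of the maximum smoothed log-derivative), the peak is the
maximum between starts, and both indices are snapped back to the raw grid
(the moving average shifts apparent onsets by up to half its window).
Candidate transients below 20% relative height are discarded.

Photobleach detrending fits a polynomial of order $n \in [2, 10]$ to the
(start time, raw value) baseline points and divides the trace by it;
residual start offsets are removed by linear interpolation so every
transient starts at exactly zero. The order is the smallest $n$ whose RSS
on the start points improves by less than 5% over $n-1$ — parsimony first,
because high-order fits oscillate between sparse support points — and any
order whose baseline crosses zero is rejected outright.

Metrics per transient: amplitude (normalized peak, measured on the
detrended trace's segment maximum), CTD90 — time from the transient start
until the decaying signal first falls below 10% of that transient's own
amplitude, interpolated sub-sample — and SR90 = CTD90/amplitude. The CTD90
clock starts at the transient start (not a fractional upstroke crossing):
with the kinetics used here the difference is a fixed offset well under the
rise time, and the start is the only landmark the detrending pins exactly.
Beating rate is $60 (n-1)/(t_{\text{last start}} - t_{\text{first start}})$
beats/min. Because a fixed *absolute* threshold would drift as bleaching
shrinks amplitudes across acquisitions, the relative threshold keeps CTD90
stable, and SR90 additionally cancels any residual amplitude dependence —
both behaviours are exercised in the test suite.

## Repeated-measures statistics

Wells are subjects, conditions are within-subject levels.
`rm_anova()` uses the textbook decomposition ($SS_\text{cond}$ against the
condition×subject interaction) and applies the Greenhouse–Geisser
$\hat\varepsilon$ (bounded in $[1/(k-1), 1]$) to both degrees of freedom
exactly when Mauchly's test rejects sphericity at 0.05, or always under
`force_gg`. The implementation is the explicit arithmetic rather than a
wrapper so that 5000-replicate calibration runs stay cheap; unit tests pin
it to `car::Anova`/`anova.mlm` to 1e-8. `dunnett_test()` performs paired
many-to-one comparisons on within-subject differences — the paired form is
the natural reading in a repeated-measures design — with familywise
adjustment through the joint multivariate-$t$ of the paired statistics
(correlation estimated from the differences, quasi-Monte-Carlo evaluation
with a fixed internal seed and ±0.0025 tolerance). Monte-Carlo checks in
the suite confirm a GG-corrected type-I rate of ≈0.04 under an AR(1)
$\rho = 0.7$ null ($n = 15$, $k = 5$) where the uncorrected test is
anticonservative (≈0.068), and a Dunnett familywise error of ≈0.05.

## What the generator emulates — and what it does not

`render_video()` warps a fixed band-limited random texture (white noise
blurred to ≈3 px correlation length, matching the gradient statistics flow
needs) by a radially convergent field $u(p,t) = -s(t)\,
\widehat{(p-c)}\, g(\|p-c\|)$ with a raised-cosine envelope $g$ vanishing at
the patch border, by bilinear backward warping. The drive $s(t)$ is
piecewise raised-cosine: rise over `t_rise`, return over `t_relax`, rest at
zero — smooth everywhere, so the rendered flow has no kink artifacts. The
radial geometry is a deliberately simple stand-in motivated by the
converging-vector appearance of contracting clusters; real monolayers move
in richer ways. Defaults mirror the acquisition design: 15.6 fps, 17.5 s
(273 frames), beat period 1.8 s giving ≈9 beats per acquisition, three
baseline acquisitions per well. Cohorts draw per-well kinematics as
log-normal perturbations (CV `well_cv`, default 0.10) and per-acquisition
jitter at half that CV; condition effects multiply rate, relaxation
duration and amplitude. `render_trace()` builds
$B\,\gamma^{a}e^{-\lambda t}(1 + a\sum_i k(t - t_i))$ + noise with a
raised-cosine-rise/exponential-decay kernel, i.e. both within-acquisition
bleaching ($\lambda$) and across-acquisition decay ($\gamma$).

Passing tests on this generator show the pipeline recovers *known radial
periodic motion* and *known transient kinetics* under Gaussian noise. They
do not establish performance on real recordings with asynchronous
sub-clusters, focus drift, non-radial or heterogeneous motion, camera
artifacts beyond additive noise, or fluorescence saturation — none of which
the generator emulates.

## Numerical choices and problem sizes

Flow: $\alpha = 0.5$, 120 iterations × 3 warp sweeps per level, pyramid down
to ≈24 px; textureless frame pairs return zero fields flagged
low-confidence instead of erroring. Segmentation: prominence 0.1, boundary
hysteresis at half the prominence threshold; ties between consecutive
same-sign extrema keep the larger. SVM CV folds are assigned at the row
level (the protocol does not state well-stratified folds). PCA is fit per
acquisition — each recording is processed alone. The package's own
verification runs use 15-well profile-fidelity cohorts (≈560 beats) for
screening checks, 64–96 px videos for flow/PCA checks, and 2000–5000
replicates for statistical calibration; video-fidelity rendering is only
needed where pixel-level behaviour is itself under test.

## Known limitations

- The 12-parameter set covers the standard beat-shape families; other
  implementations of this assay class may compose their dozen differently.
- Horn–Schunck underestimates very large inter-frame displacements; keep
  peak motion below roughly a quarter of the coarsest pyramid level.
- The paired Dunnett form assumes the within-subject differences are
  approximately multivariate normal; heavy-tailed metrics should be
  transformed first.
- Spatial PCA segmentation of asynchronously beating sub-clusters is out of
  scope.
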