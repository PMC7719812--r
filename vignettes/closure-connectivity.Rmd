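---
title: "Models and methods: closure, priming, and directed connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: closure, priming, and directed connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(closurenet)
```

`closurenet` implements the full analysis chain of a multimodal perceptual
closure / repetition priming study — stimulus and design generation, ERP
component analysis, first-level fMRI GLMs, and directed functional
connectivity by Geweke influence measures — together with a synthetic-data
module that generates behavior, EEG and BOLD from known ground truth. This
vignette documents the models, the parameters that matter, the numerical
choices, and what the synthetic data do and do not establish about real
recordings.

## Stimuli and presentation designs

Fragmented stimuli are defined by cumulative random deletion of a picture's
segments: level 1 is the complete picture, and the proportion of deleted
segments at level $L$ is $1 - 0.7^{\,L-1}$, giving seven nested versions.
The number of segments deleted at each level is the proportion times the
segment count, rounded half away from zero — a convention we fixed because
fractional counts must resolve somehow and base R's banker's rounding would
make deletion counts depend on parity. Retained sets are nested by
construction (one seeded deletion order per picture), so a repeated
presentation re-uses identical fragment masks. Scrambled control images
divide the picture into a 16-by-16 grid of tiles (zero-padding
non-divisible images symmetrically) and permute the 256 tiles with a seeded
permutation, preserving the global pixel histogram.

ERP blocks follow the ascending method of limits: each picture sequence
ascends levels 6 → 3 (most fragmented first) until the observer reports
identification. A block has 10 distinct pictures, 5 of which repeat after
one or two intervening sequences (chosen at random), for 15 sequence
presentations per block; timing constants are 750 ms image, 800 ms blank,
200 ms response prompt, 2200 ms blank. Termination of a sequence is
delegated to the observer at simulation time, so the same design code
serves simulated and recorded responses.

fMRI sessions are blocked at TR resolution (TR = 2 s): each block begins
with 4 rest TRs and contains stimulus runs of 9 consecutive TRs (primed,
unprimed, scrambled when there are three runs per block), separated by
4 rest TRs. The run order is randomized once by an explicit seed and then
held fixed across participants. The generator takes explicit
`n_blocks`/`runs_per_block` arguments rather than hard-coding a total
session length: the published elements (3 blocks × 3 runs × 9 TRs with
4-TR rests) sum to 117 TRs, so any larger advertised total must contain
unstated padding, and we prefer a generator whose arithmetic is exact.

## The synthetic observer, EEG and BOLD

The behavioral observer is a logistic psychometric function of
fragmentation level with threshold `threshold_level` (level of 50%
identification), slope, lapse rate, and a `priming_shift` that raises the
threshold for repeated sequences — identification at a more fragmented
level, which is the behavioral signature of repetition priming. A slope of
`Inf` gives a step observer used in exact tests. Threshold recovery from
AML data uses the sequential likelihood (each presented image contributes
one Bernoulli term; levels after termination contribute nothing). The
"modal level of closure" used to pick the primed fMRI level is the mode of
per-sequence identification levels, ties resolved toward the more
fragmented level.

Synthetic epochs are sums of Gaussian-bump components plus white noise.
The component table places P1 at 115 ms (window 100–120 ms, electrodes
PO5/PO6, positive), N1 at 180 ms (170–200 ms, PO7/PO8, negative) and Ncl at
320 ms (300–340 ms, PO7/PO8, negative). Only windows and peaks are
constrained by the measurement conventions; the waveform shape is our
choice, and we use Gaussian bumps with a 10 ms standard deviation (FWHM
about 23 ms), scaled so the mean over the component's own window equals the
configured amplitude exactly — this makes window-mean extraction an
identity in the noise-free case, which the tests exploit. Default
amplitudes express the qualitative pattern of interest (reduced Ncl at
identification in patients, equal N1 repetition enhancement in both groups,
P1 repetition reduction only in controls) but are nominal placeholders in
microvolts, not calibrated to any recorded dataset; effects in physical
units are not published for this paradigm.

BOLD data come from a latent VAR network over DS, LOC, PFC and HIPP run at
TR resolution (one VAR step per TR — the neuronal time grid of the
connectivity model is not observable from data sampled at the TR, so we
generate at the resolution the analysis sees):
$$x[n] = -\sum_{i=1}^{p} A[i]\, x[n-i] + C\,s[n] + u[n],$$
with condition boxcar inputs $s[n]$ and white innovations $u[n]$. The
stored coefficient matrices follow the minus-sign convention of this
equation; `network_model()` accepts couplings in the natural regression
convention ($A_\mathrm{eff} = -A$) and converts. Stationarity is enforced
by requiring the companion-matrix spectral radius to be below 1, and
violations name the radius. Each ROI voxel observes its node's series —
convolved with the canonical HRF, or untouched under the `"identity"`
option used by connectivity recovery tests to avoid the hemodynamic
confound — times a local gain, plus white observation noise. Ground truth
(coefficients, innovation covariance, input weights, gains) is always
returned with the data so recovery tests never reverse-engineer it. The
default group architectures route DS → PFC → LOC in controls and
DS ↔ LOC plus HIPP → DS in patients, with lag-1 couplings of 0.35 — strong
enough to dominate second-order (indirect) influences yet comfortably
stationary.

## ERP pipeline

Trials are rejected iff any channel strictly exceeds ±120 μV between −100
and 500 ms; trials that touch the limit exactly are retained (the
criterion's boundary semantics are unstated, and a strict inequality makes
the rule idempotent and exactly testable). Baselining subtracts each
trial's per-channel mean over −100..0 ms; averages are per condition.
Component amplitudes are means over the window's samples and electrodes,
reported per hemisphere (odd electrode numbers left, even right); mean
rather than peak measures follow from testing a fixed window of time.

Group statistics use a univariate repeated-measures ANOVA with group
between subjects and condition within (hemispheres averaged first by
default, mirroring collapsed bar-chart reporting; hemisphere can instead be
kept as a second within-subject factor). A multivariate formulation would
require knowing which factors were treated multivariately, which is not
determinable from the published description, so the univariate F is
computed and labeled as such in the output. Cohen's d comes from cell
means and the pooled SD. Subjects with incomplete cells are dropped
listwise per component and logged. Component correlations are Pearson r
with two-tailed p, per group.

## fMRI GLM

The canonical HRF is a difference of gamma densities (response peak 6 s,
undershoot 16 s, unit dispersions, peak:undershoot ratio 1/6, 32 s
support), sampled at the TR and unit-peak normalized; these defaults are
stated here precisely because "canonical" alone does not pin them down.
Design matrices contain one causally convolved boxcar per non-rest
condition, an intercept, and polynomial drift (default linear + quadratic).
Estimation is per-voxel OLS, optionally preceded by one pass of AR(1)
prewhitening with the lag-1 residual autocorrelation pooled over voxels;
this approximates the restricted-maximum-likelihood noise model of standard
fMRI packages, and outputs are labeled with the whitening actually used.
Spatial preprocessing (realignment, normalization, smoothing) is out of
scope; ROI masks live in the synthetic grid's own coordinates, with the
conventional Talairach centers of the four closure ROIs carried as metadata
labels only. Second-level tests are one-sample t per ROI within group
(df = n − 1) and pooled two-sample t between groups (df = n₁ + n₂ − 2),
signed control-minus-patient.

## Geweke influence measures and dGCM

For series $x$ and $y$, order-$p$ least-squares autoregressions give
$$F_{x\to y} = \ln\frac{\operatorname{var}(y \mid y_\mathrm{past})}
                       {\operatorname{var}(y \mid y_\mathrm{past}, x_\mathrm{past})},$$
its mirror image $F_{y\to x}$, the instantaneous term
$F_{x.y} = \ln\frac{\Sigma_{11}\Sigma_{22}}{\det\Sigma}$ from the joint
residual covariance, and the total $F_{x,y}$, which decomposes exactly as
$F_{x,y} = F_{x\to y} + F_{y\to x} + F_{x.y}$ because every variance is
taken from the same joint fit with a common divisor. Series are demeaned
and variance-normalized per analysis segment before fitting; the measures
are scale-invariant, so this is purely numerical hygiene. The default
order is p = 1 — BOLD autocorrelation at TR = 2 s carries little
exploitable structure beyond one lag — with an information-criterion
selector (`select_var_order()`) available and its choice logged.

The dGCM takes the mean series of a reference ROI as $x$ and every voxel as
$y$; the influence difference $F_{x\to y} - F_{y\to x}$ maps direction
(positive = ROI drives voxel). Reference-mask voxels are flagged and
excluded from estimation (their joint fit with the ROI mean is
degenerate). Condition-specific analysis selects only the TRs of that
condition's runs plus p lead-in TRs; lagged pairs never span a segment
boundary. Voxel-side sufficient statistics are precomputed once and shared
across the surrogate loop, which keeps thresholding at hundreds of
surrogates over hundreds of voxels in the seconds range.

Thresholds come from circular time-shifts of the reference series (uniform
shift in $[p+1, n-p-1]$), which preserve its autocorrelation while
destroying cross-dependence. The null dGCI values are pooled over
surrogates and voxels: after per-segment standardization the voxel nulls
are exchangeable, and pooling gives p-value resolution $1/(B \cdot V)$
rather than $1/B$ — with B = 200 surrogates alone, no voxel could survive
Benjamini–Hochberg correction at q = 0.05 over several hundred voxels, so
per-voxel nulls at practical B are unusable by construction. FDR level
q = 0.05 by default. The same seed yields the same mask.

Group inference represents per-subject GCIs by median and IQR. The
signed-rank test of a zero median enumerates the exact sign-assignment
distribution (dynamic programming over possibly tied midranks) for up to 25
nonzero values and otherwise uses a continuity-corrected normal
approximation; zeros are handled by the Pratt method — ranked with the
rest, then discarded — which keeps the null distribution correct in the
presence of exact zeros, a case `stats::wilcox.test()` handles only by
dropping zeros before ranking. Between-group comparisons use the Wilcoxon
rank-sum test via `stats::wilcox.test()`. Subject-level values entering
these tests are dGCI differences by default, with raw directed F values
also emitted, since either convention is defensible.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → ERP → GLM → connectivity under one
master seed; every stage seed derives deterministically from it, so a
config reproduces its outputs byte-for-byte. Defaults mirror the study
conditions: 21 controls and 19 patients, three conditions, component
windows and thresholds as above, B = 200 surrogates at q = 0.05.

Test and acceptance runs use deliberately moderate sizes chosen to make
the statistical properties measurable while keeping a full run in the
minutes range on one CPU: closed-form convergence of the Geweke measure at
n = 50,000 samples; directed-edge sign recovery over 100 replicates of
400-TR sessions; FDR calibration on 500-voxel null volumes with B = 200
over 20 seeds; two-group separation with 20 subjects per group over 20
replicates. The two-group check treats as "differing" every connection
whose population dGCI differs between the group architectures — that is
DS–PFC, LOC–PFC, DS–HIPP and also DS–LOC (the HIPP → DS inflow makes the
patients' bidirectional DS–LOC coupling asymmetric in the Geweke sense),
while LOC–HIPP and PFC–HIPP are null in both groups.

## Limitations

The synthetic EEG has no ocular or muscle artifacts, no alpha rhythm, no
trial-to-trial latency jitter, and a diagonal noise covariance, so passing
tests demonstrate correctness of the measurement chain, not robustness to
real-world artifact structure. The BOLD simulator omits physiological
noise, drift beyond what the GLM models, motion, and spatially correlated
noise. Granger-causal direction estimated on BOLD-level series is subject
to the known regional HRF-latency confound; reporting the difference term
dGCI mitigates but does not remove it (both directions share the voxel's
own HRF), and no hemodynamic deconvolution is attempted — the `"identity"`
HRF option exists precisely so that connectivity recovery can be validated
free of this confound. Pairwise (bivariate) Geweke measures also pick up
indirect influences through unmodeled nodes; conditional or partial
variants are out of scope.
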