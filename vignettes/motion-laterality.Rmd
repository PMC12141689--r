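---
title: "Quantifying hemispheric specialization for motion direction: models and design choices"
author: "lateralize package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemispheric specialization for motion direction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When a grating in central vision appears to scroll left or right, the
motion-sensitive N2 component of the visual event-related potential
(peaking near 190 ms over parieto-occipital cortex, negative-going) is
larger over the hemisphere *contralateral* to the motion direction. In
typical adults this direction sensitivity is strongly right-lateralized;
in Williams syndrome (WS), a 7q11.23 hemideletion disorder, the
lateralization reverses toward the left hemisphere. Because WS subjects
all carry the same deletion, the residual expression of single deleted
genes (notably *BUD23*) and the methylation of their promoters can be
correlated, subject by subject, with the electrophysiological laterality
phenotype. This package implements that full analysis chain and a
synthetic cohort generator that makes every stage testable without any
recorded data.

## The laterality model

For each subject we measure the N2 mean amplitude
$A_h(d)$ over hemisphere $h \in \{LH, RH\}$ electrode sets for scroll
direction $d \in \{SL, SR\}$ (155–195 ms, endpoints inclusive). Each
hemisphere's *sensitivity* is its contralateral-minus-ipsilateral
difference:

$$S_R = A_{RH}(SL) - A_{RH}(SR), \qquad S_L = A_{LH}(SR) - A_{LH}(SL).$$

Because the N2 is negative-going, negative $S$ means the contralateral
direction evoked the larger response, i.e. a more sensitive hemisphere.
The Laterality Index is

$$LI = S_R - S_L,$$

negative for right-hemisphere dominance, positive for left, zero when the
hemispheres are equally sensitive (sensitive-but-not-specialized is a
meaningful state in this metric). A documented alternative phrasing of
the index (subtracting the RH difference *from* the LH difference) exists
in the literature surrounding this design; we adopt the form above
because it is the only one under which negative values correspond to
right-hemisphere dominance for a negative-going component, and we treat
it as the canonical convention throughout. Subjects are classed
`RH_specialized` when $LI < -\varepsilon$ and `LH_specialized` when
$LI > +\varepsilon$; the dead-band $\varepsilon$ defaults to 0 µV (any
nonzero LI classifies) and can be widened for noise-aware use. Z-scored
LI uses the sample (n−1) SD, referenced to the combined cohort by
default (`zReference = "group"` switches to within-group).

## Preprocessing

Default chain, each step exported separately and re-orderable through
`preprocessEpochs(steps = ...)`:

1. **Re-reference** every channel to the mean of the two mastoids.
   Differences between channels — hence all component measures — are
   invariant to any common-mode signal, which the test suite checks as a
   property.
2. **Baseline-correct** per trial and channel over [−100, 0) ms. The
   half-open window matches the sample-covers-[t, t+Δ) convention.
3. **Reject** trials: absolute amplitude > 200 µV on any screened channel
   (analysis channels + EOG; *strictly* greater, so a trial peaking at
   exactly 200 µV is retained), or smoothed peak-to-peak > 40 µV on the
   horizontal EOG, or > 100 µV on the vertical EOG. The printed
   rejection threshold in the source material is "± 200 mV", which we
   read as 200 µV — millivolt-scale scalp EEG is physiologically
   impossible — and expose as a configuration knob. The EOG criteria are
   conventional values (they are not specified by the source design) and
   are likewise configurable. Peak-to-peak is evaluated on a 40 ms
   moving-average-smoothed trace so the criterion responds to sustained
   ocular deflections (saccade steps, blinks) rather than single-sample
   noise; with raw traces, ordinary EOG noise alone would trip the 40 µV
   criterion and no threshold could separate clean from contaminated
   trials.
4. **Average** retained trials per condition; subjects under a permissive
   floor (40 retained trials per condition by default) are flagged, not
   silently dropped.
5. **Low-pass filter the averages** at 30 Hz: a 4th-order Butterworth
   applied forward and backward (zero net phase), with odd-reflection
   padding so a DC trace is reproduced to floating point. Two-pass
   magnitude: ≈ −6 dB at the cutoff, > 20 dB down at twice the cutoff,
   < 0.04 dB ripple below half the cutoff at 250 Hz sampling. Filtering
   averages (not single trials) follows the stated convention of the
   original recording pipeline; for a linear zero-phase filter the two
   orders agree in expectation, and `lowpassFilter()` accepts either
   container. Whether rejection preceded re-referencing in the original
   work is unstated; the step list is explicit configuration so either
   order can be reproduced.

## Component measurement

P1 (motion) and N1 (color change) are measured 130–170 ms over five
midline occipital channels; the N2 is measured 155–195 ms over the left
set {P5, PO3, PO7} and right set {P4, PO4, PO8}. The printed sets are
asymmetric (P5 vs P4) and are implemented exactly as printed, with the
montage fully configurable. Window endpoints are inclusive; on the 250 Hz
grid the N2 window covers the ten samples 156–192 ms. Mean amplitude is
the mean over window samples and set channels (set averaging and time
averaging commute, a tested property). Peak latency is the
polarity-matched extremum of the *set-averaged* waveform (a single
documented choice, rather than per-channel peaks averaged), ties broken
by the earliest sample, snapped to the 4 ms grid without interpolation;
flat or wrong-polarity windows are returned flagged rather than silently.
The two scroll directions are pooled (weighted by retained trial counts)
for the P1 measure by default, since whether they were measured pooled or
separately is unstated; `poolMotion = FALSE` measures them separately.

## The synthetic cohort generator

The generator is the package's test bed: it defines the statistical
structure the analysis assumes, with known ground truth.

**Latent laterality.** Each subject draws a total sensitivity
$T \ge 0 \sim$ Gamma (SD `sensitivityScale`, default 0.7 µV) and an
allocation $\pi \in (0,1) \sim$ Beta (per group), and sets
$S_R^{true} = -T(1-\pi)$, $S_L^{true} = -T\pi$, so $LI^{true} = T(2\pi-1)$
exactly. This one-factor allocation structure makes the two hemispheric
sensitivities inversely related across subjects — the more of a
subject's total sensitivity one hemisphere takes, the less remains for
the other — mirroring the inverse interhemispheric relation the analysis
is designed to detect. With the default Betas (concentration 2) the
within-group correlation of $S_R$ and $S_L$ is ≈ −0.63 (TC) / −0.69
(WS), bracketing the reported range.

**Calibration of the allocation Betas.** The TC Beta (mean π ≈ 0.229)
puts 84% of control subjects at $\pi < 0.5$, matching the reported
fraction of right-handed controls with RH specialization. For WS we set
the Beta (mean π ≈ 0.633) so that 68% of subjects fall at $\pi > 0.5$ —
near the reported ≈ 62% left-dominant fraction but deliberately a few
points higher: at exactly 62%, a cohort of 29 has only a ≈ 91%
binomial probability of showing a left-dominant *majority*, so the
reversal would fail to appear at the group level in roughly one cohort
in eleven. The calibration trades a small bias in the per-subject
proportion for a reliably reproducible group-level reversal; both Beta
pairs are plain configuration (`allocationParams`). Gamma means derive
from `groupMeans` (default TC −1.5 µV, WS +0.8 µV; the signs encode the
direction of the group effects, the magnitudes are free defaults) via
$E[T] = \text{mean}/(2E[\pi]-1)$, so each group's expected LI is met
exactly. A length-1 allocation entry fixes π (degenerate allocation) for
analytic edge-case tests.

**Waveforms.** Each trial is a sum of Gaussian-in-time kernels (default
width 15 ms — peak latencies are specified upstream, shapes are not):
P1 (positive, occipital, motion conditions, group-dependent amplitude so
the WS motion response is selectively attenuated), N1 (negative,
occipital, color change), N2 (negative, both parieto-occipital sets,
motion conditions). The N2 hemisphere-by-direction offsets are scaled by
the kernel's window-averaging gain so that noise-free window means
reproduce $S_R^{true}$ and $S_L^{true}$ *exactly* — the generator and
the measurement code share only the window definition, making the
noise-free round trip a machine-precision identity test of the entire
chain (re-reference, baseline, rejection, averaging, measurement,
laterality). The round-trip check excludes the 30 Hz filter: its
passband gain on the 15 ms kernel is ≈ 0.99992, a linear ~10⁻⁴
attenuation that is irrelevant scientifically but incompatible with a
10⁻⁹ identity.

**Noise.** Scalp channels receive white noise mixed with a
cumulative-sum low-frequency component (`pinkFraction` of the variance;
the spectral shape is an acknowledged approximation, not a fidelity
goal). Defaults `noiseSd` = 6 µV, `pinkFraction` = 0.2 give a
single-trial N2-window noise SD near 3 µV and an average-level standard
error around 0.33 µV at the study scale of 300 trials — precise enough
that per-subject sensitivities are recovered with correlation ≈ 0.95
against truth, consistent with the clean subject-level structure the
method is meant to resolve. Heavier low-frequency fractions were
examined and documented as unrealistic: they leave window means dominated
by drift that 300-trial averaging cannot remove. EOG channels carry
white noise only (5 µV), representing the locally dominated EOG
derivations.

**Artifacts.** A Bernoulli(`artifactRate`) subset of trials receives one
of: blink (300 µV, 25 ms-SD pulse on the vertical EOG), horizontal eye
movement (sustained ±60 µV step on the horizontal EOG), or spike
(±250 µV single-sample excursion on a random analysis channel).
Amplitudes deliberately straddle the rejection criteria (200 µV absolute,
40/100 µV EOG peak-to-peak) so rejection accuracy is a meaningful score;
truth flags are returned for sensitivity/specificity computation.

**Molecular covariates.** Expression features are generated on a latent
scale as $\rho \cdot z(LI^{true}) + \sqrt{1-\rho^2}\,\epsilon$ and mapped
through two distinct batch-specific affine scales (batches split by
acquisition-order parity, mirroring the two-batch qRT-PCR design), so
within-batch z-scoring is genuinely exercised: it removes the affine
scales exactly. Promoter methylation is an inverse-logit of a latent
tied to the primary expression feature, clipped to (0,1) by
construction; its target correlation with LI (default −0.40, opposite in
sign to expression) holds on the latent scale and is mildly attenuated
(~2%) by the link's curvature. Default `rhoExpression` is 0.47 for
*BUD23*, the value the replication design is powered around.

## Inference

`group_stats`-style tests are implemented from first principles, since
they *are* part of the analysis under test: pooled-variance independent
t (df = n₁+n₂−2, so 27+29 subjects give the familiar df 54), paired t,
uncorrected 2×2 Pearson chi-square (no continuity correction — the only
form that reproduces both participant-table statistics from their
counts), and a univariate mixed repeated-measures ANOVA for one between
factor and up to two 2-level within factors. The ANOVA projects each
subject's cell means onto orthonormal within-subject contrasts
(Kronecker products of (1,1)/√2 and (1,−1)/√2); between/within sums of
squares of the projected scores are exactly the classical split-plot
sums of squares, with each within effect tested against its own
factor-by-subjects-within-groups error. Two algebraic identities anchor
correctness: with a single 2-level within factor and no between factor,
F equals the squared paired t; with a between factor only, F equals the
squared pooled independent t. Both hold to 10⁻⁹ relative tolerance on
random data, and the full three-way table matches `aov`'s split-plot
decomposition (the independent oracle in the test suite). Within factors
with more than two levels are rejected with a clear error rather than
implementing sphericity machinery the 2×2×2 design never needs.
Degenerate inputs are reported, not hidden: zero-variance t tests are
flagged, an all-equal response table yields F = 0 by convention.

Correlation inference: Pearson r (via `stats::cor` behind a validating
wrapper), $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with n−2 df, directional
one-tailed tests (one-tailed p equals half the two-tailed p when the
observed sign matches the stated direction, 1−p/2 otherwise), and
Bonferroni or Holm adjustment within a declared family. The family
defaults to *features sharing a phenotype* — the adjustment method and
family are configuration because the original multiple-comparison
procedure is not specified. Listwise deletion is per feature–phenotype
pair (molecular cohorts are routinely a subset of the ERP cohort).
Methylation β values are correlated untransformed; a logit transform is
available but off by default.

## The synthetic worksheet

`syntheticWorksheet()` builds a stand-in, labeled synthetic, for a
deposited per-subject worksheet (laterality phenotypes + combined
qRT-PCR z scores, n = 26, and a 6-subject methylation sub-cohort). Its
vectors are constructed by Gram–Schmidt orthogonalization so the sample
correlations equal the requested targets *exactly*, which turns the
correlation grid into a checkable fixture at published-scale
coefficients (0.465 / 0.441 / 0.423; −0.942 / 0.898). One subtlety the
construction surfaces: because $LI = S_R - S_L$ identically, the
correlations of a single variable with LI, $S_R$ and $S_L$ cannot carry
arbitrary independent signs; the default targets keep the published
magnitudes with the unique self-consistent sign pattern (expression
positive with LI and $S_R$, negative with $S_L$) and solve for the
$S_R$–$S_L$ correlation (≈ −0.73) that makes all three exact
simultaneously.

## Problem sizes and numerical choices

Simulation-backed tests run at sizes chosen to keep the full suite in a
few minutes while preserving the quantities under test: cohort-structure
checks run at the study scale (27+29 subjects) on the latent truth
tables, where the classification and correlation structure live; epoch-
level checks synthesize 1 000–4 000 trials; the subject-level recovery
check uses 24 subjects × 60 trials with noise scaled by √(60/300) so the
average-level precision equals the 300-trial default; the molecular
calibration uses 1 000 simulated cohorts at n = 26. A full trial-level
study-scale cohort (56 subjects × 3 conditions × 300 trials × 15
channels × 275 samples ≈ 0.5 × 10⁹ values) is the generator's
*definition*, not its working set — synthesize per subject if you need
it materialized. `defaultPipelineConfig()` therefore carries a
demonstration-scale cohort (10+10 subjects, 40 trials).

Numerical conventions worth knowing: time samples cover [t, t+Δ);
measurement windows are endpoint-inclusive (the guard test documents
that switching to exclusive endpoints moves a window mean by at most
(max−min)/n samples); peak ties break to the earliest sample; the
specialization dead-band is 0 µV; z-scores use n−1 SDs; filter padding
is odd-reflection with length min(n−1, 100).

## Limitations

The generator is a statistical emulator, not a biophysical one: no
volume conduction or realistic 64-channel geometry (only the analysis
channels plus mastoids/EOG exist), Gaussian component kernels, a crude
two-component noise spectrum, and artifacts drawn from three stereotyped
templates. Passing tests therefore demonstrate that the *analysis* is
correct and well-calibrated under the assumed structure, not that the
structure captures every property of recorded EEG. Ocular artifact
*correction* (ICA/regression), channel interpolation and vendor EEG
formats are out of scope; subject-level statistics of any real recorded
waveforms additionally depend on acquisition details no simulation can
supply.
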