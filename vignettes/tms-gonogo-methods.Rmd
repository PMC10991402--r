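---
title: "Models and methods: simulated TMS-EEG during motor inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulated TMS-EEG during motor inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package models

`tmsgonogo` simulates and analyses concurrent TMS-EEG recorded during a
visual Go/NoGo task. A session consists of 400 epoched trials (100 per
cell of the Go/NoGo x TMS/no-TMS design), each spanning -1000..+1000 ms
around a (real or virtual) TMS pulse delivered over the hand area of the
left primary motor cortex (M1), 150 ms after the response cue. The
analysis asks three linked questions:

1. How does phase-locking between the supplementary motor area (SMA) and
   M1, resolved by frequency band and task phase, differ between execution
   (Go) and inhibition (NoGo)?
2. How do the TMS-evoked potential (TEP) components -- P30, P60, N100 --
   and the task event-related components (FIX-P1, FIX-N1, CUE-N1, CUE-P1,
   CUE-N2) differ between conditions?
3. Are the connectivity modulations linearly related to the N100
   modulation and to reaction time?

Because no public recordings of this protocol exist, the package is built
around a synthetic session generator with known ground truth: every
quantity the analysis estimates is planted by an explicit generative
model, so the pipeline is validated by parameter recovery rather than by
re-analysis of deposited data.

# The generative model

**Forward model.** Sensors are an idealized 62-channel extended 10-20
montage on a 95 mm sphere. Current sources sit on an 80 mm shell
(60 by default), always including the M1 centre at MNI-like
(-31.3, -15.4, 75.8) mm and the SMA centre at (-10, -2, 77) mm; ROI
membership is every source within 15 mm (the minimum-norm localization
accuracy at this scale is about 1.5-2 cm). The gain from source $s$ to
electrode $c$ is a smooth distance decay
$g_{cs} = \exp(-d_{cs}^2/2\sigma^2)$ with $\sigma = 18$ mm, plus a 1%
deterministic geometric perturbation, columns scaled to unit maximum.
$\sigma$ trades realism (real EEG gains are broader) against the
separability of the two ROIs, which sit only ~25 mm apart; 18 mm keeps
the inverse crosstalk between their kernel rows moderate while the model
stays a smooth volume-conduction operator. A realistic boundary-element
head model is deliberately out of scope; because the generator mixes
sources to sensors through the *same* leadfield the inverse uses,
forward/inverse consistency is testable.

**Evoked components.** TEPs (TMS trials only) and ERPs (all trials) are
Gaussian-windowed monophasic deflections. Latencies/widths (ms):
P30 30/8, P60 60/10, N100 100/15; FIX-P1 -800/15, FIX-N1 -680/20,
CUE-N1 -120/12, CUE-P1 -50/18, CUE-N2 +150/30. Topographies are built
from leadfield columns of the ROI sources (N100: 0.4 M1 + 0.6 SMA,
giving the left fronto-central negativity) and normalized so that the
mean over the extraction cluster (Fz, FCz, FC1, C1, C3 for TEPs; a
medial frontal set for ERPs) equals one -- planted amplitudes are
therefore cluster-average amplitudes and can be recovered exactly in the
noiseless limit. Default condition effects are the differences this
paradigm produces: N100 larger (more negative) in NoGo by 0.884 uV;
CUE-N2 larger in Go by 1.386 uV; CUE-P1 larger in Go.

**Phase coupling.** Each band (theta 5.5, alpha 10, beta 20, gamma 40 Hz
carriers) contributes a sinusoid to both ROI sources. The SMA source
carries phase $\phi(t)$, the M1 source $\phi(t) + \Delta\phi$, where
$\Delta\phi$ is drawn per trial from a von Mises distribution whose
concentration $\kappa$ is the analytic inverse of the mean resultant
length $A(\kappa) = I_1(\kappa)/I_0(\kappa)$ at the target PLV.
$\Delta\phi$ is piecewise constant over task-phase segments (boundaries
-850, -350, -150, +10, +150, +650 ms; the cue segment extends to +10 ms
because -1..+10 ms is excised downstream) with 50 ms raised-cosine
transitions. Condition differences (NoGo - Go) default to the planted
analogues of the condition effects this paradigm elicits: theta
+0.060 / gamma -0.018 during
cue elaboration; theta +0.071, alpha -0.061, beta -0.073 during the TMS
perturbation; theta +0.023, alpha -0.028, beta -0.052 during the task
response; no differences during preparation.

**Chain calibration.** What the full analysis chain measures is not the
planted phase-difference concentration: minimum-norm crosstalk mixes the
two sources, the baseline noise covariance is signal-inflated (raising
the regularization), projected sensor noise perturbs phases, and the
finite trial count imposes a Rayleigh floor of about
$\sqrt{\pi}/(2\sqrt{N})$. The generator therefore maps requested
coupling targets through the inverse of a measured calibration curve
(`calibratePlvMap()`, frozen per band in `R/calibration.R` at the default
settings: 50 trials per cell, 62 channels), so that the PLV recovered by
the default chain approximates the requested target. The base coupling
default (0.45) sits above every band's measurement floor so condition
differences are expressible in both directions. Targets below the floor
saturate: they cannot be realized by any concentration.

**Between-subject structure and behaviour.** Per subject, each band x
phase coupling difference is drawn around its population value with sd
0.108 (consistent with group-level standard errors near 0.023 for
these differences in 22-participant studies of this paradigm), and the
baseline with sd 0.03. The subject's N100 modulation follows the linear
link `n100Diff = b0 + 8.957 * thetaTMS + 11.304 * gammaTMS + noise`
(the planted link coefficients; `b0` chosen so the
population mean is 0.884 uV; residual sd 0.3 uV). Go trials get
`RT = subjectMean + N(0, 75 ms)` with the subject mean tied inversely to
the gamma coupling modulation during cue elaboration (-150 ms per PLV
unit against a 26 ms subject-level sd, planting a correlation near
-0.5); misses (2.87%) and false alarms (0.76%) are Bernoulli flags. The
sign of an RT-theta association is ambiguous in this paradigm, so only
the gamma link is planted; signed differences are always reported as
NoGo - Go.

**Noise.** White sensor noise (2 uV) and white ROI source noise
(0.6 uV) on top of oscillation amplitudes of 3-5 uV. These amplitudes
are deliberately below ongoing-EEG levels: they are scaled so that a
desk-scale synthetic study (8 subjects x 50 trials per cell) carries
sensitivity comparable to the emulated 22-subject, 100-trials-per-cell
protocol. Passing recovery tests at desk scale therefore demonstrates
correctness of the estimators, not that effects of this size are
detectable in raw-noise recordings at n = 8. The generator also does not
simulate continuous recordings, inter-trial intervals, cranial-muscle
artifact physics, or realistic ocular dynamics (blinks are a planted
template for component-cleaning tests).

# The analysis chain

Stages run in a fixed order, matching standard TMS-EEG practice:

1. **Pulse excision** (-1..+10 ms, TMS trials): replaced by a
   least-squares cubic fitted on 20 ms flanks. The replacement is a fixed
   linear map of the flanking samples.
2. **Zero-phase filtering**: 4th-order Butterworth band-pass 1-80 Hz plus
   a Q = 35 biquad notch at 50 Hz, applied as $|H(\omega)|^2$ in the
   frequency domain with full-length reflection padding. This realizes
   the forward-backward (filtfilt) transfer function with exactly zero
   phase, vectorized across all trials and channels; like any
   forward-backward filter, the narrow notch rings for ~0.2 s at epoch
   edges, so steady-state attenuation is assessed in the epoch centre.
3. **Downsampling** to 1000 Hz (anti-alias low-pass at 80% of the output
   Nyquist, then integer decimation keeping t = 0 on the grid).
4. **Demeaning** per trial and channel (idempotent).
5. **Trial rejection** by peak-to-peak threshold (default 500 uV), an
   automatic surrogate for visual inspection.
6. **Independent component cleaning** (optional; symmetric fixed-point
   algorithm, tanh contrast) with automatic flag rules -- post-pulse decay
   variance, frontal/blink-template topography, >30 Hz power fraction --
   standing in for the manual component selection used on real data.
   Synthetic sessions plant no ocular or muscle sources by default, so
   the stage defaults off in the pipeline.
7. **Noise covariance** from the -850..-350 ms baseline, diagonal-loaded;
   **minimum-norm inverse** $K = L^\top(LL^\top + \lambda^2 C)^{-1}$ with
   $\lambda^2 = \mathrm{tr}(LL^\top)/(\mathrm{tr}(C)\,\mathrm{SNR}^2)$,
   SNR = 3; **ROI series** as the sign-aligned mean over ROI sources
   (signs from the first principal direction, so anti-correlated copies
   reinforce).
8. **Connectivity**: complex Morlet decomposition (3 cycles, 4-50 Hz in
   1 Hz steps, 1 ms resolution, unit-energy wavelets, edge samples masked
   within one wavelet half-length), trial-wise PLV between the two ROI
   series, averaged jointly over band bins (theta 4-7, alpha 8-13, beta
   14-30, gamma 31-50; shared edges assigned to the lower band) and
   task-phase windows (preparation -850..-350, cue elaboration -150..-1,
   TMS perturbation +10..+150, task response +150..+650 ms). The
   per-condition evoked mean is subtracted from the ROI series first
   ("induced activity"): without this, condition-asymmetric evoked
   components masquerade as theta-band coupling differences.
9. **Evoked analysis**: TERP (TMS-trial average), ERP (no-TMS average),
   TEP = TERP - ERP; peaks by maximum absolute value within the TOIs
   (P30 10-40, P60 40-70, N100 70-130 ms) and ERP peak-to-peak within
   five windows -- the asymmetry between the two rules is intentional and
   preserved. Ties go to the earlier sample.
10. **Statistics**: normality-gated paired tests (Shapiro-Wilk at 0.05
    choosing t vs Wilcoxon); cluster-based sensor permutation (paired t
    per channel, p < 0.05 forming threshold, same-sign neighbourhood
    clusters of >= 2 channels within 50 mm, cluster mass = sum of t,
    within-subject sign-flip null, add-one p); consecutive-timepoint
    source tests (>= 10 successive pointwise p < 0.05 samples, 3000
    permutations retained for the run-length null); within-subject ANOVA
    with Greenhouse-Geisser correction gated by Mauchly's test and
    partial eta squared; Sidak post-hocs; gated correlations; stepwise
    forward regression (entry p < 0.05 on the partial F, no removal)
    predicting the N100 modulation from the 16 band x phase PLV
    modulations.

# Design choices where the design was open

- **Repeated-measures ANOVA is computed from orthonormal-contrast
  projections** rather than through `anova.mlm`: the mlm sphericity
  machinery needs more subjects than effect degrees of freedom, which a
  4 x 2 x 4 design at desk-scale subject counts violates. The
  implementation is cross-checked against `anova.mlm`/`mauchly.test`
  (M/X interface) at n = 22 in the test suite.
- **Deferred linear processing** (`deferLinear = TRUE`): excision,
  filtering, downsampling, demeaning and the inverse map are all linear,
  so they commute with trial averaging and with the ROI projection. The
  deferred path applies them to condition averages and ROI series
  instead of every sensor trace; a test asserts equality with trialwise
  processing to float tolerance. The noise covariance is estimated
  before filtering on this path (a second-order difference entering only
  through the regularization scale).
- **Cluster statistic** is the sum of t over the cluster (cluster mass);
  the formation rule defines clusters but not the statistic, and mass is
  the common choice. Channel neighbourhoods are pairs within 50 mm.
- **Permutation conventions**: within-subject sign flips for paired
  designs; add-one p-value estimator (1 + b)/(1 + nPerm).
- **Sidak family size** for PLV post-hocs is the four bands within each
  task phase.
- **Zero-variance degenerate cases** report p = 1 by convention.
- **Band/phase averaging** is the joint arithmetic mean over all valid
  (frequency, time) bins of a cell, with wavelet-edge bins excluded via
  the validity mask.
- **Session persistence** is an RDS payload plus a JSON sidecar for the
  trial table and ground truth; all result tables export as tidy CSV
  with a JSON provenance record, and reruns under the same seed are
  byte-identical. Reading clinical EEG interchange formats is out of
  scope for the simulation-focused workflow.
- The exported functions are the interface; the analysis is meant to be
  driven from R scripts (see `scripts/acceptance.R` for a complete run),
  not from a shell command.

# Problem sizes and what the tests show

Unit tests run on reduced sessions (250-1000 Hz, 10-24 channels, a few
trials per cell) because every operator is size-agnostic. The
parameter-recovery studies use 8 subjects x 50 trials per cell
(62-channel montage for the full-stage recovery run; a 16-channel subset
for the 50-replicate regression-selection study, whose ROI- and
cluster-level estimands do not depend on montage size), and the
acceptance script reproduces the full emulated protocol at 22 subjects x
100 trials per cell. Simulated acquisition runs at 1000 Hz in these
studies; the 5000-to-1000 Hz decimation path is exercised separately by
its own contract tests.

Recovery at 8 subjects is verified as *fitted condition differences
within two empirical standard errors of the planted values*. One planted
property is not recoverable at that scale: selecting **both** theta and
gamma TMS-perturbation couplings by forward stepwise regression (entry
p < 0.05 among 16 candidates) in >= 80% of replicate studies. A power
analysis in the test design showed the binding constraint is the
theta-band PLV estimator itself: at 50 trials per cell a 3-cycle Morlet
in 140-150 ms windows yields only ~2-3 independent time-frequency
samples, so the per-subject theta modulation carries measurement noise
(sd ~ 0.12) larger than the planted between-subject spread (0.108),
capping dual-selection near 10% at n = 8 regardless of the other
generator settings (the noiseless ceiling is 77-95%). The corresponding
test asserts the property faithfully and is expected to fail; it stops
early once enough failures make the 80% bound arithmetically impossible.

# Known limitations

- The toy spherical leadfield understates real volume conduction and
  overstates ROI separability relative to nothing -- absolute PLV floors
  (0.18-0.19 at 50 trials) and the calibration curve are properties of
  this model, not of any real head.
- The chain calibration is frozen at 50 trials per cell; at 100 trials
  the floor is slightly lower, so recovered differences over-shoot
  planted ones by a small factor.
- Evoked subtraction before connectivity removes phase-locked activity
  entirely; genuinely phase-reset oscillations would be (correctly)
  excluded from PLV but are also not simulated.
- Behavioural outcomes are conditionally independent across trials;
  sequential effects (post-error slowing, fatigue) are not modelled.
- Greenhouse-Geisser epsilon and Mauchly's test require more subjects
  than transformed dimensions; below that the uncorrected p is reported
  with epsilon clamped, mirroring the small-sample reality.
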