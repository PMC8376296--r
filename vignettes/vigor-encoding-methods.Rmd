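---
title: "Analysis of cue-evoked approach-vigor encoding: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of cue-evoked approach-vigor encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In operant discriminative-stimulus (DS) tasks, a reward-predictive auditory
cue arrives at unpredictable times while a rat moves freely about an
operant chamber. On most DS presentations the animal initiates a locomotor
approach to a lever from a different starting position, presses, and
collects reward at a nearby receptacle. Neurons in ventral basal-ganglia
structures respond to the cue with a short-latency excitation whose
magnitude varies trial by trial. The analytical question this package
addresses: which parameters of the upcoming approach movement — its speed,
its path efficiency, the animal's starting proximity to the lever, its
reaction latency — are reflected in that cue-evoked firing, once the
redundancy among movement descriptors is accounted for?

The package implements the full chain needed to answer that question from
raw per-session data (two-LED head tracking at 30 frames/s, a behavioral
event log, per-neuron spike times), and a synthetic-session generator with
exported ground truth so that every stage can be validated against known
answers.

## Movement detection from head tracking

Head position is the midpoint of two head-mounted LEDs; heading is the
rear-to-front LED direction. The movement-detection signal is the
locomotor index (LI): for frame $t$,

$$\mathrm{LI}_t = \mathrm{SD}(d_{t-4}, \ldots, d_t, \ldots, d_{t+4}),$$

where $d_A$ is the Euclidean displacement of the head between frames $A-1$
and $A$. The window half-width (4 frames, i.e. nine displacements) is
configurable; the formula spans nine displacements even though the window
is conventionally described as eleven frames of positions, and we implement
the formula as written. The SD uses the sample ($n-1$) denominator.

A three-component Gaussian mixture is fitted to the session's LI
distribution. The lowest component captures tracking noise at rest, the
middle component intermediate head motion, the highest locomotion. The
movement-offset threshold is the density intersection of components 1 and
2, the onset threshold the intersection of components 2 and 3 (each a root
of a quadratic; when no root lies between the means the minimizer of the
absolute density difference is used and flagged). EM is seeded from k-means
centers with several restarts, keeping the best-likelihood converged
solution. Seeding near the three occupancy modes matters: the global
maximum-likelihood solution can use two components to fit skew within the
dominant stillness mode, which destroys the interpretability of the
thresholds; k-means seeding reliably converges to the interpretable
solution. Fits use a subsample of at most 100,000 LI values and are
deterministic given a seed.

A movement onset is the first frame of at least 4 consecutive frames with
LI strictly above the onset threshold, preceded by stillness (at least 70%
of the 30 preceding frames strictly below the offset threshold). The bout
ends at the first subsequent frame below the offset threshold. Trials where
the cue frame falls inside a detected bout are excluded from analysis
("moving at cue"). For responded trials the movement window ends at the
first lever press or receptacle entry after movement onset; otherwise at
the LI offset.

Because the LI window is centered, it blurs each movement transition by
roughly five frames. Two practical consequences, quantified with the
synthetic generator: onsets of brisk, rest-launched movements are located
within ±3 frames in over 95% of cases, but initiations that follow recent
movement by less than about a second are invisible to the stillness rule,
and movements whose early speed hovers near the onset threshold are
detected late. A small percentage of trials therefore receives a wrong
movement window; the limitations section returns to what this does to the
regression stage.

## Trial-level features

Over each trial's movement window the package computes the standard set of
locomotor descriptors: mean/max/SD of radial velocity toward the lever
(the lever-centered polar decomposition of head velocity; the angular
velocity about the lever is its tangential complement, reported as
magnitudes for mean and max), mean/SD/max speed, movement duration, path
length, latencies to maximum speed and maximum (signed first-difference)
acceleration, maximum perpendicular deviation from the straight
start-to-end line, net (unwrapped, signed) heading change, turn efficiency
(cumulative absolute heading change over the absolute net change; flagged
undefined when the net change is under $10^{-3}$ rad, and such trials are
dropped listwise by the regression stage), and path efficiency
(straight-line distance over path length). State variables are measured at
the cue-onset frame: distance and absolute egocentric bearing to the
lever, and times since the last reward, lever press, and cue. Distance to
the lever is evaluated at cue onset (not movement onset) throughout, and
the bearing is reported as an absolute angle in $[0, \pi]$ because a
left/right sign convention would be arbitrary.

## Excitation detection and response measures

Spikes are binned in 20-ms bins around cue onsets of still-at-cue DS
trials. Baseline statistics come from the 50 trial-averaged bin rates of
the 1-s pre-cue window; the detection criterion is the baseline mean plus
$z_{0.9995} \approx 3.2905$ baseline SDs (a two-sided 99.9% normal
criterion; a Poisson-exact variant on summed counts is available via
`excitation_method = "poisson"`). A neuron is cue-excited when at least
three consecutive bins between 40 and 180 ms exceed the criterion.
Monte-Carlo calibration on homogeneous Poisson neurons puts the
false-positive rate under 1%, and two-phase kernels peaking at three times
baseline are detected with over 95% sensitivity at 80 trials. Response
onset latency is reported as the first supra-criterion bin after cue
onset, whether or not it belongs to the qualifying run. Z-scored responses
use the same baseline statistics. Response windows are 40–400 ms
(overall), 40–180 ms (early peak), and 180–400 ms (late tail); a 50–500 ms
variant can be configured, but 40–400 is the set used by all reported
analyses.

## Regressor selection

The movement descriptors are deliberately redundant. The selection chain
is: (1) squared multiple correlations (SMC, the $R^2$ of each variable on
all others), iteratively dropping the worst variable while any SMC exceeds
0.8; (2) eigenvalues of the correlation matrix with Kaiser's criterion
(eigenvalue > 1) to choose the number of factors; (3) maximum-likelihood
factor analysis with varimax rotation; (4) a rep score per variable — its
highest factor loading minus the signed sum of its loadings on the other
factors; (5) per factor, the assigned variable with absolute loading of at
least 0.6 and the best rep score becomes the factor's representative, and
variables whose largest absolute loading is below 0.4 enter as
"independent" regressors. The 0.6/0.4 cutoffs are configuration values
chosen to reproduce the reference selection on the bundled loading table
(`reference_factor_loadings()`); a manual override list exists because, on
that table, the printed factor-3 representative does not have the top rep
score for its factor, so exact reproduction of the published set requires
an override. Rotation is varimax by default (the reference table's simple
structure is consistent with an orthogonal rotation) and configurable.

## The Poisson GLM and the IDR Firing Difference

For each cue-excited neuron and response window, the spike count $Y$ over
correct, still-at-cue DS trials is modeled as

$$\ln E[Y] = \beta_0 + \beta_1 x_1 + \cdots + \beta_n x_n,$$

a Poisson GLM with log link on the unstandardized regressors. Effect sizes
are made comparable across regressors by the interdecile-range firing
difference:

$$\mathrm{IFD}_A = \left(e^{\beta_A \cdot \mathrm{IDR}_A} - 1\right) \times 100\%,$$

where $\mathrm{IDR}_A$ is the difference between the 90th and 10th
percentiles (linear-interpolation rule) of regressor $A$ over that
neuron's retained trials. Regressors are left unstandardized because the
IDR transform provides the cross-regressor comparability. Population
inference is a two-sided one-sample t test of per-neuron IFDs against
zero, per regressor, Holm-corrected within each response window (the
10-regressor family for the full model, 3 for the focused model). A
one-way fixed-effects ANOVA across subjects checks that population effects
are not driven by one animal. Sessions with a DS response ratio below 0.80
are excluded from the GLM stage. Neurons are excluded when fewer than
(number of regressors + 10) complete trials remain or when the fit fails
to converge.

## Pre/post-infusion epoch comparison

When a session has an infusion marker, Q1 is the 45 minutes before it and
Q2 the 45 minutes after. Each neuron with at least 10 DS trials and a
finite Z in both epochs contributes a (Q1, Q2) pair of response Z-scores
(computed exactly as the trial-averaged Z above, separately per epoch and
per window, 40–180 and 180–400 ms). Ordinary least squares of Q2 on Q1
gives a slope and intercept with t tests against slope = 0, slope = 1 and
intercept = 0 (df = n − 2). A slope significantly below 1 indicates
attenuation of cue-evoked responses.

One caveat is intrinsic to this design: both axes are estimates from a few
dozen trials, so sampling error in the Q1 estimate attenuates the slope
below 1 even when nothing changes (classical errors-in-variables). With
roughly 35–45 trials per epoch the no-change slope is biased a few percent
below 1, which inflates the slope-vs-1 rejection rate above its nominal
level. The regression machinery itself is exactly nominal when the pairs
are measured without error (verified by simulation); the inflation appears
only when Z-scores are estimated from finite trials, and it is a property
of the published procedure, not of this implementation.

## The synthetic-session generator

The generator produces complete session bundles plus ground truth. Its
defaults are the study conditions of the task it emulates; the notable
choices:

* **Schedule.** A single interleaved cue stream: after each cue's maximum
  extent (onset + 10 s) an exponential gap with mean 30 s elapses before
  the next onset; each cue is DS with probability 0.5. This reproduces all
  three published scale facts simultaneously: a 30-s mean intertrial
  interval, roughly 130 DS presentations per 3-h session, and a mean
  interval between DS presentations of about a minute. (Two independent
  per-type exponential streams, an alternative reading, would produce more
  than twice as many cues as observed.)
* **Inter-trial behavior.** A three-state semi-Markov process: stillness
  (mean 6 s), brisk Ornstein–Uhlenbeck roaming (mean 4 s, per-bout step
  scale lognormal around 10 mm/frame, with ~5-frame acceleration and
  deceleration ramps), and brief low-amplitude "fidget" epochs (mean
  2.5 s, ~3.5 mm/frame) that emulate head movement without locomotion and
  populate the middle mode of the LI distribution.
* **Approach.** On responded DS trials (probability 0.92; NS 0.10), after
  a lognormal reaction latency (median 0.8 s, shape 0.9, capped below the
  cue deadline), the head follows a curved path to the lever: a sinusoidal
  perpendicular bow (SD 0.30 of the chord) and a trapezoidal speed profile
  with a brisk rise (0.1 s), a launch burst (speeds elevated ~45% over the
  first frames, decaying over ~5 frames), multiplicative lognormal
  gait-cycle speed jitter (shape 0.45) that fades in after the ballistic
  launch, and a slower fall (0.3 s). Peak speeds are lognormal (median
  430 mm/s, shape 0.3) with a 260 mm/s floor: cued lunges are brisk, which
  is what the published clean latency statistics and ~0.33 m/s mean
  approach speeds imply. Short approaches compress the rise/fall so they
  remain lunges rather than sub-threshold creeps. An animal that was
  roaming at the cue keeps moving into the approach; a still or fidgeting
  animal holds still until movement onset, and re-orientation after recent
  movement imposes at least ~1.5 s of stillness before initiation — without
  this refractory gap the centered LI window makes such initiations
  undetectable by construction.
* **Tracking.** Front/rear LEDs 40 mm apart along the heading, white
  Gaussian noise of 1.5 mm per coordinate per LED (an AR(1)-correlated
  variant is available via `tracking_noise_ar1`), and rare dropouts.
* **Spikes.** Each neuron is an inhomogeneous Poisson process: baseline
  uniform in 3–12 Hz; 65% of neurons carry a two-phase evoked kernel
  (early 40–180 ms at 14 Hz, late 180–400 ms at 5 Hz at unit gain, so that
  the DS-evoked early-window rate is ~21 Hz). The trial gain is
  $\exp\{s_j \sum_v \beta_v (v - v_{\mathrm{ref}})\}$ with couplings on
  maximum radial velocity ($+4\times10^{-4}$ per mm/s), path efficiency
  ($+1.0$), and lever distance at cue onset ($-1.2\times10^{-3}$ per mm),
  computed from the noise-free realized features; the magnitudes were
  chosen so population IFDs land near the ±20–30% scale of the published
  effects. $s_j$ is a per-neuron lognormal coupling-strength multiplier
  (shape 0.4) reflecting the wide per-neuron effect distributions seen in
  real populations. NS trials scale the gain by 0.6; an optional infusion
  multiplies post-infusion gains by an attenuation factor.

Problem sizes used in the shipped tests are deliberately moderate: most
unit tests run 20–60-minute sessions with a handful of neurons; the
end-to-end recovery experiment pools two full 3-h sessions of 80 neurons
(≥100 cue-excited) per replicate across 20 replicates; the detector
calibration uses 10,000 simulated null neurons.

### Declared noise-propagation tolerances

Ground-truth features are computed from the noise-free pose over the true
movement window. Re-measured features differ because of (a) white
tracking noise entering frame-difference velocities (~45 mm/s per
coordinate at 30 frames/s) and path-length inflation on slow frames, and
(b) imperfect window recovery. The generator declares: lever distance at
cue essentially exact (~1 mm); maximum radial velocity positively biased
by roughly +100 mm/s (a max-statistic under velocity noise) with residual
SD a few hundred mm/s; path efficiency negatively biased with median
absolute distortion within 0.15. Tests assert at these declared levels.

## What passing tests do and do not show

The generator validates the implementation, not the biology: it emulates
the statistical structure the analysis assumes (renewal cue scheduling,
taxic approaches from variable starts, log-linear gain coupling,
Poisson spiking). Real data differ in ways the generator does not model:
non-Poisson spike-count dispersion, slow drifts in excitability,
history-dependent behavior, grooming and rearing postures that move the
LEDs without locomotion, and tracking artifacts beyond white noise and
dropouts.

Two honest limitations surfaced by the validation deserve emphasis,
because both are properties of the published procedure that ground-truth
simulation makes visible:

1. **Feature measurement error leaks into the population GLM tests.**
   All simultaneously recorded neurons share one design matrix. Any
   systematic difference between measured and true regressors (noise-greedy
   max statistics, path-length inflation, the small fraction of trials with
   mis-detected movement windows) biases every neuron's coefficients in the
   same direction, and the population t statistic scales that common bias
   by $\sqrt{n_\mathrm{neurons}}$. With paper-scale couplings the coupled
   regressors are recovered with the correct signs and Holm-significant
   tests in every replicate, but small pseudo-effects (a few percent IFD,
   chiefly on movement-onset latency) reach Holm-corrected significance in
   a substantial fraction of replicates. Pooling sessions dilutes but does
   not remove the directional component. An analyst applying this pipeline
   to real data should treat small but "significant" population IFDs on
   variables entangled with detection quality (latency, duration) with
   corresponding caution.
2. **The slope-vs-1 epoch test is anticonservative under estimation
   noise**, as described above; published no-change slopes a little below
   1 are exactly what errors-in-variables predicts.

## Numerical and degenerate-input conventions

Half-open spike bins $[lo, hi)$; strict threshold inequalities in bout
detection (ties are measure-zero); invalid LI frames fail both threshold
comparisons; bouts reaching the end of the trace are closed there and
flagged; zero-variance baselines make a neuron's excitation flag
degenerate-by-convention (excited if any post-cue activity exists);
constant regressors yield IDR 0 and IFD 0, flagged; undefined turn
efficiency propagates as missing and the GLM drops those trials listwise;
mixture fits require at least 1000 valid LI values with nonzero variance;
selection ties break by higher absolute loading, then variable name. All
times are seconds from session start with frame $k$ at $k/$frame-rate;
session files are written at 6-decimal precision and round-trip exactly at
that precision.
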