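---
title: "Models and methods in coordlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in coordlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordlearn)
```

coordlearn packages the measurement and analysis machinery of coordinated
rhythmic movement learning studies: experiments in which people learn to
produce a novel bimanual relative phase (typically 90°) with coordination
feedback, while 2AFC judgement tasks track the perceptual side of that
learning. Because human data for such studies are expensive, every stage is
paired with a synthetic generator with known ground truth, so the whole
pipeline is testable end to end. This vignette documents the models, the
tunable parameters, and the design choices made where the methods literature
leaves the details open.

## The movement generator

Human relative-phase production in this task is not described by any agreed
generative model; what is well established is a set of stylised facts:
before training only 0° and 180° are stable, 0° more so than 180°, and 90°
is the least stable of all; training with feedback makes 90° stable. The
generator is therefore deliberately minimal: a stochastic differential
equation on the relative phase $\phi$ (degrees) with the classic
two-attractor (HKB-style) intrinsic landscape plus one learned attraction
term,

$$ d\phi = \Big[-a\,\sin\phi - 2b\,\sin 2\phi + c\,\sin(\psi - \phi)\Big]
  \frac{180}{\pi}\,dt + \sigma\,\sqrt{dt}\;\varepsilon, $$

where $\psi$ is the target phase, $\varepsilon$ is standard normal, and the
left/right channels are $A\sin\omega t$ and $A\sin(\omega t + \phi(t))$.
Integration is Euler–Maruyama at the display sample rate (dt = 1/60 s);
at these rates the integration error is negligible relative to the noise
term, and the noiseless fixed points are verified exactly in the tests.

The parameters, their defaults, and what they control:

| parameter           | default | units        | role |
|---------------------|---------|--------------|------|
| `intrinsic_a`       | 1       | 1/s (scaled) | depth of the 0° attractor |
| `intrinsic_b`       | 0.75    | 1/s (scaled) | depth of the 180° attractor (stable iff $b > a/4$) |
| `coupling_strength` | 0       | 1/s (scaled) | learned attraction toward the target phase |
| `noise_sd`          | 35      | °/√s         | phase diffusion |
| `frequency`         | 1       | Hz           | movement frequency |
| `amplitude`         | 300     | px           | on-screen amplitude |
| `sample_rate`       | 60      | Hz           | display/sampling rate |
| `duration`          | 20      | s            | trial length |

With these defaults and zero coupling, linearising the drift gives
relaxation rates $a + 4b$ at 0° and $4b - a$ at 180°, hence stationary
phase SDs of roughly 12° and 17° — near-ceiling PTT20 at 0°, good but
lower PTT20 at 180° — while 90° is a repeller and scores near floor. That
reproduces the stylised stability ordering, which the test suite checks by
simulation. The defaults were fixed once, from this linearised reasoning,
not adjusted against any downstream test.

Two things the generator does *not* emulate: transfer (the learned coupling
is applied only at the trained phase, so improvements at 60°/120° never
arise from the generator itself), and any within-trial learning or fatigue
(skill is constant within a trial and changes only between sessions via the
skill schedule). Passing tests therefore demonstrate that the pipeline
measures what the generator produces — not that the generator reproduces
every feature of human data.

`make_skill_schedule()` encodes learning as a saturating growth of the
coupling across sessions, $c(s) = c_{\max}(1 - e^{-r(s-1)})$, with the rate
$r$ as the single "fast vs slow learner" knob used in the end-to-end
recovery tests.

## The kinematic pipeline

The scoring pipeline mirrors standard practice for this task: each channel
is mean-centred, low-pass filtered (Butterworth, 10 Hz cut-off), and
differentiated; the continuous phase of each channel is the four-quadrant
arctangent of normalized velocity and position; the relative phase is the
per-sample difference; PTT is the fraction of samples within the scoring
bandwidth of the target.

Choices the literature leaves open, and what this package does:

* **Filter order and phase.** 2nd-order Butterworth, applied forward and
  backward (`signal::filtfilt`), so the net filter has zero phase lag —
  essential when the quantity of interest *is* phase. Edge effects are
  reduced by odd-reflection padding (one second at each end). The two
  endpoint samples still carry the one-sided differentiation error; tests
  treat them accordingly, and a configurable `trim` is available (default
  0 s: no samples are dropped).
* **The arctangent.** A literal two-quadrant $\arctan(V/X)$ loses quadrant
  information and is dimensionally inconsistent. The package computes
  $\mathrm{atan2}(x/\hat A,\; v/(\hat A\hat\omega))$ with per-trial
  amplitude $\hat A$ (half the peak-to-peak of the filtered trace) and
  frequency $\hat f$ (dominant FFT peak, falling back to a caller-supplied
  hint for degenerate spectra). For $x = A\sin(2\pi f t + c)$ the result is
  exactly $360 f t + c$ degrees. Because position and velocity are scaled
  by the same amplitude estimate, slow amplitude drift cancels to first
  order — this is also why the position-perturbed displays (below) do not
  disturb the phase estimate.
* **Differentiation.** Central differences on the filtered signal
  (one-sided at the endpoints): at 60 Hz the bias on a 1 Hz sinusoid is
  below 0.2%, and noise amplification is modest because differentiation
  follows the low-pass filter.
* **Folding.** The relative phase is wrapped to (−180°, 180°] and folded by
  absolute value to [0°, 180°], pooling lead and lag, as is conventional in
  the bimanual coordination literature. Whether original analyses scored
  signed phase instead is generally not reported; folding is this package's
  documented convention, and the scoring is symmetric under swapping the
  two channels because of it.
* **Band edges.** A sample exactly at the bandwidth boundary counts as on
  target (closed band). Distance on the folded scale respects the
  identification of $\phi$ with $-\phi$: the distance between folded
  values $s$ and $t$ is $\min(|s-t|,\; s+t,\; 360 - s - t)$, so samples
  near 0° or 180° are measured along the shorter arc.

## The training protocol

Training sessions are 30 trials at the trained phase. Coordination feedback
(a colour change whenever the produced phase is inside the error bandwidth)
is shown on all trials except every fifth; after each feedback trial the
participant receives a knowledge-of-results comment keyed to their
percentage score. The printed comment brackets share their edge values
(25%–50% and 50%–75% both contain 50%); the package resolves this as
half-open intervals [lower, upper), with the top bucket closed at 100%.

Progression and stopping:

* If PTT20 exceeded 0.5 in at least 20 of the 30 trials, the feedback
  bandwidth for the next session narrows by 5°, through the schedule
  30° → 25° → 20° → 15° → 10° (never below 10°). Whether this criterion
  should count feedback trials only is unstated; all 30 trials are used.
* Training stops when the last two sessions were both *run at* the ±10°
  bandwidth with PTT20 above 0.6 in at least 20 trials each, or after 10
  sessions. The "run at ±10°" reading (rather than "bandwidth currently
  10°") matters: it makes the earliest possible stop the 6th session
  (five fading steps plus a second qualifying session at 10°), consistent
  with the 7–10 sessions that trained participants actually take in this
  paradigm. The stop rule is evaluated after the progression step of the
  same update. The inequalities are strict, as printed ("greater than
  0.5/0.6").

`run_protocol()` drives a virtual participant through this loop; the
property suite checks that a steep skill schedule reaches ±10° and stops
early with the criterion met, while a flat one uses all 10 sessions.

## The judgement task

Thresholds for discriminating 90° come from two interleaved transformed
1-up/2-down staircases, one probing comparison phases above 90°, one below.
Defaults: initial difference 30°, step up 10°, step down 54.88% of the step
up (5.488°), stop after 8 reversals. During the initial descent every
correct response steps down; the first error records the first reversal and
engages the 1-up/2-down rule. Open details and this package's choices:

* the initial-descent step size is unstated in the methods literature; the
  down step is used, for continuity;
* interleaving is a seeded uniform-random pick among unfinished staircases
  (deterministic under seed, not predictably alternating);
* the difference is floored at 1°, where a 2AFC comparison is still
  defined;
* reversal values are the difference at which the reversing response
  occurred, and threshold estimation averages reversals excluding the
  first, per staircase, then averages the two staircases.

**Where this staircase converges.** It is common shorthand that 1-up/2-down
targets the 70.71%-correct point, but that holds for *equal* up and down
steps. For unequal steps the stationary point is where expected movement
vanishes; a Markov analysis of the rule (stationary split between the
"zero correct" and "one correct" counter states) gives

$$ \frac{1-p^{*2}}{p^{*2}} = \frac{\Delta^-}{\Delta^+}, $$

so the 0.5488 ratio targets $p^* = 80.35\%$. The property suite verifies by
simulation that reversal-averaged estimates converge on the observer's
80.35%-correct difference (with a small upward finite-run bias from the
30° start and 8-reversal stop). Consequently, estimated "thresholds" from
this procedure sit systematically above the observer's 70.71% point — by an
amount governed by the psychometric slope — which is worth keeping in mind
when comparing absolute threshold values across procedures.

**The simulated observer** answers correctly with probability
$0.5 + (0.5-\lambda)F(\Delta)$, $F$ a cumulative Weibull rescaled so that
the lapse-free probability at `threshold_70` is $\sqrt{0.5}$. The default
shape (slope) is 3.5, the conventional 2AFC value (the QUEST default), and
the default lapse rate is 0.02.

**Position-perturbed displays** redraw the top dot's amplitude uniformly on
[0.25 × nominal, `max_amplitude`] at each of its own zero crossings —
amplitude changes at zero crossings keep both position and instantaneous
phase continuous — and set the bottom dot's amplitude to half the top's at
each of the bottom dot's own zero crossings. The two constraints from the
task (the dot must cross the midline; it cannot leave the screen) pin down
only the support of the draw, not its law; the uniform law and the 0.25
lower fraction are this package's parameterised choices. Because both
channels of the phase estimator normalise position and velocity by the same
amplitude, the perturbation leaves the mean relative phase intact (verified
to within 3° over seeded displays) while the half-cycle amplitude sequence
has positive variance — destroying exactly the relative-position
information the perturbation exists to destroy.

## The statistical layer

* **Contrast test.** `contrast_test()` computes per-participant scores
  $L_i = \sum_j x_{ij}\lambda_j$ with zero-sum weights and tests
  $H_0\!: \bar L = 0$ with $t = \bar L / \sqrt{\hat\sigma^2_L/n}$ on
  $n-1$ df. p values are two-sided (sidedness is rarely stated for these
  analyses; two-sided is the conservative default). If every participant is
  constant across conditions all $L_i$ are zero and the statistic is
  undefined; the package raises a degenerate-variance error rather than
  reporting $t = 0$.
* **Effect size.** $g = \bar L/\mathrm{SD}_L = t/\sqrt{n}$, with no
  small-sample correction: this operational definition reproduces the
  published $(t, n, g)$ triples for this paradigm exactly, so it is taken
  as the field's working definition.
* **Holm–Bonferroni.** A thin wrapper over `stats::p.adjust(method =
  "holm")`; the family is the set of untrained phases tested in one
  analysis. The unit tests replay the step-down rule by hand as an
  independent check.
* **Proportion of transfer.** Implemented as (change at the transfer
  phase) / (change at the criterion phase). Verbal descriptions of this
  quantity sometimes invert the ratio, but published percentage values
  (e.g. ≈ 64% transfer to a neighbour when the trained phase improves by
  0.41 and the neighbour by ≈ 0.26) are only consistent with
  transfer/criterion; the implementation follows the numbers.
* **Learning curves.** `fit_learning_curve()` fits
  $\mathrm{PTT20} = a\,e^{-b/S}$ by bounded nonlinear least squares
  (`minpack.lm::nlsLM`; start $a = \max(y)$, $b = 1$; bounds
  $a \in [0, 1.5]$, $b \in [0, 20]$ — the curve is monotone and
  well-conditioned here, and the bounds only prevent runaway on degenerate
  input). The learning rate is the exact derivative
  $(ab/S^2)e^{-b/S}$ evaluated at $S = 1$ (Baseline), implemented in
  `learning_rate()` and checked against a finite-difference oracle.
  Sessions are numbered consecutively in chronological order, Baseline = 1
  and Retention last; participants with fewer than 10 sessions contribute
  the sessions they have. How original analyses aligned 7–9-session
  participants on a 1..10 axis is unstated; consecutive numbering is this
  package's documented generalisation.

## Problem sizes in the test suite

The property suites run at sizes chosen to keep Monte-Carlo error well
below the asserted tolerances while remaining quick: 30 trials per phase
for the stability ordering, 20 trials per coupling level for monotone
learnability, 100–200 seeded staircase sessions for convergence, 50 seeded
perturbed displays, 100 paired-t comparisons, 2,000 null replicates for the
type-I error rate, and 200 noisy-curve replicates for parameter recovery.
Virtual-participant protocol runs use 5-s trials; trial length affects only
the per-trial sampling noise of PTT, not any of the logic under test.

## Known limitations

* The SDE generator and all its defaults are implementation choices; no
  distributional description of human trial-to-trial variability exists to
  fit them to. Ground-truth recovery results say nothing about model
  misspecification against real data.
* The generator does not produce transfer, so transfer statistics can only
  be exercised on constructed or real per-phase tables, not on raw
  simulated studies.
* The phase estimator assumes roughly sinusoidal, single-frequency
  movement; strongly non-harmonic movement would need a different
  instantaneous-phase method (a Hilbert-transform option is deliberately
  out of scope in this version).
* Reversal-averaged staircase estimates are biased relative to the
  observer's 70.71% point, as analysed above; comparisons should be within
  procedure, not across.
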