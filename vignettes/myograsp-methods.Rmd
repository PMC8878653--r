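---
title: "Methods: from surface EMG to grasp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from surface EMG to grasp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myograsp)
```

`myograsp` models the full control computation of a two-channel
myoelectric prosthetic hand: synthesize or load surface-EMG (sEMG),
condition it, segment it into overlapped windows, extract time-domain
features, classify the wearer's intent with a Fisher discriminant, and
drive a simulated dual-loop grasp controller. A separate kinematics
module solves the hand's finger-linkage loop-closure equations. This
vignette records the models, the tunable parameters, and the design and
numerical choices, in that order of the pipeline.

## The synthetic sEMG generator

Surface EMG during a sustained contraction is well approximated, for
classification purposes, by band-limited noise whose *amplitude* carries
the information: the interference pattern of many motor units summing
asynchronously. The generator therefore produces, per channel,

> saturate( envelope(t) × carrier(t) + baseline noise + powerline tone )

* **carrier** — white Gaussian noise shaped to 20–450 Hz by a 256-tap
  FIR band-pass and normalized to unit variance. The sharp FIR
  transition keeps spectral content above 450 Hz well below 1% of total
  power, consistent with the 0–500 Hz content of sEMG sampled at
  1000 Hz.
* **envelope** — a per-gesture gain (mV, RMS scale) gated by the
  schedule and smoothed by a first-order low-pass with a 50 ms time
  constant (`envelope_rise_ms`): neuromuscular drive does not switch
  discontinuously, and the smoothing produces the ramped onsets that a
  majority-vote controller must tolerate.
* **channel structure** — channel 1 responds strongly to `grasp`
  (flexor-side electrode) and weakly to `open`, channel 2 the reverse
  (extensor side). Defaults: gain 1.0 mV for the preferred gesture,
  0.25 mV cross-talk, 0 at rest. This two-muscle asymmetry is what makes
  the two gestures linearly separable — deliberately, since the study
  conditions the package emulates use electrodes on two antagonist
  forearm muscles.
* **baseline noise** 0.02 mV and an optional 50 Hz tone of 0.05 mV
  stand in for sensor noise and mains pickup.
* **saturation** at ±6 mV keeps every sample inside the stated
  physiological peak envelope.

All randomness flows from one explicit integer seed; identical inputs
give bit-identical recordings. `make_subject_dataset()` encodes the
acquisition protocol used throughout: alternating grasp/open bouts
(default 10 repetitions held 5 s each) separated by 2 s rests after a
1 s lead-in.

**What the generator does not emulate:** motor-unit action-potential
shapes, ECG and motion artifacts, electrode lift-off, sweating, muscle
fatigue, day-to-day electrode placement shifts, and the heavy-tailed
amplitude statistics of real sEMG. Tests passing on synthetic subjects
therefore demonstrate the *correctness of the computation*, not the
field accuracy of the classifier on recorded human data; real two-class
sEMG recognition typically lands in the 90–98% range rather than the
near-100% these clean conditions give.

## Signal conditioning

The software front end (`filter_spec()`) applies a gain (default 1 —
amplification is a hardware concern, units stay in mV), a 4th-order
Butterworth band-pass at 20–450 Hz, and a Butterworth notch at 50 Hz
with quality factor 30 (bandwidth f0/Q ≈ 1.7 Hz). No cutoffs were
prescribed by the modeled acquisition chain, so these are the standard
surface-EMG choices: 20 Hz removes motion artifact and baseline drift,
450 Hz stays under the 500 Hz Nyquist margin, and the notch frequency is
configurable to 60 Hz for other mains regions.

Both filters run forward–backward (`signal::filtfilt`), i.e. zero
phase, so per-sample gesture labels stay aligned with the activity that
produced them; the magnitude response is consequently squared, which
`filter_response()` reports as applied. One practical consequence of the
narrow notch: its impulse response rings for roughly two seconds, so
attenuation contracts are only meaningful a couple of thousand samples
away from the record edges, and the tests measure them there.

## Windows and time-domain features

Frames are `window_ms = 250` ms long and advance by `step_ms = 100` ms —
the standard real-time compromise: long enough windows for stable
statistics, short enough steps for sub-second decision latency. A
recording of `N` samples yields `floor((N − W)/S) + 1` left-aligned
frames. A frame's label is the majority of its per-sample labels, ties
going to the gesture that starts earlier in the window (label semantics
over transitions are otherwise arbitrary; this rule is deterministic).

Six per-channel window statistics are implemented exactly as defined:
iEMG `sum(|x|)·dt` (the discretized rectified integral, `dt` = one
sample period), RMS, MAV, thresholded zero crossings, sample variance
(n−1 denominator) and the raw minimum. Two definitional notes:

* **Zero crossings.** The default counts consecutive pairs with
  `x[n]·x[n−1] < 0` and `|x[n] − x[n−1]| ≥ threshold` (default
  0.01 mV — the threshold suppresses baseline chatter; no canonical
  value exists, so it is exposed). Some published statements of the
  thresholded-ZC formula invert the sign condition and thereby count
  *concordant* pairs; `feature_zc(literal = TRUE)` implements that
  variant verbatim so results computed under either reading can be
  audited. The default is the standard crossing count.
* **MIN.** Defined here as the raw per-channel minimum of the window.
  With symmetric noise it behaves as a (negated) amplitude measure;
  users wanting `min |x|` can compose it themselves.

The default feature selection for gesture recognition is
`{VAR, RMS, MIN}` per channel — six features per window — with the full
set `{iEMG, RMS, MAV, ZC, VAR, MIN}` selectable. Feature columns are
channel-major (`ch1_VAR, ch1_RMS, ch1_MIN, ch2_VAR, ...`).

## Fisher LDA, from first principles

With classes `i = 1..c` (here `open` and `grasp`), `fit_lda()` computes
class means `u_i`, the grand mean `u` over all `m` training windows,
the count-weighted between-class scatter
`Sb = Σ n_i (u_i − u)(u_i − u)'` and the within-class scatter
`Sw = Σ_i Σ_{x∈i} (x − u_i)(x − u_i)'`. Two conventions deserve
explicit statement because loose phrasings of the algorithm leave them
ambiguous:

* the grand mean averages over *samples*, not over class means — only
  then does `Sb + Sw` equal the total scatter about `u`;
* no additional weighting beyond the `n_i` factor in `Sb` (and the
  implicit per-sample summation in `Sw`) is applied for unbalanced
  classes; the decomposition above already accounts for class sizes.

The discriminant maximizes the generalized Rayleigh quotient
`J(w) = (w'Sb w)/(w'Sw w)`. Numerically: `Sw` is ridge-regularized with
`eps = 1e-6 · trace(Sw)/d` (absolute floor `1e-12`) — deterministic and
scale-aware, protecting against collinear features or few windows —
then Cholesky-whitened (`Sw + eps I = R'R`) and the symmetric matrix
`R^{-T} Sb R^{-1}` eigendecomposed; at most `c − 1` directions are kept
(the rank of `Sb`). Columns of `omega` are unit-norm with their first
non-negligible component positive, so a fit is a pure function of its
input up to floating-point rounding and serializes reproducibly.

The decision rule, unstated in common descriptions of LDA control, is
the simplest consistent one: assign to the nearest projected class
mean, i.e. a midpoint threshold on the single score for two balanced
classes. Exact ties go to the first class in the model's class order.
Two-class correctness is verifiable against the closed form
`w ∝ (Sw + eps I)^{-1}(u_1 − u_2)`, and the test suite also
cross-checks directions and predictions against an independent LDA
implementation.

## Evaluation protocol and baselines

Recognition is scored on a per-subject set of 128 feature windows, 64
per gesture (drawn seeded from the session's windows), split 64
training / 64 test, stratified so each side holds 32 of each gesture.
"128 samples" is read as 128 feature *windows* — the only reading under
which a 64/64 split of an LDA training set is well-defined.
Accuracy is `100·trace/total` of the test confusion matrix;
`error_rate()` is defined as its exact complement so the two always sum
to 100.

The comparison harness runs, with the same split per subject: Gaussian
naive Bayes (`e1071`, fitted per-class standard deviations floored so
zero-variance features cannot degenerate), Euclidean k-NN (in-package,
`k = 5`, vote ties deterministically to the smaller class index — the
reason it is not delegated to an external k-NN, whose tie-breaking is
randomized), CART with Gini impurity (`rpart`, depth ≤ 4,
deterministic), and the package's LDA. `k`, the depth and the variance
floor have no prescribed values in the modeled protocol; the defaults
are conventional and exposed in the configuration. The harness has a
pluggable classifier slot (a named `function(train, test)` list), which
is where an SVM would be added; none is bundled, since a from-scratch
QP solver is outside the package's scope and no installed dependency is
treated as part of the core method.

## The grasp controller

Frame decisions stream into a two-stage actuation layer:

1. **Confidence gate.** A window whose projected score's
   nearest/second-nearest margin is below `gate = 0.5` × the inter-mean
   projected distance is replaced by `rest`. Rest windows project near
   the midpoint of the two gesture means (both channels quiet, and the
   channel-symmetric defaults keep rest centred), so the gate is what
   prevents a two-class discriminant from actuating on no activity.
2. **Majority vote** over the last `m = 3` decisions (odd; ties to the
   most recent raw decision) rejects single-frame flickers at a cost of
   two extra steps (200 ms) of latency. The first correct command after
   a clean gesture onset therefore arrives within
   `window_ms + m·step_ms` = 550 ms.

The controller itself runs one tick per frame step (100 ms). Closing
advances the motor `position_rate = 1` mm per tick toward the
`stroke = 10` mm limit (position loop). A grasped object is modeled as
linear: current = `stiffness × (position − contact)` beyond its contact
point. The moment simulated current reaches `current_limit = 1` A the
position is pulled back onto the limit isocline
(`contact + limit/stiffness`) and the mode latches to `holding` — so
current never exceeds the limit for more than the single tick in which
contact was discovered (with the default rates it never exceeds it at
all, since the pull-back happens within the tick). With no object the
motor holds at the stroke limit. `open` retracts monotonically to 0 and
`idle`. None of the loop gains, rates or limits are prescribed by the
modeled hardware description; these are the simplest dynamics that
exhibit the described behavior, and all are configurable. Current
monitoring participates only in grasp termination, not in intent
recognition.

## Finger-linkage kinematics

The underactuated finger is a one-degree-of-freedom linkage described
by two closed vector loops over eight links, `r4 + r6 = r3 + r5` and
`r1 + r2 + r7 = r3 + r5 + r8`, under the package's convention: x
rightward, y upward, direction angles counter-clockwise from +x, with
link angle assignments `r1→θ2` (crank), `r2→θ4`, `r3→θ1` (proximal
phalanx), `r4→θ4+δ`, `r5→θ3` (distal phalanx), `r6→θ5`, `r7→θ5+β`,
`r8→θ7` (frame constant). δ and β are rigid offsets of the two ternary
coupler bodies. The four XY scalar components of the loops were
re-derived from this convention rather than transcribed — published
component forms of such loop equations are prone to sign/trig typos —
and are validated by tests that forward-construct consistent poses and
check the residual vanishes to machine precision.

`solve_pose()` runs Newton iteration with the analytic 4×4 Jacobian on
the four non-driven angles (driven coordinate configurable, default the
crank θ2), to a residual norm below `1e-12` mm in ≤ 100 iterations; a
Jacobian reciprocal condition number below `1e-12` raises a
singular-configuration error (mechanism dead point), non-convergence a
no-solution error. Sweeps use continuation — each solution seeds the
next guess — which keeps the trajectory on one assembly branch; the
assembly branch itself is selected by the initial guess, and
`reference_pose()` provides an extended-finger guess for the packaged
geometry. An independent oracle (progressive 2-D grid over the phalanx
angles with the first loop closed in closed form) agrees with Newton to
better than `1e-3` rad in the tests.

**The reference geometry is illustrative and synthetic.** The physical
hand's link dimensions are not published, so the packaged configuration
(`reference_geometry()`, also shipped as
`inst/extdata/finger_reference.yaml`) was constructed once by
forward-placing a consistent extended pose and then calibrating the
slider-crank radius (θ2 = θ_ref + asin(s/a), a ≈ 10.47 mm) so that the
full 10 mm actuator stroke flexes the proximal joint through its
configured 84.5° design limit. The 84.5°/135° joint limits are treated
as configuration constants throughout — design targets, not solvable
outputs. Scaling all link lengths by a common factor leaves every
solved angle unchanged (the residuals are homogeneous in length), which
the tests exploit as a similarity-invariance check.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen to exercise the contracts while staying fast: 10 synthetic
subjects of 141 s each for the recognition protocol, 200 random
problems for the closed-form discriminant check, 1000 random windows
for the feature identities, 100 randomized sessions for controller
safety, and 101-pose stroke sweeps for kinematics. Every stochastic
path takes an explicit seed and is bit-reproducible; the acceptance
script derives all of its seeds from its `--seed` argument.

## Known limitations

* Synthetic subjects are much cleaner than recorded sEMG (see the
  generator section); accuracy numbers obtained here characterize the
  pipeline, not human performance.
* The discriminant is strictly linear; heavily overlapping gesture
  classes (fatigue, electrode shift) would need more features or a
  nonlinear classifier.
* The controller's object model is a linear spring with a single
  contact point; no dynamics, friction or slip.
* The kinematics module covers the planar finger loops only — no
  statics, spring compliance, contact mechanics, or the thumb's passive
  rotation.
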