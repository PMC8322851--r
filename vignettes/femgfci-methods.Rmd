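---
title: "Facial-EMG intent decoding without hardware: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial-EMG intent decoding without hardware: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femgfci)
```

## The problem

A face-computer interface (FCI) maps facial-muscle activity, recorded as
surface electromyography (fEMG), to machine commands, so that people without
limb function can steer an assistive robotic arm. Six facial movements are
used: lift eyebrows (LEb), slow left and right single blinks (LEBO, REBO),
a jaw clench ("bick", Bk), and tilting the mouth left or right (TML, TMR),
plus REST. Six monopolar electrodes sit on the forehead, the two outer eye
corners, the masseter, and the two mouth corners; each movement has one
"main" channel, but movements bleed into neighbouring electrodes, so simple
per-channel thresholding is not enough and a classifier over multi-channel
window features is used instead.

This package implements the entire offline-and-online pipeline — synthetic
signal generation, filtering, windowing, feature extraction, classifier
selection, a two-stage finite-state intent decoder, and a Cartesian arm
simulator closing the loop on a drinking task — with no dependence on
recording hardware.

## Synthetic fEMG: what it emulates and what it does not

Surface EMG during a sustained contraction is well approximated by
band-limited, amplitude-modulated Gaussian noise. The generator realises
each movement epoch as white noise band-passed to 20–450 Hz, normalised to
unit RMS, shaped by a raised-cosine on/off envelope with 100 ms ramps, and
scaled per channel by a cross-talk gain matrix. On top of that every channel
carries always-on baseline instrumentation noise (sd 0.02 in signal units)
and a common 50 Hz mains sinusoid (amplitude 0.01, small because the bench
rig the package emulates is well grounded; both are configurable).

The default gain matrix encodes the qualitative structure seen on real
recordings: the clench (Bk, main gain 1.0 on the masseter channel) bleeds
into all six channels at 10–25 % of its main gain; the eyebrow lift
(LEb, 0.6) is confined to the forehead; the mouth tilts (TML/TMR, 0.4) leak
slightly to the eye-corner and masseter channels; the blinks (LEBO/REBO,
0.15) are the weakest, with a small blink leak onto the forehead. The
amplitude ordering Bk > LEb > TML = TMR > LEBO = REBO and the cross-talk
topology are the modelled facts; the numeric gains are package defaults,
chosen once to reproduce that ordering, and exposed in
`crosstalk_profile()`.

The acquisition protocol mirrors a standard session: per round the six
movements appear once each in seeded random order, each action lasting 3 s
after its prompt with a 5 s rest before it; 20 rounds form a dataset. All
generation is seeded and bit-reproducible.

What the generator does **not** model: motor-unit physiology, electrode-skin
impedance drift, fatigue, movement artefacts, or correlated cross-channel
noise (cross-talk here is independent noise scaled per channel, not a shared
source). Classification on this data is therefore easier than on real
recordings; passing tests demonstrate that the pipeline's mechanics are
correct, not that its accuracies transfer to human subjects.

## Preprocessing

The filter chain is an IIR notch at the mains frequency (RBJ biquad,
Q = 30 — the quality factor is a package default) followed by a
second-order Butterworth band-pass, 10–450 Hz at 1,000 Hz sampling. Both
filters are applied causally by default, because the online decoder must be
causal and offline and online paths are required to share one code path; a
zero-phase forward-backward mode (`causal = FALSE`) exists for offline
exploration only. The stateful filter core carries per-channel state between
chunks, so streaming chunk-by-chunk reproduces whole-signal filtering to
machine precision — the property the online loop relies on.

## Windowing

A 200 ms window slides in 50 ms steps. Per prompt, the span from 1,500 to
2,650 ms after the prompt yields 20 windows carrying the prompt's label
(the first 1.5 s is discarded as reaction-and-ramp time), and the 350 ms
immediately before the prompt yields 4 REST windows. Window offsets are
half-open, `[start, start + 200 ms)`, so the last active window starts at
2,450 ms and ends exactly at 2,650 ms; this convention is what makes the
counts come out to 20 and 4 exactly. With 20 rounds this gives
20 × 6 × 24 = 2,880 windows, and stratified 5-fold splits of
2,304 train / 576 test rows with 320/80 per action class and 384/96 REST.
Stratification is a design choice: those per-class counts are only
achievable under exact per-class 80/20 splits.

## Features

Eight time-domain features per channel per window, for a window
$x_1 \dots x_N$:

* MAV $= \frac{1}{N}\sum |x_i|$, RMS $= \sqrt{\frac{1}{N}\sum x_i^2}$,
  MAX $= \max x_i$;
* MC $= \frac{1}{N}\sum_{i<N} (x_{i+1}-x_i)$ — note this telescopes to
  $(x_N - x_1)/N$, which the tests assert; it carries almost no
  discriminative information, consistent with it ranking last;
* MAC $= \frac{1}{N}\sum_{i<N} |x_{i+1}-x_i|$;
* ZC = number of strict sign changes ($x_i x_{i+1} < 0$; exact zeros never
  count);
* VAR: the standard sample variance (denominator $N-1$). A variant
  truncating the sum at $i = N-1$ is available as `var_as_printed = TRUE`;
  the truncated form is not a named statistic, so the textbook estimator is
  the default;
* ARC: the three coefficients of an AR(3) model
  $x_i = \sum_{k=1}^{3} a_k x_{i-k} + e_i$. The estimation method is a
  design choice: Yule-Walker on the biased, non-demeaned autocovariance
  (deterministic and always stable), with the covariance/least-squares
  method selectable. Only the coefficients are features; the residual
  variance is not.

Design matrices come in three modes: `SF:<family>` (one family on all six
channels — 6 columns, 18 for ARC), `AF` (all families, 60 columns), and
`EF` (the elected subset VAR/RMS/MAC, 18 columns). Columns are
channel-major with a fixed canonical feature order, so single-feature
blocks are contiguous and reproducible.

## Classifier comparison

`model_registry()` provides the twelve classifiers compared offline: LR,
NB, DT, linear-kernel SVM, MLP, Ridge, RF, QDA, Ada, GBC, LDA and LGBM.
Hyperparameters are fixed library defaults under a global seed; no search
is performed. Three entries deserve a note:

* **Ridge** is the closed-form L2-penalised least-squares classifier on
  ±1 one-hot targets (argmax decision), i.e. the classical "ridge
  classifier", implemented directly since it is three lines of linear
  algebra;
* **Ada** is SAMME AdaBoost over depth-1 CART stumps, implemented in the
  package (no boosting-by-reweighting library is among the dependencies);
* **GBC** is exact-split depth-wise gradient boosting and **LGBM** is the
  leaf-wise histogram variant (`grow_policy = "lossguide"`, 31 leaves) of
  the same boosted-tree family — the two ends of the design spectrum that
  the two names conventionally denote; both are backed by xgboost.

Evaluation is stratified 5-fold cross-validation (`run_cv()`), reported as
per-fold accuracies with means and standard deviations.
`rank_single_features()` orders the eight families by model-averaged
single-feature accuracy (ascending, ties broken by the canonical feature
order), and `feature_reduction_curve()` drops families one at a time in a
given order — by default MC, ZC, ARC, MAV, MAX, VAR, RMS, MAC, i.e. the
ascending ranking — recording CV accuracy and the feature-computation cost
of the surviving set. Cost is measured once per family and summed over
survivors, which makes the curve monotone in the set size by construction
while still being a wall-clock measurement. The last three surviving
families, VAR, RMS and MAC, are the elected features (EF) used online.

Two statistical helpers mirror the offline/online comparisons: a paired
t-test across subjects per model (`compare_modes()`; with identically zero
paired differences it returns p = 1, and with non-zero constant differences
it raises an error rather than reporting an infinite t statistic), and a
two-sided permutation test for task-time differences
(`permutation_test()`, default 10,000 draws with the add-one estimate
(b+1)/(m+1), switching to exact enumeration whenever the number of distinct
regroupings is at most 10^6).

## The two-stage decoder

Window predictions arrive every 50 ms. Stage one: a selector movement —
REBO→X axis, LEBO→Y, TMR→Z, TML→gripper — must persist for
`debounce_windows` consecutive windows (default 5, i.e. 250 ms; the
recognition dwell is deliberately configurable) before it is accepted,
which suppresses single-window misclassifications. Acceptance emits the
selection broadcast ("Left or right", "Forward or back", "Up or down",
"Gripper") and starts a 5 s deadline. Stage two: LEb selects the positive
direction and Bk the negative, after a shorter second debounce (default 3
windows, 150 ms): the windows straddling a burst onset contain mostly ramp
and are easily misread as one of the weak movements, and acting on a single
such window would start motion in the wrong direction and void the
selection. Axis motion is hold-to-move: it continues while the accepted
label persists (each such window refreshes the deadline), and stops only
after
`rest_hysteresis_windows` consecutive non-matching windows, so a lone
misclassified window cannot stutter the arm. The gripper is momentary and
self-locking: LEb closes, Bk opens (the broadcast table's convention;
`gripper_swap = TRUE` flips it, since the prose and the table of the
original interface description disagree), and the command is honoured only
below 10 cm with the arm over the desktop — otherwise a refusal is logged
and nothing moves. If the second action does not begin within the 5 s
deadline the decoder silently returns to stage 0.

The decoder's entire reachable output is audited exhaustively in the tests:
eight commands (±X, ±Y, ±Z, close, open) and twelve broadcast strings, and
nothing else.

## Arm simulation and the drinking task

The arm is a point-model end effector moving at 3 cm/s along one Cartesian
axis at a time inside a workspace of x 20–120, y −70–100, z 5–120 cm,
clamped at the boundaries. Only the +Y desktop edge may be overhung, by at
most 30 cm and only within a mid-desktop x band (55–85 cm), which is where
the mouth zone sits (y 100–130, z 60–100 cm); the exact mouth geometry is
configurable since only the overhang is fixed by the setting being
modelled. The cup (7.5 cm diameter, 13 cm tall) starts on a 30 × 15 cm
saucer centred at (90, 45, 0); scenarios draw the cup position on the
saucer and the gripper start (x, −45, z) uniformly at random under a seed.
Closing within a 5 cm grasp radius of the cup's mid-body picks it up
(roughly cup radius plus clearance — the soft gripper has no quantified
capture region); while held the cup rides with the gripper; opening
releases it where the gripper is. "Drinking" is holding the cup inside the
mouth zone for at least 1 s. The task clock starts at the first motion
command and stops when the cup is back on the saucer.

Two drivers close the loop. `scripted_policy()` is the deterministic
"virtual button" solver whose elapsed time equals the Manhattan path
length divided by 3 cm/s plus the drinking dwell — the closed-form check
used in the tests at 5 %. `run_fci_task()` runs the full pipeline: a
planner looks at the arm's actual state, chooses the next intent (selector,
direction, hold duration), synthesises the corresponding fEMG, streams it
through the causal filters, classifies every 200 ms window, decodes, and
applies the commands. Because the planner re-plans from the observed state
after every segment, occasional misclassifications are corrected rather
than accumulated. Its positioning tolerance is 2 cm: the shortest
recognisable burst (about 0.7 s — bounded below by the envelope ramps and
the debounce) moves the arm about 2–3 cm, so a finer tolerance would
oscillate around the target while 2 cm still sits comfortably inside the
5 cm grasp radius and the 10 cm gripper-height guard.

## Numerical choices and degenerate inputs

* Filters are applied as direct-form-II-transposed IIR with explicit
  carried state (compiled); chunked and whole-signal outputs agree to
  better than 1e-9.
* The AR(3) Yule-Walker system falls back to zero coefficients when the
  window has zero power (all-zero windows are legal inputs, e.g. in the
  tie-break tests).
* LDA/QDA retry once with a small deterministic jitter
  (1e-3 × data sd) when a class has exactly collinear features — possible
  on degenerate synthetic designs, not on noisy data.
* The permutation test compares statistics with a 1e-12 relative guard so
  ties at the observed value count as at-least-as-extreme.
* Fold assignment is per-class round-robin after a seeded shuffle, so any
  class count divisible by k splits exactly.

## Problem sizes used in the shipped checks

The package's own acceptance checks run the full 20-round protocol
(2,880 windows) for the segmentation arithmetic and the GBC + EF
cross-validation, a 4-round training set for the closed-loop drinking task
(enough for near-ceiling accuracy on the synthetic profile), and
1,000 random windows for the feature-oracle comparison. These sizes are the
package's chosen study conditions; the generator defaults are never moved
to make a check pass.

## Known limitations

* Synthetic separability is high by construction; the 90 % closed-loop
  accuracy bound is a mechanics check, not a claim about human subjects.
* The LGBM registry entry is leaf-wise histogram boosting implemented via
  xgboost, not the LightGBM binary; split-finding details differ.
* EDF support covers the subset the package writes (16-bit EDF+C, 1 s
  records, one annotation channel); it is not a general EDF reader.
* The arm model has no joint space, dynamics or collision geometry — the
  interface being modelled delegates those to the manipulator API, and so
  does the simulator.
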