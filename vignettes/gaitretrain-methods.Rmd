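---
title: "Methods: coordination retraining analysis, model and synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordination retraining analysis, model and synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitretrain)
```

## The analysis in one paragraph

Walkers with elevated knee loading can, with per-step haptic feedback,
learn to walk with less gastrocnemius activity; because the gastrocnemius
dominates the muscle-generated knee contact force in late stance, the
late-stance contact-force peak should fall with it. This package
implements the full measurement chain for such experiments: EMG
conditioning and MVC normalization, step segmentation from the vertical
ground reaction force, the adaptive vibration-feedback controller,
selection of the analyzed 50-step windows and representative steps,
EMG-constrained static optimization on a reduced musculoskeletal model,
axial knee-contact-force metrics, and normality-gated paired statistics
with false-discovery-rate control.

## Signal processing

EMG is band-passed at 30–500 Hz (4th-order Butterworth), rectified and
low-passed at 6 Hz (4th order); kinematics and ground reaction forces are
low-passed at 6 Hz (orders 6 and 4). All filters run forward-backward
(`filtfilt_zp()`), which cancels phase and *squares* the magnitude
response; the stated orders are the design orders of the one-pass filter,
matching standard practice. The band-pass requires a sampling rate above
1 kHz (the 500 Hz edge must stay below Nyquist); envelopes are therefore
synthesized or recorded at 2 kHz in raw mode.

Steps are contiguous runs of vertical GRF above a 20 N threshold, with
runs shorter than 0.3 s discarded; neither value is dictated by the
protocol, so both are configurable (`default_config()`). Stance windows
are half-open sample intervals `[onset, offset)`, 1-based (the R idiom;
the underlying design is language-agnostic 0-based — only the index origin
differs). Normalized EMG is *not* clipped at 1: walking can exceed MVC
effort, and clipping would bias percent changes downward. Percent-stance
curves use a 101-point grid (0–100%). The 40 ms electromechanical delay is
applied as an integer-sample shift with first-value padding, avoiding a
spurious onset transient.

## Feedback controller

Vibration counts partition the percent-change axis: more than −5% → 2
vibrations, between −5% and the goal → 1, at or beyond the goal → 0.
The boundary reading is: exactly −5% earns one vibration ("greater than
95% of baseline" read strictly) and exactly −goal earns none ("below the
goal" read inclusively). The adaptive goal (10 → 20 → 30%, capped) updates
only at trial boundaries, from the *within-trial* 50-step moving average;
qualification (10% for session 1, 20% for the session-2 early finish) uses
the same moving-average machinery, and windows never span trial
boundaries. These choices are ours where the protocol's language is open;
they are exercised directly by the unit tests.

## Window and step selection

Two 50-step selectors exist: the window with the greatest mean
gastrocnemius reduction, and the analysis window minimizing the *sum* of
gastrocnemius and vasti mean percent changes (reported downstream, since
it represents the loading obtainable once compensatory vasti activity
subsides). Window means are arithmetic means of per-step percent changes,
ties break to the earliest start, and windows stay within a trial. Five
representative steps per condition are those whose stance-mean
gastrocnemius EMG lies closest to the target level — the baseline-trial
mean for baseline steps, the selected window's mean for feedback steps —
with ties to the lower step index. Both selectors are verified against an
exhaustive enumeration oracle.

## Musculoskeletal model and static optimization

A full 3D lower-limb model is a non-goal; the model here is a reduced
sagittal-plane stand-in that preserves the *optimization structure* —
redundancy, passive forces, EMG constraints — at desk scale. Three joints
(hip, knee, ankle; flexion, extension and plantarflexion positive,
respectively, for both angles and moments) are actuated by eight lumped
muscles with constant moment arms, rigid tendons, a Gaussian active
force-length curve (`f_L(1) = 1`, width 0.45) and an exponential passive
curve (zero at or below optimal length). Normalized fiber length follows
joint excursion, `ℓ̃ = 1 − Σ_j r_mj (θ_j − θ_ref,j)/ℓ_opt`.
Force-velocity effects and tendon compliance are omitted — each frame is
quasi-static. The default parameter table (`default_muscle_table()`) uses
order-of-magnitude physiological values chosen so baseline walking yields
a two-humped contact force of roughly 2–3 body weights.

Per frame, with reserve moments eliminated, the problem

min Σ a² + w_res Σ (M_j − Σ r F(a))², 0 ≤ a ≤ 1 (plus EMG boxes)

is a strictly convex box-constrained quadratic program, solved exactly by
a primal active-set method. Reserve actuators (`w_res = 1000`) guarantee
feasibility; frames where a reserve exceeds 5% of its joint moment are
flagged. Numerical notes: the QP's curvature spans ~2 to ~10⁸, so
objective values near 10⁷ cannot resolve activation differences of 10⁻⁶
in double precision; along nearly-flat recruitment directions two
solutions can differ by a few 10⁻³ in activation at numerically identical
objectives. Tests therefore demand 10⁻⁶ agreement with the enumeration
oracle on small well-conditioned frames and 5×10⁻³/10⁻⁶-relative-objective
agreement on full-model frames. The activation lower bound is 0; the 2%
EMG constraint is a *relative* band around the scaled target, intersected
with [0, 1] (a warning flags targets above the ceiling).

The EMG-to-activation scale factor divides stance means (activation mean /
delayed-EMG mean per representative baseline step, averaged over the five
steps); the alternative pointwise-ratio reading of the calibration
sentence is noisier wherever EMG approaches zero, which is why the
stance-mean reading was chosen.

Knee contact force is the axial superposition
`(interseg + Σ c_m F_m) / (m g)` with per-muscle axial projection
coefficients `c_m`; the intersegmental axial force is a pipeline *input*
(from files or the generator), not recomputed by inverse dynamics.

## Statistics

Paired differences are gated by Shapiro–Wilk at α = 0.05 (the study α
reused for the gate, which the protocol does not state separately):
normal → two-sided paired t, otherwise two-sided Wilcoxon signed-rank
(exact for n ≤ 25). The two primary outcomes bypass multiplicity
correction; every exploratory outcome enters one Benjamini–Hochberg family
per report (the family composition is configuration, since the source
analysis does not enumerate it). All-zero difference vectors return p = 1
with a degenerate flag; nonzero constant differences (t undefined) return
p = NA with the flag rather than a fabricated value.

`paired_power_n()` solves the continuous noncentral-t sample-size equation
and rounds. For the 0.38 ± 0.39 BW late-peak effect at power 0.9 and
α = 0.05 the continuous solution is 13.14: the nearest-integer convention
(the default) gives the published 13, while the smallest integer whose
power actually reaches 0.9 is 14 (`rounding = "ceiling"`). The strict mode
is the one that satisfies the Monte-Carlo bracket
`power(n) ≥ target > power(n−1)`; the default reproduces the
determination as published. Both are tested.

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults *are* the stated experimental world: 13
participants, six-minute feedback trials (150 feedback-leg steps at a
0.65 ± 0.03 s stance), true gastrocnemius reductions
`r_i ~ N(25%, 15%²)` truncated at zero, per-step AR(1) noise (SD 4
points, φ = 0.7), and a saturating-exponential learning curve reaching
95% of `r_i` by the end of trial 2 (most responders succeed within two
trials). Envelopes are Gaussian bumps on the percent-stance axis whose
centers *lead* the corresponding moment lobes by ~6% stance — the 40 ms
electromechanical delay — so that delayed EMG aligns with the
static-optimization activation waveform; a raw mode modulates 30–500 Hz
band-limited carrier noise by the envelope so the full conditioning chain
is exercised. Vertical GRF is a clean double hump (peaks ≈ 1.15 BW).

Vasti compensation has three parts, all documented because two go beyond
the minimal parameter list: (1) the coupling `κ_i × realized reduction`
(κ ~ N(1.5, 0.5²), putting the mean vasti increase near +38% at a 25%
reduction); (2) independent per-step AR(1) vasti noise (SD 12 points) —
without it the vasti envelope is perfectly collinear with the
gastrocnemius reduction, and since the mean vasti increase exceeds the
mean reduction, the summed gastroc+vasti window objective would
degenerately select the *least*-reduced window; (3) a participant-level
co-contraction transient (≈ +30% vasti at the start of training, decaying
with the learning curve), the elevated-co-contraction-early-in-learning
mechanism familiar from motor-learning studies. Together these reproduce
the observed pattern that the joint-objective window sits slightly below
the best-gastrocnemius window in reduction but far below it in vasti cost.

Moment coupling: the late-stance ankle plantarflexion and knee flexion
lobes shrink by `γ × realized reduction` (γ = 0.5), feedback trials gain
early-stance dorsiflexion proportional to the reduction, and the
intersegmental axial force is held at baseline — contact-force changes
flow through the muscles.

Not emulated: early-stance knee-extension-moment increases (so the
generator under-represents early-peak growth mechanisms other than vasti
EMG), kinematic variability beyond noise, soleus/hamstring strategy
changes, and any physiological EMG-force dynamics. A green end-to-end
test therefore establishes that the *pipeline* recovers what the
generator injects — not that the model reproduces any particular
participant's physiology.

## Parameter recovery and calibration checks

The recovery acceptance test runs 20 independent 13-participant cohorts
and estimates each participant's reduction as the final-trial mean
percent change divided by that trial's known mean learning level — no
best-window selection, which is optimistically biased by construction.
The exact target of this estimator under the generator is the
truncated-normal mean `E[N(25, 15²) | r ≥ 0] ≈ 26.6%` (truncation at zero
is part of the stated world; 25 is the pre-truncation location), and the
test asserts that this target lies inside the 95% CI across replicates,
plus a coarse 3-point bound on the distance to 25. Type-I error of the
gated paired test is checked against 0.05 ± 0.01 over 10 000 seeded null
replicates; the directional end-to-end property (every responder with
`r ≥ 5%`, γ > 0 and small κ reduces the late-stance peak) runs on a
six-participant modeled cohort.

## Known limitations

Constant moment arms and rigid tendons understate fiber-length effects;
the contact-force scale is only order-of-magnitude physiological; the
reduced model cannot separate medial/lateral compartments; the generator's
clean GRF makes step segmentation easier than on real force plates; and
session-level clinical quantities (pain, retention) are out of scope.
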