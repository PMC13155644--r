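# gaitretrain

Analysis pipeline for **muscle-coordination gait retraining** experiments in
which walkers receive per-step haptic biofeedback instructing them to reduce
gastrocnemius electromyography (EMG), with the downstream goal of lowering
the late-stance peak of **knee contact force** — an interventional target in
knee osteoarthritis, where the gastrocnemius dominates the muscle-generated
knee load in late stance.

The package is written for biomechanics and neuromechanics researchers who
need a tested, reproducible desk-scale implementation of this analysis:
from raw EMG and ground-reaction-force time series through the adaptive
feedback controller, analysis-window selection, EMG-constrained static
optimization on a reduced musculoskeletal model, knee-contact-force metrics,
and the cohort statistics. A synthetic gait-cohort generator with known
ground truth stands in for participant data and backs the validation suite.

## What it computes

**EMG conditioning.** Band-pass (30–500 Hz, 4th-order zero-phase
Butterworth), full-wave rectification, low-pass (6 Hz, 4th-order
zero-phase), normalization by each muscle's maximum voluntary contraction
(MVC) value, and stance-phase averaging per step (stance detected from the
vertical ground reaction force at a 20 N threshold).

**Feedback controller.** After each step the percent change of stance-mean
gastrocnemius EMG from baseline maps to a vibration count: 2 if the
reduction is under 5%, 1 between 5% and the adaptive goal, 0 at or beyond
the goal. The goal starts at 10% and tightens by 10 points (to a 30% cap)
whenever a 50-step moving average within a trial beats it. Sessions
qualify at a 10% (session 1) or 20% (session 2) average reduction over 50
consecutive steps.

**Static optimization.** Per frame of the stance grid, muscle activations
solve

    min  Σ_m a_m² + w_res Σ_j ρ_j²
    s.t. Σ_m r_mj F_m(a_m) + ρ_j = M_j ,   0 ≤ a_m ≤ 1,
         F_m(a) = F_max,m (a f_L(ℓ̃_m) + f_P(ℓ̃_m))

on a reduced sagittal-plane model (hip/knee/ankle, 8 lumped muscles,
constant moment arms, rigid tendon). The baseline trial is solved
unconstrained; the feedback trial additionally constrains the
gastrocnemius activation to the measured EMG (delayed 40 ms, scaled by a
baseline-calibrated factor) within a ±2% band. Each frame is a strictly
convex box-constrained quadratic program solved exactly by an active-set
method.

**Knee contact force.** Axial (tibia-aligned) joint-reaction superposition,
`F_knee = interseg + Σ c_m F_m`, in body weights; early/late peaks are the
maxima over 15–35% and 65–85% stance; the impulse is the trapezoidal
integral over stance time.

**Statistics.** Paired baseline-vs-feedback comparisons gated by
Shapiro–Wilk normality (paired t vs Wilcoxon signed-rank), the two primary
outcomes (gastrocnemius EMG, late-stance peak) uncorrected, all exploratory
outcomes in one Benjamini–Hochberg family, and the a priori noncentral-t
power analysis (a 0.38 ± 0.39 BW effect at power 0.9, α = 0.05 → 13
participants).

## Worked example

```r
library(gaitretrain)

params <- cohort_params(n_participants = 5, steps_per_trial = 80, seed = 2026)
cohort <- generate_cohort(params)     # synthetic cohort with ground truth
report <- run_cohort(cohort)          # full pipeline + statistics
print(report)
```

```
<cohort_report> n=5 participants
  gastrocnemius EMG change (%)     mean  -17.214 +/- 15.753  p=0.07095
  late-stance peak (BW)            mean   -0.274 +/- 0.129  p=0.008884
  vasti EMG change (%)             mean  +20.219 +/- 18.444  p=0.07036 (adj 0.1055)
  early-stance peak (BW)           mean   +0.026 +/- 0.004  p=8.967e-05 (adj 0.000269)
  contact impulse (BW.s)           mean   -0.060 +/- 0.098  p=0.2441 (adj 0.2441)
```

Reading this: across the 5 synthetic participants the selected 50-step
windows show a mean 17% gastrocnemius EMG reduction with a compensatory 20%
vasti increase; the late-stance knee-contact-force peak drops by 0.27 body
weights (paired test p = 0.009) while the early-stance peak rises slightly;
3 of 5 participants reduce their contact-force impulse
(`report$summary`). Per-participant detail:

```r
print(report$participants[[1]])
#> <participant_result> P01: gastroc -6.5%, vasti +5.4%
#>   late peak -0.196 BW (-7.3%), early peak +0.026 BW, impulse +0.057 BW.s
```

Trial files round-trip through tab-delimited motion/storage (`.sto`/`.mot`
dialect) or CSV via `write_participant()` / `read_timeseries()` /
`load_trial()`, so synthetic and recorded data enter the pipeline
identically. A thin CLI wraps the same calls:

```sh
Rscript exec/gaitretrain cohort --n 5 --seed 2026 --out report_dir
```

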