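---
title: "Methods: gait indices, montage statistics and field dose-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait indices, montage statistics and field dose-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdose)
```

# The problem

Cerebellar transcranial direct current stimulation (ctDCS) is a candidate
adjunct therapy for post-stroke gait rehabilitation. Two questions drive the
analysis this package implements: do two different electrode montages change
overground gait differently, and is the change in gait predicted by the
electric-field dose each cerebellar lobule receives? Answering them requires
a chain of computations: detecting heel-strike and toe-off events from
instrumented-shoe pressure sensors, deriving spatiotemporal gait indices per
trial, reducing pre/post trials to bounded change scores, testing the
montage contrast non-parametrically, and regressing the change scores on
the per-lobule mean field strength. `gaitdose` implements that chain, plus
a synthetic cohort generator so every stage is testable without patient
data.

# Gait model and event detection

## The two-leg event model

A walk trial is modelled as two phase-shifted periodic event trains. Each
leg produces heel-strikes every `cycle_time` seconds; toe-off follows each
heel-strike after `stance_fraction * cycle_time`. The unaffected leg is
offset by `phase_offset` (default half a cycle). Independent
truncated-Gaussian jitter (truncated at 3 SD, so the event order is
preserved for realistic SDs) perturbs every event time. This is the
simplest timing structure that yields all seventeen indices; it does not
model kinematics, ground-reaction forces, turning, or within-trial slowing.

Defaults describe slow hemiplegic overground gait: a 1.25 s cycle at
0.8 m/s on a 10 m walkway, stance fraction 0.62 on the affected (paretic)
side and 0.68 on the unaffected side — paretic limbs bear weight for a
smaller share of the cycle while the sound limb compensates — and 0.02 s
timing jitter. These are generator conditions chosen once as clinically
plausible magnitudes, not fits to any data set.

## FSR synthesis and detection

Each shoe carries three force-sensitive resistors: greater toe, lateral
heel, medial heel. Synthesis places heel-channel contact from heel-strike
to 70% of stance and toe-channel contact from 15% of stance to toe-off, so
the earliest heel onset is the heel-strike and the latest offset across
channels is the toe-off. Detection thresholds each channel at a fraction
(default 0.2) of its dynamic range, merges supra-threshold runs separated
by less than the debounce window (default 50 ms) and discards runs shorter
than it. Both constants are exposed in the API: the hardware reference the
detection emulates does not pin them down, so they are package choices.
When the medial and lateral heel channels disagree, the earlier onset
defines heel-strike — a documented convention, made so the derived event is
the first floor contact.

On noise-free traces the detection error is bounded by one sample period
plus the onset ramp; the round-trip tests assert exactly that bound.

# The seventeen gait indices

Per leg, a gait cycle is heel-strike → toe-off → next heel-strike; stance
is the first interval, swing the second, so stance + swing equals the
cycle time identically. Per-trial values are means over retained cycles;
by default the first and last complete cycle of each leg are trimmed to
reduce acceleration/deceleration bias over a short walkway (the bias is
real; whether the original device trimmed is unknowable, so the flag is
exposed and defaults on).

* Stride time: ipsilateral heel-strike interval.
* Step time of leg L: from the preceding contralateral heel-strike to
  L's heel-strike (the attribution of a step to the leg that *ends* it is
  a convention; the alternative merely swaps the two columns).
* %Stance, %Swing: per-cycle stance/swing as a percentage of that cycle.
* %Single-support time of leg L: contralateral mean swing time as a
  percentage of L's mean cycle time.
* Cadence (steps/min): heel-strikes of both legs per unit time. It is
  measured as `60 * (n_HS - 1) / (last HS - first HS)`: the initiating
  strike of a pass opens the walk rather than counting as a step, which
  makes the measured cadence equal the nominal steps-per-minute of a
  periodic train exactly.
* Walking speed: walkway distance over walk duration.
* Step length = step time × walking speed; normalized step length divides
  by subject height.
* Gait stability ratio = cadence (steps/s) / speed (m/s): steps per metre.
  Cadence is stored in steps/min throughout and converted inside this one
  formula.
* Walk ratio = step length / cadence (steps/min).
* Symmetry index, computed on left/right percent stance:
  `SI = (X_L - X_R) * 100 / (0.5 * (X_L + X_R))`; zero at symmetry,
  antisymmetric under leg swap.

# Change scores and montage comparison

The pre→post change of each index is the percent normalized change
`(POST - PRE) * 100 / (POST + PRE)`, bounded in (−100, 100) for positive
inputs, antisymmetric and scale-invariant. Cells with `PRE + POST = 0` are
flagged missing rather than propagated.

Each gait parameter's change distributions under the two montages are
compared with a two-sided Wilcoxon rank-sum test. Mid-ranks handle ties.
With combined n ≤ 20 and no ties the two-sided p-value is exact:
`min(1, 2·min(P(W ≤ w), P(W ≥ w)))` with the null distribution obtained by
full enumeration of all `choose(n, n_a)` rank assignments. Larger or tied
samples use a normal approximation with tie and continuity corrections,
and the method used is recorded in the result. The exact path is the
default regime for small crossover cohorts and makes small-sample p-values
bit-reproducible. No multiplicity correction is applied across the
seventeen parameters by default, matching common practice in small
feasibility analyses; a Benjamini–Hochberg option exists behind a flag.

# PLS regression of change on lobular field strength

The dose-response model is regression-mode partial least squares (PLS2) of
the change table (observations = subject × montage rows, responses = the
17 parameters) on the mean lobular field strengths (predictors = 30 lobule
labels by default). Data are column-centred and *not* scaled to unit
variance: the predictors share units (V/m) and the responses share units
(percent change), so covariance-scale saliences are meaningful; a
standardizing variant would change the loadings and is intentionally not
the default.

Per component: the predictor weight vector is the dominant left singular
vector of the current cross-covariance `t(X) Y`; the score is the
projection of the deflated `X` onto it; X- and Y-loadings are regressions
of each block on the score; both blocks are deflated by the score. Scores
are mutually orthogonal, cumulative percent variance explained in `Y` is
non-decreasing, and at full rank it equals `100·R²` — all of which are
property-tested. The SVD's sign ambiguity is fixed by making the
largest-magnitude weight element positive, so loadings are reproducible
across runs. A rank-deficient cross-covariance truncates the model with a
warning rather than fabricating components. The default component count is
10, capped at `min(rows − 1, predictors)`. No cross-validation or
bootstrap inference is attempted: the model is used as a descriptive
correlation technique, and a resampling layer can be built on top of
`fit_pls()` if needed.

`R²` is pooled over all response columns: `1 − SS_res / SS_tot` about the
column means. Predictor importance for recovery checks is ranked by the
Euclidean norm of each predictor's row of the coefficient matrix — the
total estimated linear effect across responses — which is less sensitive
to how a sparse signal is distributed over components than any single
component's loading.

# The synthetic cohort

The generator emulates: cohort heights uniform on 1.55–1.85 m with a 40%
left-hemiplegic share (deterministic rounding); the gait model above;
two-montage lobular field profiles; and a plantable linear map from
centred field strength to gait change for regression ground truth.

Field profiles are qualitative constants, user-overridable: the dentate
montage at 0.25 V/m on the dentate nuclei and 0.12 V/m across the
anterior/posterior lobes; the leg montage at 0.10 V/m on lobules VIIb–IX
and the dentate nuclei and 0.04 V/m elsewhere. Only inequalities for these
ranges are published, so the constants are package choices honouring them.
Between-subject variability is unpublished; it defaults to a 25%
coefficient of variation, chosen once as a realistic inter-individual
spread for head-model-derived fields. The 30-label lobule set is a
SUIT-style parcellation re-keyed contra-/ipsi-lesional plus the two
dentate nuclei.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: sensor drift and baseline wander, partial
foot contact and shuffling gait, missed or spurious footfalls, fatigue
trends within a pass, and any true biomechanical coupling between field
dose and gait change (the planted map is linear by construction).

# Numerical choices and degenerate inputs

* All times are seconds, 0-based from trial start; fields are V/m.
* Grid-aligned contact edges carry a 1e-9 s guard against floating-point
  exclusion of the boundary sample.
* A leg without complete cycles yields missing index fields plus a
  `missing_side` attribute, never a crash; fatal stream defects
  (non-monotone time, duplicate timestamps) abort index computation.
* Zero-variance responses, single-row centering, empty rank-sum groups and
  mismatched predictor labels raise classed errors.
* Seeds: every generator takes an explicit seed; the pipeline derives
  per-stage seeds deterministically from one master seed, and identical
  seeds give bit-identical outputs.

The verification suite runs at deliberately small problem sizes chosen to
exercise every property well within a desktop minute: cohorts of 4–10
subjects, 100-replicate recovery experiments at 20 observations × 30
predictors × 17 responses, 200-instance exact-test cross-checks at
combined n ≤ 10, and 20 random PLS/least-squares equivalence problems.

# Known limitations

* The event model is strictly periodic plus jitter; real hemiplegic gait
  shows serially correlated cycle-to-cycle variability.
* The exact rank-sum p-value can differ in the third decimal from
  asymptotic implementations on the same data; the method field makes the
  regime explicit.
* With far more predictors than observations the PLS coefficient rows of
  correlated lobules share credit; ranking by coefficient norm mitigates
  but does not remove this.
* Clinical MCID flagging uses fixed published thresholds (0.10 m/s walk
  speed gain, 8 s timed-up-and-go reduction, 12.5 Berg Balance points) and
  performs no inference.

# A compact worked run

```{r demo, eval = FALSE}
cfg <- analysis_config(n_subjects = 10, seed = 1,
                       out_dir = file.path(tempdir(), "demo"))
report <- run_full_analysis(cfg)
print(report)
```

The report collects the per-trial index table, the change table, the
rank-sum table with significance flags, the fitted PLS model (R², variance
explained, loadings), MCID flags and run metadata; every section is also
written as a CSV/JSON artifact under the output directory.
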