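---
title: "Methods: patient-specific hypotension forecasting on synthetic vital signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-specific hypotension forecasting on synthetic vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute hypotensive episodes (AHE) — sudden, sustained drops in mean arterial
pressure (MAP) — are associated with organ failure and death in intensive
care, and advance warning gives clinicians time to look for the underlying
process.  The conventional definition (30 minutes in which 90% of MAP
readings are below 60 mmHg) is absolute: it misses clinically meaningful
collapses in patients with high baselines and conflates them with patients
hovering just under the cutoff.  `ahepredict` implements a *relative*
definition and the machinery to learn to forecast it from per-minute
monitor data (MAP, heart rate, SpO2), evaluated entirely on a synthetic
cohort generator so that every claim in the test suite is checkable against
planted ground truth.

## The episode definition and annotator

Two trailing (causal) moving averages of MAP are evaluated at the same
minute: a short 5-minute average tracking the current state and a long
60-minute average serving as the patient's own baseline.  An onset is the
first minute `t` with

`MA5(t) <= (1 - 0.20) * MA60(t)`,

ties included ("20% or greater").  Validity requires every MAP sample in
the 10 minutes after detection to be observed and above 20 mmHg — a guard
against sensor drop-offs and non-physiological values.  The episode ends at
the first subsequent minute where the gap has re-closed; episodes whose gap
re-closes in under 10 minutes are discarded outright, so 10 minutes is the
definitional minimum duration (`minimum_event_duration()`).

Choices the definition's verbal form leaves open, fixed here:

* **Alignment.**  Both averages are trailing and evaluated at the same
  index.  Trailing windows are the only causal choice (usable online), and
  comparing the two smoothed curves at the same time matches how the
  definition is drawn.
* **Missing samples.**  Inside an averaging window they are excluded from
  the mean (an average of the available values); an index whose window is
  entirely missing, or with fewer than `width` prior samples, has no
  average and can be neither onset nor end.  Inside the 10-minute validity
  horizon a missing sample *rejects* the candidate — that is the point of
  the horizon.
* **End rule.**  The same MA pair used for detection is re-tested; an index
  where either average is undefined cannot close an episode.
* **Indexing.**  Minute indices are 0-based; episode intervals are
  half-open `[onset, end)`; an episode still open at the end of a record
  has `end = NA`.

Two structural consequences worth knowing: the first 59 minutes of a record
can contain no onset (the long average is undefined), and because the long
average *adapts* to a depressed plateau, a sustained drop of depth just
past the threshold typically closes within 15–25 minutes even if MAP stays
low — the definition flags the *transition*, not the low state itself.

The conventional fixed-threshold rule is provided for comparison
(`annotate_conventional()`): qualifying 30-minute windows (≥ 90% of
non-missing readings < 60 mmHg) are merged into maximal intervals.

## Window extraction

For a model that predicts with lead time `gap` from `obs` minutes of data,
a positive sample is the window `[onset - gap - obs, onset - gap)` — it
ends exactly `gap` minutes before the onset.  One window is taken per
episode; when a prior episode exists, the window must start at least two
hours after that episode's end.  Negative windows are packed greedily left
to right with stride `obs` (advancing one minute past blocked positions),
subject to no annotated episode intersecting `[start - 120, start + obs +
120)`.  The two-hour guards constrain *episodes* only: a window near a
record edge qualifies if the in-record part of its margin is episode-free
(`strict_margin = TRUE` demands the full margin).  Negatives are therefore
independent of `gap` and shared across the gap axis.  Windows with more
than 10% erroneous samples — missing or outside physiological ranges,
counted jointly over all three channels — are excluded (strictly greater
than 10%: a 60 × 3 window with exactly 18 erroneous samples survives).

## Preprocessing

All preprocessing is windowed: no value outside the extracted window is
ever used, so no information can leak across window boundaries or from the
future.  Steps, in order: (1) samples outside physiological ranges are set
to missing; (2) missing values are backfilled (next observed value
propagated backwards) and any trailing run forward-filled; (3) features are
scaled to [0, 1] with *static* ranges — MAP and HR 40–160, SpO2 60–100 —
and clipped (clipping is only reachable when the configurable physiological
ranges are set wider than the normalisation ranges; by default they
coincide, which is also why those are the default physiological bounds: no
other ranges are pinned down numerically).  Sources sampled faster than
once a minute are first reduced to per-minute means
(`resample_to_per_minute()`).

The decay model bypasses imputation: it receives the unfilled normalised
values, the observation mask, and per-channel time-since-last-observation
`delta` (`delta[1] = 0`; 1 after an observed step; accumulating +1 across
unobserved steps).  Unobserved positions carry the per-channel *training
set* mean — the decay target — substituted at fit time.

## Models

**Stacked LSTM.**  Two LSTM layers of 60 units on the `[obs × 3]` window,
dropout 0.4 between the final recurrent output and a one-unit sigmoid
head, L2 penalty 1e-3 on *all* parameters (weights and biases, literally),
binary cross-entropy, Adam under cosine annealing with warm restarts
(maximum rate 1e-3, minimum 1e-5, 10-epoch period — the schedule's shape
parameters are not pinned by the design and are exposed in `lstm_spec()`).
Dropout is applied only at that single position; recurrent-internal
dropout is not used.

**Decay-gated recurrent unit.**  A single 100-unit layer for unfilled
inputs.  Per channel, an input decay `exp(-max(0, w δ + b))` interpolates
the last observed value toward the channel mean as the time since
observation grows; a second trainable decay multiplies the hidden state.
The observation mask enters the gates as an additional input.  With zero
missingness and zeroed decay/mask parameters the cell reduces exactly to a
standard gated recurrent unit — a unit test asserts the hidden trajectories
agree to 1e-10 against an independently coded reference.  Training uses a
fixed learning rate of 1e-4, dropout 0.3, and otherwise the LSTM's
hyperparameters.

Both networks are implemented in vectorised base R: sequences are at most
60 steps and batches small, so BLAS-backed matrix algebra is fast enough
without compiled code, and the implementation is short enough to verify
directly — every analytic gradient is checked against central finite
differences (relative error below 1e-5 at epsilon 1e-5) in the test suite.
Epoch count (default 100), batch size (64) and early selection (parameters
from the epoch with the best validation loss) are package defaults, all
exposed.  Fits are pure functions of (data, spec, seed): initialisation,
dropout masks and shuffling all derive from the seed.

**Baselines.**  Logistic regression on the window-mean MAP in raw mmHg
(raw units keep the coefficient interpretable: it comes out negative when
low MAP precedes episodes), and an RBF-kernel SVM (cost 1, features
standardised on training statistics — kernel and cost are not pinned by the
design; AUROC uses its decision values) on the window means of all three
channels.

## Experiment orchestration

Records are split into train/validation/test *by patient*, never by
window; a leakage assertion aborts any split that shares a patient.
Negative windows in train and validation are randomly down-sampled to the
positive count (a 2:1 option reproduces the 66%/33% composition also
explored); the test set always keeps every negative so that reported
metrics reflect deployment imbalance.  The default experiment plan crosses
six observation lengths with six gap lengths (10–60 minutes by 10), one
model per cell per family: 36 configurations per family, 72 deep models
over both recurrent families (`grid_plan()`, `run_grid()`).

Transfer to a new cohort (`transfer_finetune()`) copies the source
weights into an identical architecture and fine-tunes on class-balanced
tuning sets of 10–50 windows at a reduced fixed rate of 1e-4, selecting on
target-domain validation loss.  All layers are fine-tuned (the plainest
reading of fine-tuning); the source model is never mutated, and a
30-epoch default budget covers the unstated fine-tuning length.

## Evaluation

AUROC is the Mann–Whitney statistic (midranks; ties count one half) and is
tested against a brute-force all-pairs count and against `pROC`.
Uncertainty comes from a percentile bootstrap over windows (1000 resamples
by default; one-class resamples are redrawn); because windows within a
patient are dependent, a cluster bootstrap resampling whole patients is
available — the plain variant is the default as the simpler, more common
choice.  Sensitivity, specificity and PPV are reported at a threshold
(default 0.5, sweepable); PPV with no positive predictions is *undefined*,
not zero.  The per-patient "classification rate" is operationalised as the
fraction of a patient's test windows correctly classified at the operating
threshold, with summary counts at cutoffs 0.85 and 0.90.

## The synthetic cohort generator

`generate_cohort()` emulates what the analysis assumes about monitor
extracts, with defaults chosen once as plausible ICU magnitudes:

| parameter | default | why |
|---|---|---|
| record length | 480–1440 min | 8 h to a day of monitoring |
| baseline MAP / HR / SpO2 | 70–110 mmHg / 60–100 bpm / 94–99% | inter-patient variability |
| within-patient noise | AR(1), φ = 0.9; SD 2 / 3 / 0.8 | slow autocorrelated physiology, bounded so null records never open a 20% MA gap |
| episode prevalence | 0.35 of records | yields a few-percent positive-window fraction after extraction |
| episode depth / duration | 25% / 20–60 min | just past the 20% threshold, as the definition targets |
| precursor | 60 min lead; HR +10 bpm, MAP −5 mmHg linear ramps | a learnable, lead-time-decaying signal |
| missingness | 2% per sample per channel, MCAR | simplest mechanism consistent with the design |
| artifacts | 0.2% isolated out-of-range spikes | exercises range filtering and window rejection |

The planted drop is multiplicative on the local signal with a sigmoid
descent centred on the onset sample (the plateau is reached by the second
minute).  The descent speed is deliberate: the trailing 5-minute average
registers a step-like drop about 4–5 minutes after onset, so a descent
whose midpoint sits 2–3 minutes in would push detection past the ±5-minute
round-trip tolerance by simple trailing-window arithmetic.  Modified MAP
samples are floored at 25 mmHg so planted episodes respect the validity
floor.  Everything is deterministic given (config, seed).

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: hemodynamic dynamics (no cardiovascular ODEs),
bursty or informative missingness (real drop-offs cluster; MCAR is
optimistic for the decay model and pessimistic for the validity rule),
treatment responses, beat-level waveforms, and any real covariance between
channels beyond the planted precursor.  Synthetic results validate the
*pipeline*, not clinical performance.

A consequence of planting episodes only marginally past the threshold: at
the default noise (MAP SD 2, autocorrelated), about 7% of planted episodes
have their MA gap re-close within 10 minutes — an autocorrelated dip plus
long-average adaptation — and are correctly discarded by the minimum-
duration rule.  The round-trip validation studies therefore use MAP noise
SD 1 ("low noise"), where recovery is essentially complete and event-free
cohorts yield zero false episodes.

## Reproduction studies and problem sizes

The studies run by the test suite and by `scripts/acceptance.R` use sizes
chosen to be statistically informative while keeping a full run in minutes
on one core:

* `study_event_recovery()`: 100 single-episode records + 100 null records.
* Annotator–oracle agreement: 100 records (lengths 300–800) against a
  naive re-implementation that recomputes both averages from scratch at
  every index.
* Windowing guard checks: 100 three-patient cohorts, exhaustive over every
  emitted window at two observation lengths.
* `study_learnability()`: 300 patients, strong precursor (HR +15 bpm,
  MAP −8 mmHg over a 60-minute lead), LSTM at 40 epochs, 3 seeds per gap.
  Windows at a 10-minute gap overlap 50 minutes of precursor; at a
  60-minute gap they end where the precursor begins, so discrimination
  should fall to near chance — the qualitative lead-time trend.
* `study_null_calibration()`: 5 shuffled-label refits at 12 epochs; test
  AUROC should be chance, anything else indicates leakage.
* `study_bootstrap_coverage()`: 200 binormal score sets with true AUROC
  0.8 (negatives N(0,1), positives N(√2·Φ⁻¹(0.8), 1)), nominal 95%
  intervals; percentile-bootstrap coverage on AUROC is typically a few
  points below nominal but should stay above the high-80s.

```{r, eval = FALSE}
library(ahepredict)
res <- study_learnability(seed = 1)
tapply(res$auroc, res$gap, mean)
```

## Known limitations

* The recurrent training loop is single-threaded R; it is comfortable at
  the study sizes here but not meant for cohorts of tens of thousands of
  windows.
* The relative definition's adaptation means long depressed plateaus
  produce one short annotated episode near the transition; consumers
  wanting "time in hypotension" need the conventional definition instead.
* MCAR missingness understates the advantage a decay-gated model has on
  real, informatively-missing data.
* Percentile bootstrap over windows ignores within-patient dependence; the
  cluster variant is provided but widens intervals on small cohorts.
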