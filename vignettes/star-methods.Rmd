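---
title: "Stochastic targeted glycaemic control in silico: models, controller and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic targeted glycaemic control in silico: models, controller and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stargc)
```

## The problem

Critically ill patients frequently develop stress-induced hyperglycaemia.
Controlling blood glucose (BG) with insulin is hard because both the
patient's response to insulin and its evolution over time vary strongly —
between patients and, hour to hour, within a patient. `stargc` implements an
in-silico version of the STAR (Stochastic TARgeted) framework, which treats
glycaemic control as a risk management problem: identify the patient's
current insulin sensitivity (SI) from the data at the bedside, forecast the
*distribution* of SI over the next one to six hours with a stochastic model,
translate that distribution into a 5th–95th percentile band of likely BG
outcomes for each candidate insulin/nutrition dose, and pick the dose whose
predicted risk of hypoglycaemia stays at the pre-set 5% level. The package's
purpose is to quantify, by simulation on virtual patients, what happens to
safety (hypoglycaemia), efficacy (time in the 4.4–8.0 mmol/L band) and
nurse workload (BG measurements per day) when the treatment interval is
extended from the classical 1–3 h up to 4, 5 or 6 h, under two controller
variants: *Standard*, and *Upper-Limit-Controlled* (ULC), which additionally
requires the predicted 95th-percentile BG to stay below 8.5 mmol/L.

## The physiological model

Virtual patients and BG predictions share one deterministic
glucose–insulin–nutrition model of the ICING family. State variables are
blood glucose `G` (mmol/L), plasma and interstitial insulin `I`, `Q` (mU/L)
and two gut compartments `P1`, `P2` (mmol). Glucose is cleared by a
non-insulin pathway (`p_G`) and by a saturable insulin-mediated pathway
`SI * G * Q / (1 + alpha_G * Q)`; endogenous production (`EGP`) minus
central-nervous-system uptake (`CNS`) and gut absorption feed glucose in.
Insulin is cleared renally and hepatically (saturable) and diffuses between
plasma and interstitium; enteral feed passes through the two-compartment gut
with a saturable emptying ceiling. The equations and the shipped default
parameter set (`icing_params()`, file `extdata/icing_default.txt`, set name
`icing-default-1`) are a literature-standard reconstruction for critically
ill adults; every value is overridable. Two modelling assumptions deserve
emphasis:

* **Endogenous insulin secretion defaults to zero.** Secretion is strongly
  suppressed in the critically ill, and a zero default makes insulin
  exposure entirely input-driven: with no insulin given and no insulin
  history, `Q(t)` is exactly zero and hours without insulin are declared
  non-identifiable rather than fitted against noise. A constant secretion
  parameter (`u_en`) exists for sensitivity analyses.
* **Insulin is dosed as hourly boluses.** A rate of `r` U/h over an interval
  is administered as a bolus of `r` U at the top of each hour, the simulated
  standard of care. Continuous infusion is also supported by the simulator.

Integration uses a fixed-step classical Runge–Kutta scheme (0.5 min step,
compiled) with every event — hour-boundary SI switches, boluses, feed
changes — snapped exactly onto the step grid, so piecewise-constant
semantics are exact by construction rather than approximated by an event
finder. The dynamics are smooth and non-stiff at physiological rates, and
the trial engine needs on the order of a million short integrations per
study, which is why a fixed-step compiled scheme was preferred over an
adaptive stiff solver. Accuracy is verified two ways in the test suite:
against an independent adaptive solver (`deSolve::lsoda` at tolerance
1e-10), agreeing to ~1e-7 mmol/L over six hours, and by step halving, which
moves end-of-interval BG by less than 1e-6 mmol/L.

## Identifying insulin sensitivity

`identify_si()` fits one SI value per hour by sequential one-dimensional
least squares: starting from the episode's initial state, the SI of each
hour minimises the squared mismatch between model-predicted BG and the
measured BG linearly interpolated in time, evaluated at the hour end and at
any measurement inside the hour. Evaluating residuals at those points (and
not on a dense grid against the piecewise-linear interpolant) means
noise-free model-generated data are recovered exactly up to optimiser
tolerance — the round-trip property the test suite enforces at 1% for
constant traces and 5% per hour for arbitrary traces. The search runs on
log-SI over [1e-6, 1e-2] L/(mU·min), a generous physiological envelope.
Flags are the only exclusion mechanism: hours whose interstitial insulin
never rises above 0.5 mU/L are `nonidentifiable` (the SI multiplies a term
that is numerically zero), and hours where even SI = 0 over-predicts the BG
drop are `clamped` to zero. Flagged hours never enter stochastic-model
training.

## The stochastic SI transition model

Future SI given current SI is modelled as a first-order Markov process. From
all identifiable hours, pairs (SI_n, SI_{n+i}) are formed for horizons
i = 1..6 — always within one episode, never across. The joint density is a
kernel estimate: an average of per-pair product Gaussians centred at the
data points, with per-point bandwidths *weighted by local data density* —
the bandwidth of a centre is the distance to its k-th nearest neighbour
(k = n/20, floor 10), separately per axis, with a floor of 1e-3 log units so
degenerate (tied) data remain well-posed. SI is log-transformed before
kernel placement: on the log axis the data are approximately Gaussian and
positivity of SI is automatic, so the per-kernel positive-domain
normalisers carried in the model structure equal one exactly in the working
coordinate (they are retained explicitly so that the stored object matches
the estimator's general truncated form, and the test suite checks the
implementation against a direct double-loop evaluation of the kernel sum at
1e-12). Conditional percentiles invert the gridded conditional CDF (300
log-spaced points spanning [min/3, 3·max] of the training SI) with local
root refinement inside the bracketing cell, which removes the grid-spacing
limit on inversion accuracy; percentiles agree with a 10^6-draw Monte-Carlo
sample of the conditional to better than 0.5%.

Fitting across a cohort uses fivefold cross-validation **by patient**:
`fit_si_transitions()` partitions patients, fits all six horizons on each
training set, and `models_for_patient()` hands every virtual patient the
models of the fold in which it is held out. Model archives are JSON with
17-significant-digit numerics, so a reload is bit-exact.

## The dosing controller

At each decision, candidate treatments live on configurable grids (default
insulin 0.5 U/h steps up to 6 U/h, at most +2 U/h over the previous dose;
nutrition 5 %GF steps between 100 %GF and
`max(30, previous − 30)` %GF). For an interval of L hours the controller
queries the 5th and 95th percentile of SI at each horizon 1..L conditional
on current SI, and simulates the candidate under both hour-wise percentile
paths; since BG is monotone non-increasing in SI, the low-SI path bounds BG
from above and vice versa. Admissibility encodes the risk rules: the
predicted 5th-percentile BG must stay at or above 4.4 mmol/L at *every*
hour of the interval (enforcing the band floor only at interval end would
tolerate predicted mid-interval hypoglycaemia); under ULC the predicted
95th-percentile BG at interval end must additionally stay below 8.5 mmol/L.

Several points in the protocol are stated qualitatively in the clinical
literature and had to be made precise here; the choices are isolated and
documented:

* **Objective.** "Best overlap with the target band" is implemented
  lexicographically: among admissible candidates, nutrition is reduced only
  if insulin alone is not sufficient (the highest admissible feed level is
  taken first), and at that level the candidate maximises the fraction of
  the predicted interval-end BG band lying inside 4.4–8.0 mmol/L, with the
  distance from band as tie-breaker, then the lower insulin dose. A
  collapsed (zero-width) band counts as fully in band when inside it. This
  reproduces the protocol's characteristic behaviour: feed stays near goal
  under Standard, and the ULC ceiling — not the objective — pulls feed down
  when uncertainty grows.
* **Interval availability.** The virtual-trial convention takes the longest
  interval offered. A longer-than-1 h interval is offered only if an
  admissible candidate keeps the predicted 95th percentile within
  `band_hi + 2` mmol/L (Standard; the slack is configurable) or under the
  ULC ceiling (no slack). The bedside gating rule is not printed anywhere,
  so it is kept behind this single predicate.
* **ULC infeasibility.** On entry hyperglycaemia no 1 h treatment can meet
  the 8.5 mmol/L ceiling; the controller then shortens to 1 h and doses by
  the Standard rule (flagged `relaxed`) until the ceiling becomes
  attainable. Without this the ULC arm would dead-end at episode start.
* **Safety fallback.** If no candidate is admissible anywhere (imminent
  predicted hypoglycaemia), the controller returns a flagged 1 h fallback:
  insulin 0 or unchanged — whichever predicts the higher 5th-percentile
  BG — with feed raised toward 100 %GF.

The central calibration property ties everything together: when the true
1 h SI transition is drawn from the same conditional the controller uses,
the realized BG falls below the predicted 5th-percentile bound in ~5% of
intervals (the acceptance suite demands 5% ± 1% absolute over 10,000
intervals). This holds by construction — P(BG below the 95th-SI-path
prediction) = P(SI above its 95th percentile) — given the monotone insulin
effect, and it is what "risk-based dosing" means operationally.

## Virtual patients and trials

A virtual patient is an hourly true-SI trace (its digital-twin identity)
plus starting BG, episode length and goal feed. `run_episode()` closes the
loop under ideal protocol compliance: measure BG (noise-free model value; a
noise hook exists but defaults off), re-identify SI from what the
controller has seen — the controller maintains its own model state and
fits a constant SI over the elapsed interval, equivalent to the hourly
identifier on noise-free data — select a treatment, and advance the *true*
state with the true SI trace. The first decision, before any data, uses the
median of the transition model's training distribution as the SI prior.
Episodes end when the cumulative interval reaches the episode length; the
last interval may overrun, so arms differ slightly in control hours, and
the accounting identities (intervals sum to GC hours, rows to measurement
counts) are asserted in the tests.

The synthetic cohort generator supplies the study conditions. Episode
lengths are log-normal with a 24 h median, truncated above 10 h; at this
desk scale a 100-patient default cohort simulates under all eight study
arms in minutes on one core while exercising every code path; starting BG
is log-normal around 9.2 mmol/L truncated above 7.0 mmol/L (the episode
inclusion rule is strict on both boundaries); goal feeds are normal around
65 mmol glucose/h, roughly 1.5 g/kg/day of carbohydrate for an 80 kg adult.
Log SI follows a per-patient AR(1) process (coefficient 0.97, innovation SD
0.15 per hour) around a patient level drawn with 0.3 SD between patients,
centred so the cohort's operating point — median BG ≈ 6.5 mmol/L at
~3 U/h and full feed — matches the clinical operating point the protocol
reports. On top of the AR(1) core, rare abrupt sensitivity shifts
(probability 0.007/h, log-magnitude SD 0.7) emulate the sudden SI rises
that drive hypoglycaemia when they fall inside a long unobserved interval;
with these defaults 1–3 of 100 patients dip below 2.2 mmol/L under the 6 h
Standard controller, the design point for the safety analysis, while the
hour-to-hour log-SI change SD stays within 10% of the nominal innovation
SD.

What the generator does *not* emulate: measurement error and sensor drift,
nurse mistiming of measurements, dextrose rescue boluses, circadian or
drug-driven SI structure, and the demographic composition of a real ICU
cohort. Passing tests therefore demonstrate internal consistency of the
method and qualitative reproduction of the workload-versus-safety
trade-off, not clinical performance: the synthetic hour-to-hour SI
variability is deliberately on the high side, which makes the simulated
controller more conservative (lower time-in-band, and a ULC arm that
mostly keeps short intervals) than the clinical reports.

## Outcome metrics

`compute_metrics()` reports the standard comparison set on hourly-resampled
BG: pooled %BG in 4.4–8.0 and 4.4–7.0 mmol/L, above 8.0, below 4.4 and
below 2.2 mmol/L; per-patient median [IQR] of BG, insulin and nutrition
(medians of per-episode medians); workload as 24 × measurements / GC hours
(rounded for display, raw value retained); and per-patient counts of ≥50%
time-in-band and of severe hypoglycaemia (minimum hourly BG < 2.2 mmol/L).
Band edges are inclusive — "in 4.4–8.0" means 4.4 ≤ BG ≤ 8.0 with "< 4.4"
and "< 2.2" strict — so the three-way partition {<4.4, in-band, >8.0}
closes to exactly 100% before rounding; the source convention is not
printed, and edges-in is the choice that keeps the partition exact.
`tradeoff_summary()` and `plot_tradeoff()` arrange the risk-reward axes
across variants.

## Numerical choices and degenerate inputs

* Integration step 0.5 min; output grid 5 min; all event times snapped to
  the step grid. Compartments are clamped at zero after each step (the
  model cannot go negative except by rounding). Non-finite states abort
  with the failure time in the error.
* Kernel bandwidth floor 1e-3 log units; kernels with relative conditional
  weight below 1e-14 are pruned from CDF evaluation; percentile inversion
  refines grid interpolation by root-finding inside one grid cell.
* Identification optimises log-SI to tolerance 1e-9 and compares the
  boundary value SI = 0 explicitly before clamping.
* Ties in treatment selection resolve by documented lexicographic order,
  ending in grid order, so selection is fully deterministic; the virtual
  trial loop contains no randomness unless measurement noise is enabled,
  and cohort generation flows from a single seed.

## Known limitations

The ICING parameter set is a reconstruction, not fitted to any cohort
shipped here; absolute BG levels carry that uncertainty even though the
identification/simulation round trip is exact by construction. The
transition model is first-order Markov in SI and blind to therapy history.
The availability predicate for long intervals is a modelling choice pinned
behind one function. Clinical-scale quantitative agreement (e.g. exact
time-in-band percentages) is out of reach of a synthetic cohort; the
package's quantitative claims are the internal ones its acceptance suite
computes — kernel normalisation, controller calibration at the 5% risk
level, constraint audits, and the monotone workload/hyperglycaemia trends.
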