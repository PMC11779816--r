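---
title: "Circadian phenotyping of home-cage activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian phenotyping of home-cage activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmscreen)
library(dplyr)
```

## What the package measures

`rhythmscreen` analyses minute-binned home-cage locomotor activity from
capacitive-sensor cages. The activity measure is an animal locomotion
index (ALI): the percentage of floor electrodes activated within a time
bin, from 0 (no movement) to 100 (all electrodes at once). A circadian
screen records this signal continuously for weeks while the lighting
cycle is manipulated: a baseline 12:12 light–dark (LD) cycle, an abrupt
6-h phase advance ("jet lag"), constant darkness (DD), re-entrainment to
LD, a 2-h light pulse at ZT14–16 followed by DD, and constant light
(LL). From each condition the pipeline extracts the standard descriptors
of circadian organisation:

* **period** and **rhythm robustness** from the chi-square periodogram;
* **inter-daily stability (IS)**, **intra-daily variability (IV)** and
  **relative amplitude (RA, via M10/L5)** — the nonparametric
  rest–activity disruption measures;
* **activity-bout length distributions**, **light-phase activity
  fraction** and **total daily activity**;
* **activity onsets**, and from them the **light-pulse phase shift**
  (Aschoff type II) and the **days to re-entrain** after the jet-lag
  advance.

A companion simulator generates whole cohorts with known ground truth
over the same protocol, so every estimator can be validated end to end.

## The chi-square periodogram

For a candidate period of $P$ bins, the first $K = \lfloor N/P \rfloor$
complete cycles ($N' = KP$ points) are folded into a $K \times P$ array
with column means $M_h$ and grand mean $M$:

$$Q_P \;=\; \frac{N' \, K \sum_{h=1}^{P} (M_h - M)^2}{\sum_{i=1}^{N'} (x_i - M)^2}.$$

Under a white-noise null $Q_P \sim \chi^2_{P-1}$ approximately, giving
the per-candidate significance line $\chi^2_{1-\alpha}(P-1)$; a
noiseless periodic signal reaches the ceiling $Q_P = N'$ at its true
period. Missing bins are excluded from every mean and sum with matching
counts, so welfare-check gaps neither add nor remove variance.

Defaults follow common actogram-software practice: candidate periods
from 16 h to 32 h in 1-bin steps on 6-min re-binned data, i.e. 0.1-h
resolution — fine enough to resolve the ~0.1-h differences that matter
between entrained (24 h), free-running dark (≈23.5 h) and free-running
light (≈25 h) periods. The reported peak maximises $Q_P$ minus the
significance line, which removes the slow upward drift of both $Q_P$
and its critical value with $P$.

**Peak significance is Bonferroni-corrected.** The curve stores the
nominal per-candidate line for plotting, but the rhythmic/arrhythmic
call at the peak compares against $\chi^2_{1-\alpha/m}(P-1)$ with $m$
the number of candidates (161 by default). A per-candidate 5% line
applied to the maximum of 161 correlated statistics over-calls
rhythmicity in genuinely arrhythmic data; the corrected call keeps the
family-wise false-positive rate at $\alpha$. Robust rhythms clear the
corrected line by an order of magnitude, so the correction costs no
sensitivity in practice.

## Nonparametric disruption metrics

With $p$ bins per day (hourly by default, the convention in the
actigraphy literature), per-bin-of-day means $\bar x_h$ and grand mean
$\bar x$ over $N$ bins:

$$IS = \frac{N \sum_h (\bar x_h - \bar x)^2}{p \sum_i (x_i - \bar x)^2},
\qquad
IV = \frac{N \sum_{i=2}^{N} (x_i - x_{i-1})^2}{(N-1) \sum_i (x_i - \bar x)^2}.$$

IS is 1 when every day repeats exactly and has expectation ≈ $1/D$ for
$D$ days of uncorrelated noise; IV is ≈2 for white noise and small for
consolidated rhythms. Both are invariant to affine rescaling of the
activity, so they are comparable across animals with different overall
activity. M10 and L5 are the extreme circular 10-h and 5-h window means
of the daily profile and $RA = (M10 - L5)/(M10 + L5)$.

IS, IV and RA are computed on the raw (unsmoothed) re-binned series.
The 30-min running average exists to bridge welfare-check gaps and to
draw actograms and onsets; smoothing before computing IV would
mechanically deflate it.

Undefined values — RA of an all-zero profile, IS/IV of a zero-variance
series, light-phase fraction under DD — propagate as explicit `NA`
markers (empty fields in CSV), never as zeros.

**Bout definition.** The study literature plots bout distributions
without printing a definition, so the package makes its own explicit:
a bout is a maximal run of minutes with ALI above a threshold
$\theta = 0$, with interruptions of at most $g = 0$ minutes bridged,
tallied into eight length classes (1–7 min and 8+). Both parameters are
arguments and are echoed into the provenance block of every report.

## Onsets, phase shifts and re-entrainment

Onsets use a step-template contrast: for each day the onset is the time
$t$ maximising the mean activity in $[t, t+6\,\mathrm{h})$ minus the
mean in $[t-6\,\mathrm{h}, t)$, scanned at bin resolution with windows
reaching into neighbouring days; ties go to the earliest candidate. The
score is translation-equivariant and scales linearly with activity, so
detected times are invariant under positive rescaling; on smoothed
square-gated simulations the detected onset sits within ±5 min of the
true gate onset. A zero contrast flags an unreliable (e.g. constant)
day.

**Sign convention: positive shift = phase delay.** The light-pulse
shift is the circular difference `onset(day +4) − onset(day −1)` mapped
to (−12, 12] h, so an early-night pulse that moves onsets later yields
a positive number. Many phase-response conventions use the opposite
sign; this one matches the language of delay used for early-night
pulses.

Because the animal free-runs in DD after the pulse, the Day −1 vs
Day +4 comparison mixes the pulse-induced shift with four-plus days of
free-run drift (≈ −0.5 h/day at a 23.5-h period). The package therefore
also fits a line through the post-pulse onsets (days +2 to +9,
unwrapped on the 24-h circle) and extrapolates it back to the pulse
day: the intercept minus the pre-pulse onset estimates the shift free
of drift, and the slope estimates the free-running drift itself. The
single-day comparison stays available (and is the field's conventional
report); the regression value is the one to compare against a known
injected shift, and recovers it to within ≈0.07 h on noiseless
simulations (the small residual is the phase-hours → wall-hours
conversion through the non-24-h period).

Re-entrainment is reached on the first day $d \ge 1$ after the shift
such that the circular distance between onset and the new dark onset
stays within $\varepsilon = 0.5$ h for $c = 2$ consecutive days. For an
animal correcting an $S$-hour shift at $\rho$ h/day with noiseless
onsets this equals $\lceil (S - \varepsilon)/\rho \rceil$ — 6 days for
a 6-h advance at 1 h/day, with the default tolerance.

## The cohort simulator

Each simulated animal carries a circadian phase $\varphi$ advancing at
$24/\tau$ phase-hours per wall-clock hour, with $\tau$ set by the
lighting condition: 24.0 h entrained, 23.5 h in DD, 25.1 h in LL (the
values reported for C57BL/6J-like animals under these conditions).
Activity is gated on for the half-cycle from $\varphi = 12$; expected
minute activity is `baseline + amp` inside the gate (1 and 20 ALI by
default) and is multiplied by `mask_light = 0.2` whenever lights are on
(negative masking). Emission is zero-inflated gamma per minute: a zero
with probability 0.2, otherwise a gamma draw (shape 1) whose mean keeps
the minute's expectation — reproducing the skewed, zero-heavy
distribution of electrode-activation counts. One 5-min gap per day at a
fixed wall-clock time is marked missing, emulating welfare checks.

Three design choices deserve explanation:

* **Entrainment is a daily step, not a continuous pull.** On entrained
  days the phase is corrected toward lock at each lights-on by at most
  $\rho = 1$ h, and corrections begin at the first lights-on *after* a
  schedule change — the animal has to experience one full shifted cycle
  before adjusting. This produces onset deviations of exactly
  6, 5, 4, 3, 2, 1, 0 h on days 0–6 after a 6-h advance, i.e. the
  aggregate 1-day-per-hour rule, without inventing a phase-response
  curve the data would not identify. The entrained period is
  consequently 24.0 h for every animal — a locked oscillator expresses
  the zeitgeber's period, which is why cohort jitter is applied to the
  free-running periods and amplitude only.
* **The pulse delays the phase instantaneously and releases the animal
  into free run.** The injected delay is 1.3 h; from the end of the
  pulse the phase advances at the DD rate (the remainder of that night
  is dark and no light follows), which is what an Aschoff type II
  protocol assumes.
* **Arrhythmic (cryptochrome-deficient-like) animals have no
  oscillator.** Their gate is driven by light alone — active in the
  dark and for 1 h before each dark onset (hence earlier apparent
  onsets), with weaker light suppression (0.5) and heavier zero
  inflation (0.5) — and it churns on/off in independent 6-min blocks
  (on-probability 0.7). The churn fragments activity, raising IV and
  the short-bout count the way clock-less animals fragment; at the
  periodogram's analysis bin width the blocks are uncorrelated, so DD
  activity is statistically white and the periodogram correctly finds
  nothing. Longer churn blocks would inflate the periodogram's
  fluctuations beyond its chi-square null and produce spurious
  "rhythmic" calls — a known liberality of the test under
  autocorrelation that the simulator deliberately avoids building in.
* **LL weakens rhythms by masking, not by an arrhythmia switch**: the
  24-h light multiplies the whole cycle by `mask_light`, shrinking the
  expressed amplitude while the period lengthens to `tau_ll`.

The simulator emulates the statistical structure the analysis relies on
— gated, masked, skewed, zero-inflated, gap-ridden activity with
condition-dependent period and rate-limited re-entrainment. It does not
emulate ultradian feeding bouts in wild-type animals, cage-change or
oestrous effects, sex differences (multipliers exist but default off),
thermoregulatory or sleep structure, or electrode-level spatial detail.
Passing recovery tests therefore demonstrates estimator correctness
under realistic noise, not robustness to every artefact of real
recordings.

## Analysis windows and problem sizes

Metrics are computed per protocol phase on up to 7 consecutive full
days from the phase's first full day (one week per lighting condition);
a phase needs at least 5 full days to be analysable, otherwise its row
is emitted with `NA` markers and a warning — the rule that tolerates a
truncated final recording. The periodogram needs at least 3 full cycles
of the longest candidate (4.3 days at 32 h). The baseline LD phase
contributes 6 full days, because the day of the 6-h advance is 18 h
long and breaks the run of complete days.

The validation suite runs the full pipeline on a 12-animal wild-type
cohort over the 62-day protocol and on a 6 + 6 wild-type/arrhythmic
cohort over 17 days — about 90 s of compute in total; these sizes were
chosen to match the study design they emulate while keeping the
package's checks quick to run.

## Known limitations

* The chi-square periodogram's null is anti-conservative for
  autocorrelated activity; the Bonferroni-corrected peak call mitigates
  but does not remove this. Cross-checking arrhythmicity calls against
  IS and RA is advisable on real data.
* The onset template assumes a rest-to-active step; animals with very
  gradual onsets or bimodal activity may need different window widths
  (both are arguments).
* Day boundaries under constant conditions project the last real
  lights-on forward on a 24-h grid; after many free-running cycles the
  onset can wrap across that boundary, and downstream statistics use
  circular arithmetic to stay correct, but actogram rows will show the
  onset walking across the plot — as they do on paper actograms.
* The re-entrainment criterion is onset-based only; activity offset or
  midpoint criteria are out of scope.
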