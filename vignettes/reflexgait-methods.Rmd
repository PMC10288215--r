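---
title: "Quantifying phase-dependent cutaneous reflexes and interlimb coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phase-dependent cutaneous reflexes and interlimb coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexgait)
library(dplyr)
```

## The problem

During locomotion, a brief electrical stimulus to a cutaneous nerve (the
superficial radial nerve at the wrist, or the superficial peroneal nerve at
the ankle) evokes short reflex responses in muscles of all four limbs. These
responses are strongly *phase-dependent*: the same stimulus can excite a
muscle in swing and inhibit it in stance, and the depth of that modulation
changes with the locomotor task — for instance between tied-belt treadmill
locomotion (equal left-right belt speeds) and split-belt locomotion (unequal
speeds), which imposes a sustained left-right asymmetry.

`reflexgait` implements the full analysis chain needed to quantify this:

1. **Spatiotemporal gait parameters** from paw contact/liftoff events:
   cycle, stance and swing durations, step and stride lengths.
2. **Interlimb coordination** as circular quantities: phase intervals
   (contact-timing offsets in degrees), gap intervals (contact-placement
   offsets in degrees), left-right symmetry indexes, resultant vector
   lengths, Rayleigh and Watson–Williams tests.
3. **Reflex quantification**: baseline locomotor EMG (blEMG) from control
   cycles, stimulus-triggered averaging per phase bin, automated response
   detection against a confidence band, latency classification (P1/N1,
   P2/N2, P3/N3), net reflex values and phase-modulation indexes.
4. **Group statistics**: one-factor repeated-measures ANOVA with unadjusted
   pairwise comparisons and pooling of left/right nerve datasets.
5. A **synthetic session generator** with ground truth, so that every stage
   is testable end-to-end without recorded data.

## Definitions implemented

With cycles defined from successive paw contacts of the same limb
(reference limb: left forelimb, except the homologous hindlimb coupling,
which uses the left hindlimb):

* **Cycle duration** = time between successive contacts; **stance** =
  contact to liftoff; **swing** = cycle − stance.
* **Stride length** = |x(contact) − x(liftoff)| + belt speed × swing
  duration.
* **Step length** = horizontal paw separation at the leading limb's contact;
  the trailing paw's position is interpolated at belt speed during stance
  and linearly between liftoff and the next contact during swing (the
  event-level analogue of video tracking).
* **Phase interval** = contact-time offset / reference cycle duration × 360°
  (180° = strict alternation; 0°/360° = in-phase).
* **Gap interval** (homologous pairs) = step length / reference stride
  length × 360° (180° = contacts half a stride apart).
* **Symmetry index** = |angle − 180°| / 180° × 100 — the relative deviation
  from perfect left-right alternation. We interpret "relative deviation
  from 180°" with this formula; it is mirror-symmetric about 180° and maps
  0°/360° to 100%.
* **Net reflex value** = (∫stimulated − ∫blEMG) / ∫blEMG over the response
  window (trapezoidal integration of rectified traces). The subtraction
  order makes excitation positive and inhibition negative, matching the P/N
  response letters, and the division makes the value invariant to overall
  EMG scale (electrode gain).
* **Modulation index** = max − min of the normalized responses over the 10
  phase bins of a condition. Normalization is to the maximal *signed* net
  value per muscle/latency window across all conditions; this is exactly
  what lets the index exceed 100% when a muscle is excited in some phases
  and inhibited in others (a `method = "abs"` alternative is available).

## Reflex analysis pipeline

Cycles are tagged **stimulated** (a stimulus fell inside the half-open
cycle), **excluded** (the cycle right after a stimulated one) or **control**.
Control cycles, rectified and time-normalized, give the blEMG and its 10
bin means. Stimulated cycles are grouped by the phase bin of their stimulus,
`floor(10 × fraction)` clamped to bin 9.

**Detection.** The original workflow identified deflections visually, guided
by 97.5% confidence intervals; here detection is automated and the exact
criterion is a documented surrogate. For each bin we average the rectified
EMG around each stimulus, and build a baseline from control cycles sampled
at the *same within-cycle fractions* as that bin's stimuli, so stimulated
and baseline averages see the same locomotor envelope. Baseline windows that
would overlap any post-stimulus span, or leave the recorded gait span, are
discarded. Both traces are smoothed with a 2 ms moving average. A response
opens when the stimulated average leaves the t-based 97.5% band for at least
3 ms with onset inside 7–60 ms, and closes when it returns into the band.
The band's standard error uses the two-sample form
`sd × sqrt(1/n_stim + 1/n_control)`: a band built from the control mean
alone would ignore the sampling noise of the stimulated average (n = 4–26
stimuli per bin) and inflate the false-positive rate well above the nominal
level. With this form plus the 3 ms persistence rule, the per-cell
false-detection rate on null injections stays at or below 5% (verified by
simulation in the test suite).

**Classification.** Onsets 7–18 ms are short-latency (P1/N1), 19–34 ms
mid-latency (P2/N2), 35–60 ms long-latency (P3/N3). Responses in
non-stimulated limbs with onsets ≤ 18 ms are always P1/N1 (the minimal
spino-bulbo-spinal latency). Onsets below 7 ms are rejected as stimulus
artifacts. The printed windows leave 1 ms gaps (18–19, 34–35 ms); onsets
falling in a gap go to the nearer window and are flagged — the source
convention never addresses them, so the flag preserves the information.

**Activity windows.** The activity period of a muscle is the longest
contiguous (circular) run of phase bins whose blEMG mean exceeds
`min + 0.2 × range`; mid-activity and mid-inactivity windows are the period
midpoints ± 7.5% of the cycle. The 20% threshold is a package choice — any
threshold between the noise floor and the burst peak recovers a
raised-cosine burst's window to within one bin, which is what the tests
assert.

## Circular statistics

The resultant vector length `r` is the modulus of the mean unit vector;
the Rayleigh statistic is `z = n r²` with the finite-sample approximation
`p = exp(sqrt(1 + 4n + 4(n² − R²)) − (1 + 2n))`, `R = n r` — the expression
used by the standard circular-statistics toolboxes, against which our
implementation is checked to 1e-6. Watson–Williams is the high-concentration
F test with the `1 + 3/(8κ̂)` correction and Fisher's `A⁻¹` approximation
for κ̂; warnings are emitted when the weighted mean resultant length falls
below 0.45 or groups are small. Tests verify agreement with a
10,000-permutation oracle to within 0.02. Two analysis entry points exist:
per-cycle angles within one subject (`coupling_angles`), and group-level
summaries where per-subject means are compared across conditions.

## Inference

`rm_anova()` is the one-factor within-subjects F test computed from the
two-way sum-of-squares decomposition (subjects as blocks), cross-checked
against `aov()` with an `Error()` stratum to 1e-6. No sphericity correction
is applied by default, matching the analysis being reproduced;
Greenhouse–Geisser is available behind a flag. Pairwise comparisons are
paired two-sided t tests with *raw* p values — multiplicity adjustment is
deliberately not applied in this workflow (to avoid type-II errors), and
the package follows that choice rather than imposing one. Left/right nerve
datasets from the same animal are pooled as separate rows
(`pool_nerve_datasets()`), excluding datasets without an evoked response.
Treating two sides of one animal as independent rows is statistically
questionable; it is implemented as specified and should be read as a caveat.
Normality is not gated: with these sample sizes a normality test has little
power, and the pipeline mirrors the assumption made in the analysis it
reproduces.

## The synthetic generator

`simulate_session()` is a forward model of a four-limb treadmill session,
not a biophysical EMG model. What it emulates, with defaults chosen to match
the study conditions:

* **Conditions and speeds**: tied 0.4/0.4 and 0.8/0.8 m/s, split 0.4 vs
  0.8 m/s.
* **Cycle durations**: linear in the mean belt speed, `1.05 − 0.5·v` s,
  giving ≈0.85 s (tied slow) > ≈0.75 s (split) > ≈0.65 s (tied fast) — the
  observed ordering. Stance fraction is linear in the limb's own belt speed
  (`0.80 − 0.25·v`), so the slow side of a split session stands longer.
  Coefficients are free parameters with these documented defaults.
* **Coupling**: homologous pairs alternate at 180°, the homolateral pair
  at 270° (diagonal 90° follows). Per-cycle deviations are von Mises;
  concentrations default so tied-fast is tightest and the split conditions
  have the largest *spatial* dispersion. Gap-interval targets are 180°
  (tied) and 270°/90° (split) — realized by placing the non-reference paw a
  step of `gap/360 × reference stride` away. The prose description of
  270°/90° as "1/3 and 2/3 of the stride" is arithmetically inconsistent
  with the defining formula (90/360 = 1/4); the formula is implemented.
* **EMG**: per muscle, a raised-cosine burst over its activity window
  (extensors in stance, flexors in swing) on a 0.05 a.u. floor, with
  multiplicative (SD 0.15) and additive (SD 0.05) Gaussian noise, clamped at
  zero. Sample rate defaults to 2000 Hz — comfortably above the 1000 Hz
  minimum needed to resolve 7–60 ms response windows.
* **Stimulation**: trains of 3 × 0.2 ms pulses at 300 Hz, 1.2 × motor
  threshold (metadata), delivered every 2–4 cycles; 360 cycles give ≈120
  stimuli per condition. The within-cycle delay is uniform, so all 10 phase
  bins are populated; the delay distribution of the original protocol
  ("varying delays" from an extensor-burst onset) is unspecified, and
  uniform-over-cycle is the stated assumption.
* **Injected responses**: smooth raised-cosine bumps at configurable onset
  and duration (any C¹ unimodal kernel would do; this one is fixed and
  documented). Amplitudes are expressed in *net-reflex units*: each bump's
  discrete integral equals the profile value of the stimulus phase bin times
  the integral of the clean envelope over the bump support. On noise-free
  sessions the pipeline therefore recovers the injected 10-bin profile
  *exactly* (to machine precision) when integrating over the injected
  window — the package's strongest self-test. Inhibitory bumps cannot drive
  the signal below zero; profiles beyond roughly −0.5 saturate against that
  physical floor, so default inhibitions stay at −0.4.
* **Determinism**: one integer seed feeds a single RNG stream; identical
  configurations give bit-identical sessions. Event and stimulus times are
  snapped to the EMG sample grid, which is what makes the noise-free
  recovery exact rather than merely close.

What the generator does **not** emulate: motor-unit potentials and EMG
spectra, stride-to-stride drift or fatigue, irregular stepping (the
real workflow removes such sections by inspection), video/pose estimation,
and supraspinal pathways. Passing tests therefore demonstrate that the
*analysis* is correct and calibrated under the stated noise model — not
that real recordings meet those assumptions.

## Numerical choices and degenerate inputs

* Angles live in `[0, 360)`; a resultant length below 1e-12 flags the mean
  direction as undefined. Watson–Williams errors on a degenerate
  denominator (all angles identical within every group).
* `rm_anova` returns F = 0, p = 1 when the factor sum of squares vanishes
  (all cells equal) and F = ∞, p = 0 when the error stratum vanishes with a
  non-zero effect. Pairwise comparisons: all-zero differences give t = 0,
  p = 1; constant non-zero differences (zero variance, undefined t) raise
  an error naming the pair.
* Net reflex values are undefined (NA, with a warning) when the integrated
  blEMG falls below a floor (default 1e-9) — the division-blow-up guard.
* Bins with fewer than 4 stimulated cycles are reported as `insufficient`,
  never silently dropped.
* Problem sizes in the test suite: sessions of 60–720 cycles at 2000 Hz,
  2,000 null simulations for the ANOVA type-I calibration, 10,000
  permutations for the Watson–Williams oracle — sizes at which the checked
  properties are statistically meaningful while the suite stays quick.

## Known limitations

* The automated detector is a surrogate for visual scoring guided by
  confidence bands; on real data the two can disagree near threshold.
* blEMG phase bins are defined on the reference limb's cycle for all
  muscles (as in the source workflow); muscles of other limbs have their
  activity windows phase-shifted by the coupling.
* The generator's uniform stimulus-delay assumption and its simple noise
  model are idealizations; calibration figures (e.g. the ≤5% false-positive
  rate) are statements about this model.
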