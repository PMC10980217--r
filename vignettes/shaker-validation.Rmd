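---
title: "Validating raw wearable accelerometry on an orbital shaker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating raw wearable accelerometry on an orbital shaker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shakeval)
```

Mechanical shaker tables are the standard bench reference for accelerometer
validation: an orbital shaker translates its plate in a horizontal circle of
known diameter at a set frequency, so every device clamped to it experiences
a centripetal acceleration of known, constant magnitude. shakeval implements
the full analysis chain for such a study — reference model, trial protocols,
a synthetic raw-signal generator, second-level ENMO processing, and the
reliability/validity/equivalence statistics — so the pipeline can be
developed and tested end to end without bench recordings.

## The reference: frequency to acceleration

For an orbit of radius $r$ (cm) at rotational frequency $f$ (Hz), the plate
speed is $v = 2\pi r f$ and the textbook centripetal acceleration is

$$a = \frac{v^2}{r} = 4\pi^2 r f^2 \quad \text{(cm/s}^2\text{)} .$$

`shaker_config()` holds the orbit geometry (default diameter 1.9 cm) and the
gravity constant used to express $a$ in units of g (980 cm/s², i.e.
g = 9.8 m/s²). Two conversion variants are provided because the reference
magnitudes this class of study reports for a 1.9 cm orbit — 4.4 mg at 0.6 Hz
and 124.7 mg at 3.2 Hz — equal the textbook expression divided by exactly
$\pi$, i.e. $a = 4\pi r f^2$. The `"as_used"` variant (the default)
reproduces those anchors; `"as_printed"` keeps the textbook form. The ratio
between the two is $\pi$ at every frequency, and both are quadratic in $f$
and zero at rest. We deliberately default to the variant that matches the
reported reference values rather than guessing which form was intended;
analyses that need the textbook form switch one argument.

## Trial protocols

Two protocol builders reproduce the study timelines:

* **Validity** (`build_validity_protocol()`): 15 s rest, seven 2-minute
  oscillation blocks at 3.2, 2.8, 2.4, 1.9, 1.5, 1.0, 0.6 Hz (fastest
  first), 15 s rest — 870 s in total.
* **Reliability** (`build_reliability_sequence()`): `n_trials` back-to-back
  2-minute trials at one speed with a 15 s rest at each end; five trials at
  one speed occupy 630 s. The batch timing is only consistent with rests
  book-ending the run rather than wrapping every trial, so the bookend
  layout is the default and `per_trial_rests = TRUE` is available. With
  four brands, two batches of five devices, two speeds and five trials,
  `reliability_study_design()` accounts for the design's 80 trials.

Seconds are 0-based and half-open from protocol start. `reference_trace()`
expands a protocol into one reference value per second (0 during rest).

## The synthetic signal generator

`simulate_device_stream()` produces raw triaxial streams the way a clamped
device would record them. The ideal plate signal during oscillation is a
rotating vector of constant magnitude $a$ (the reference acceleration in g)
in the orbit plane, plus the constant 1 g gravity reaction.

**Mounting.** A rotation cannot change a vector norm, so if gravity were
simply composed with the motion before rotating into device axes, every
orientation would yield the same ENMO. What matters physically is the angle
between the orbit plane and gravity as the device senses them. The
generator therefore rotates the *orbital motion* into the device frame and
keeps gravity on the device z axis: `device = R %*% motion + (0, 0, 1)`.
With the identity rotation (`mounting_flat()`) gravity stays perpendicular
to the motion and the signal norm is constant at $\sqrt{1 + a^2}$, giving
tiny ENMO ($\approx a^2/2$). With `mounting_upright()` (the default) the
orbit plane contains the gravity axis, the norm oscillates as
$\sqrt{1 + 2a\sin\theta + a^2}$, and second-level RMS ENMO scales as
$\approx a/\sqrt{2}$ — the magnitude regime wearable devices actually
report on a shaker. `ideal_enmo_stats()` provides the closed-form
(flat) and quadrature (general) cycle averages used as an independent
oracle for the sampled pipeline.

**Hardware model.** Per device: sampling rate and dynamic range from
`brand_preset()` (ActiGraph 100 Hz ±8 g, Apple 100 Hz ±8 g, Garmin 25 Hz
±8 g, Fitbit 50 Hz ±4 g; the Apple and Garmin ranges are documented
defaults, not published figures), per-axis gain and bias, additive Gaussian
noise (default SD 0.01 g per axis, a typical MEMS magnitude), hard clipping
at the range, and dropout that removes whole 1 s blocks so downstream
missing-second handling is exercised. The phase at each segment start is
drawn from the seeded RNG; per-second aggregates are phase-robust only for
seconds containing at least one full cycle, which is why comparisons
against the cycle-average oracle aggregate over the middle minute (60 s
contains an integer number of cycles at all seven protocol frequencies).
The `all_negative_enmo` fault mode halves the recorded vector so its norm
never reaches 1 g — the implausible-device signature.

**Inter-device spread.** `simulate_brand_devices()` jitters bias
(SD 3 mg/axis) and gain (SD 0.2%) across units. These are
factory-calibration magnitudes, chosen once: because the mean-aggregate
ENMO of pure orbital motion is small (see below), a 1% gain error would
shift the 1 g baseline by 10 mg and routinely produce *healthy* devices
whose ENMO never crosses zero, which contradicts the screening premise
that all-negative ENMO marks a faulty unit.

**What the generator does not emulate.** Firmware filtering, timestamp
jitter, temperature drift, the vibration harmonics and rattle of a real
clamp, or real devices' proprietary onboard processing. Passing tests
therefore demonstrate that the *pipeline and statistics* are correct under
a controlled signal model, not that any real device would achieve the
simulated agreement.

## Signal processing

ENMO is $(\sqrt{x^2+y^2+z^2} - 1) \times 1000$ mg per sample. Negative
values are retained (no truncation at zero) because the device-exclusion
rule — drop a device when *all* of its values are below zero — presupposes
that negative ENMO is representable; GGIR-style truncation is available as
an option but off by default. Aggregation to seconds takes the arithmetic
mean and the RMS of per-sample ENMO within each whole second; incomplete
seconds are dropped, not padded. The middle minute (seconds 30–89) of each
2-minute block is retained, giving 60 seconds per block, 420 per device
through the validity protocol, and the familiar count laws (10 devices →
4,200 device-seconds; 9 after one exclusion → 3,780). Missing seconds
propagate as absent rows; nothing is imputed.

### Mean versus RMS aggregation

Under the idealized orbital model the within-second mean of ENMO nearly
cancels (cycle average $\approx a^2/4$, under 4 mg even at 3.2 Hz), while
the RMS tracks $a/\sqrt{2}$. Synthetic studies therefore show high
correlation, concordance and reliability for the RMS aggregate and weak
ones for the mean aggregate. Real devices report substantial mean ENMO
because their raw output contains more than the ideal translation; this is
a known divergence between the simulator and bench data, and it is why the
package's synthetic-study reports should be read primarily through the RMS
rows.

## Agreement statistics

* **ICC(2,1)** (`icc_2way_random_absolute()`): two-way random effects,
  absolute agreement, single measure, computed from the ANOVA mean squares,
  with the McGraw–Wong F-based 95% CI. Subjects are seconds; raters are the
  five co-mounted devices. Ten devices tested five-at-a-time yield one ICC
  per brand by stacking batches as additional subjects with columns indexed
  by clamp position (`summarize_reliability()`); how the original design
  combined batches is not stated anywhere we can check, so this choice is
  documented prominently and a single batch passes through unchanged.
  Interpretation bins are lower-inclusive: < 0.50 poor, 0.50–0.75 moderate,
  0.75–0.90 good, ≥ 0.90 excellent.
* **Lin's CCC** (`lins_ccc()`): population-moment estimator with the
  Fisher-z CI using Lin's asymptotic standard error. CCC = r × C_b with
  C_b ∈ (0, 1], so |CCC| ≤ |r| always. The narrative ladder (< 0.20 poor,
  0.20–0.40 fair, 0.40–0.60 moderate, 0.60–0.80 good, ≥ 0.80 excellent) is
  used for interpretation only.
* **Error metrics** (`mean_absolute_error()`, `mean_bias_loa()`): MAE, and
  mean bias with 95% limits of agreement (bias ± 1.96 SD of differences).
  Published tables in this literature sometimes label LoA-width intervals
  as "95% confidence intervals"; both the LoA and the (much narrower)
  SE-based CI of the mean bias are returned, explicitly labelled, with LoA
  used for table reproduction.
* **TOST** (`tost_one_sample()`): two one-sided t-tests at α = 0.05 against
  a ±6.3 mg zone by default; equivalence iff the 90% CI of the mean
  difference lies strictly inside the zone (provably the same decision as
  both one-sided p-values < α; the tests assert this duality on random
  inputs). The fixed 6.3 mg is retained as the reproduction default even
  though 10% of the mean reference over the seven protocol speeds is
  ≈ 5.4 mg; the fractional derivation is available and the discrepancy is
  surfaced rather than resolved by guesswork. Pooling per-second
  differences ignores device-level clustering (observations within a
  device are not independent), mirroring the study convention; the CIs are
  accordingly anti-conservative.

## Numerical choices and degenerate inputs

Quadrature for the ENMO oracle uses a 4096-node midpoint rule over the
cycle. ICC with zero total variance, correlations with zero variance, and
CCC with two constant series are errors, not NaNs. Perfect agreement
(residual variance 0) collapses the ICC CI to the point estimate, as does
a zero-spread TOST interval, where equivalence is then decided by the
interval rule. The ICC CI uses Satterthwaite degrees of freedom; Lin's
variance expression can round fractionally negative at r ≈ 1 and is
floored at zero. Clipping is applied after gain, bias and noise; the fault
mode is applied before clipping. All simulation randomness flows through a
single integer seed per stream (`withr::with_seed`), so identical inputs
give bit-identical streams.

## Problem sizes used in the test-suite and reports

The packaged synthetic study uses 10 devices per brand for validity and
2 batches × 2 speeds × 5 trials for reliability — the full design — at the
native sampling rates. Calibration checks use 10,000 TOST replicates of
n = 100 and a 10,000-second ICC recovery problem; oracle cross-checks use
100 random 5×10 matrices. These sizes keep every analysis comfortably
reproducible on a laptop while leaving Monte-Carlo error well below the
asserted tolerances (TOST rate within ±0.01 of α, ICC recovery within
0.02 of the variance-component target).

## Known limitations

* The generator's agreement level is set by its noise/bias defaults, not
  calibrated to any real device; absolute CCC/MAE values from synthetic
  runs characterize the model, not hardware.
* Mean-aggregate results under the orbital model are structurally near
  zero (see above).
* Device clocks are assumed aligned to the protocol start; only a constant
  per-device offset is supported.
* No spin-up/spin-down transients between frequency blocks are modelled;
  each block is steady state, which is also why the middle minute is the
  analysis window.
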