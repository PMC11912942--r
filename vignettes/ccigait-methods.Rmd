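---
title: "Quantifying muscle co-contraction in treadmill gait: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle co-contraction in treadmill gait: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccigait)
```

## The problem

Children with cerebral palsy (CP) commonly show elevated *co-contraction*:
simultaneous activation of muscles that act as agonist and antagonist about a
joint, which stiffens the joint, raises the energetic cost of walking and
limits selective motor control. Aquatic treadmill walking is a candidate
intervention -- buoyancy unloads the limbs and water both supports and
resists movement -- and a natural question is whether it reduces
co-contraction relative to conventional (dry) treadmill walking, at matched
relative speeds, in CP and typically developing (TD) children.

Co-contraction is not a directly observable quantity. It is estimated from
surface EMG of an agonist-antagonist pair through a *co-contraction index*
(CCI), and several competing index definitions are in routine use. Because
the definitions weight magnitude, timing and muscle role differently, the
same trials can lead to different clinical conclusions depending on the
index. This package implements the full analysis chain for two standard
pairs -- rectus femoris / semitendinosus (RF/ST, thigh) and tibialis
anterior / medial gastrocnemius (TA/MG, shank) -- under three index
definitions, together with a synthetic-data generator that makes every stage
testable against known ground truth.

## Signal model and processing chain

### Linear envelopes

Raw EMG is modelled, per muscle, as activation-amplitude-modulated
zero-mean, unit-variance white noise plus additive sensor noise:

$$x(t) = a(\phi(t))\,\varepsilon(t) + \sigma\,\eta(t), \qquad
  \varepsilon, \eta \sim \mathcal{N}(0, 1),$$

where $\phi(t) \in [0,1)$ is the gait-phase fraction at time $t$ and
$a(\cdot)$ the activation profile. Under this model the classic *linear
envelope* -- bias removal, full-wave rectification, low-pass filtering --
estimates $\mathbb{E}|x| = \sqrt{2/\pi}\,\sqrt{a^2 + \sigma^2}$, i.e. the
activation profile up to a known constant when $a \gg \sigma$.

`linear_envelope()` uses a dual-pass (forward-backward, hence zero-phase)
Butterworth low-pass, 2nd order per pass, 6 Hz cutoff. Three conventions had
to be fixed where common usage is ambiguous:

* "2nd order" is interpreted *per pass* (4th order effective after the dual
  pass), with no cutoff correction for the second pass; `order` and
  `cutoff_hz` are arguments, so the alternative reading is selectable.
* Edge effects are handled by odd (reflective) padding of length
  3 x filter order before the forward-backward pass.
* Negative undershoot left by the filter is clipped to zero, because every
  CCI formula assumes nonnegative activation.

### Dynamic normalization

Envelopes are normalized per muscle by the maximum envelope value observed
in that limb's **Dry Fast** trial (`dynamic_normalize()`). A dynamic
reference task is preferred over maximal voluntary contraction in pediatric
and clinical gait work because maximal efforts are unreliable in these
populations. Two further conventions were open and are fixed as defaults
(both are the natural readings for an envelope-domain index):

* the reference maximum is taken from the *filtered envelope*, not the raw
  rectified signal;
* normalization is per limb, not per participant -- the two limbs of one
  participant get independent factors.

Values above 1 in non-reference trials are legitimate and preserved. The
reference trial's own maxima are exactly 1, and renormalizing an already
normalized limb is a no-op, which the test suite checks.

### Gait segmentation

Initial contacts are detected from the foot's vertical acceleration as the
dominant impact peaks (`detect_initial_contacts()`): local maxima whose
topographic prominence reaches twice a robust noise scale (scaled median
absolute deviation), thinned to a minimum separation of half the expected
stride time. Two practical points:

* The prominence rule alone is scale-free -- an isolated noise maximum has
  prominence of roughly four noise SDs against a threshold of two -- so
  wherever stride-time variability leaves room beyond the minimum
  separation, noise peaks can slip through. `detect_initial_contacts()`
  therefore accepts an optional `height_frac` criterion (a fraction of the
  trial's maximum acceleration); the pipeline wrapper `analyze_cohort()`
  uses 0.5, which implements the "greatest peaks" reading directly, since
  impact transients are an order of magnitude above the noise floor.
* The expected stride time is estimated per trial from the median spacing of
  dominant peaks (`estimate_stride_time()`), so the separation guard adapts
  to each condition's walking speed instead of assuming one cadence.

Strides are left-closed windows between consecutive contacts, with times in
seconds from trial start. Stride-time outliers are flagged in a single,
non-iterative pass using the sample SD: a stride is removed iff its duration
deviates from the mean by more than 3 SD. The rule is applied per trial
(whether the original convention was per trial or per participant is not
decidable; per trial is the more conservative reading). With fewer than
three strides no spread can be estimated and nothing is flagged.

Each retained stride's envelopes are linearly interpolated onto a fixed grid
of 101 points spanning 0-100% of the stride (both endpoints included), so
strides of different durations are comparable. Strides extending beyond the
recording are dropped, never padded.

### The three indices

For a muscle pair with envelopes $e_1, e_2$ on the 101-point grid, with
$s = \min(e_1, e_2)$, $l = \max(e_1, e_2)$ pointwise:

* **Common-area index** (`cci_unnithan()`):
  $\mathrm{CCI} = \int_0^{100} s(\phi)\, d\phi$ by the trapezoid rule on the
  percent phase axis. Captures intensity and duration of simultaneous
  activation; symmetric in the two muscles. The percent axis (0-100 rather
  than 0-1) is adopted because it reproduces the magnitude range of
  published condition tables for normalized envelopes (roughly 5-23).
* **Ratio-weighted index** (`cci_rudolph()`):
  $\mathrm{CCI} = \frac{1}{101}\sum_\phi \frac{s}{l}(s + l)$. Weights timing
  (the ratio) and magnitude (the sum); low values indicate selective
  activation.
* **Antagonist-fraction index** (`cci_falconer_winter()`):
  $\mathrm{CCI} = \frac{1}{101}\sum_\phi \frac{2\,e_{ant}}{e_{ant}+e_{ago}}
  \cdot 100\%$, bounded in $[0, 200]$, with the antagonist fixed for the
  whole cycle: RF in RF/ST, TA in TA/MG.

Samples where the denominator vanishes (silent pair) contribute zero by
default -- co-contraction requires activation -- with a `zero_policy =
"drop"` alternative that excludes such samples from the mean. Per-stride
values are averaged into one value per trial (`cci_trial()`).

## The synthetic cohort

No public recordings accompany the study design this package models, so the
generator (`simulate_cohort()`) is first-class, tested code rather than a
fixture. It emulates:

* **Gait-phase structure**: per-muscle activation is a tonic co-activation
  floor plus Gaussian bursts at textbook gait phases (TA around initial
  contact and swing; MG through stance; RF in loading response and
  pre-swing; ST around terminal swing, wrapping continuously across the
  100% -> 0% boundary).
* **Condition effects**, all multiplicative on activation amplitude:
  an aquatic factor (default 0.6) applied to Wet trials; speed factors
  0.75 / 1.00 / 1.25 mirroring walking at 75 / 100 / 125% of self-selected
  speed (stride time scales inversely with the same factor); and a higher
  tonic floor for CP (0.15) than TD (0.05) participants.
* **Stride timing**: lognormal stride durations (mean 1.1 s at Normal
  speed, CV 0.05), with occasional outlier strides (probability 0.02)
  lengthened by a factor 1.8.
* **Participant heterogeneity**: a lognormal burst-amplitude multiplier per
  participant (SD 0.15 on the log scale), shared across that participant's
  trials -- the data-generating justification for a random intercept per
  participant.
* **Instrumentation**: EMG at 2000 Hz; foot vertical acceleration at 142 Hz
  carrying a ~50 ms half-sine transient centred on every initial contact
  over a low noise floor; both streams share one clock and trials begin at
  an initial contact (synchronization details are not specified by the
  study design; a shared clock is the simplest consistent choice).

Cohort sizes default to the study design being emulated: 15 TD and 10 CP
participants, both limbs, all 2 environments x 3 speeds per limb, ~3-minute
trials (150 strides). Effect *directions* follow the published condition
tables (CP > TD co-activation, Wet < Dry amplitude, Fast > Slow amplitude);
effect *magnitudes* are invented, documented defaults -- the pipeline's job
is to recover whatever is injected, not to reproduce clinical values. The
additive noise floor defaults to 1% of the burst scale; because this floor
is not scaled by the environment factor, a much larger value would dilute
recovered environment contrasts (the generator is required to hand the
envelope stage a recoverable effect, and does).

What the generator deliberately does **not** emulate: volume-conduction
crosstalk between channels, electrode lift-off and motion artefacts,
nonstationary fatigue drift, hydrodynamic loading of the limbs, or any
musculoskeletal dynamics. Passing tests therefore demonstrate that the
*processing chain* is correct and that injected condition effects survive
it; they say nothing about the physiological validity of any particular
clinical dataset.

## Study-level statistics

`summarize_conditions()` produces per-cell means and sample SDs over
limb-trials, keyed by pairing, method, population, environment and speed.
Percent-change contrasts are computed from *cell means* (not pooled
limb-trials): `environment_contrast()` averages the three speed cells within
each environment before comparing Wet to Dry; `speed_contrast()` averages
over whichever of environment/population is not fixed. This convention is
the one under which published percent statements are exactly recoverable
from printed condition tables, which is also what the worked examples and
the acceptance script verify (the package ships those printed cell values as
`reference_cci_summary()`).

`fit_model_ladder()` fits eight nested linear mixed-effects models by
maximum likelihood with `lme4`, starting from an intercept-plus-random-
intercept model and adding Environment, Population, Speed, then the two- and
three-way interactions one term at a time. Successive models are compared by
likelihood-ratio tests; the selected model is the most complex whose
addition is significant at `alpha` (default 0.05). Conventions fixed here:

* ML rather than REML throughout, because information criteria and
  likelihood ratios across different fixed-effect structures are only
  meaningful under ML.
* Sequential p-values come from likelihood-ratio chi-square tests between
  adjacent fits, the portable reading of `anova()` on nested `lmer` models.
* Limbs enter as repeated observations within participant (random intercept
  on participant only), matching the random-effects structure the design
  implies; `nest_limb = TRUE` adds a limb-within-participant intercept for
  sensitivity analysis.
* Singular fits are recorded in the returned object (`$singular`) but are
  not fatal; with small cohorts and weak participant heterogeneity the
  random-intercept variance legitimately estimates to zero.

## Numerical choices and degenerate inputs

* Trapezoid integration on the 101-point grid agrees with a $10^5$-point
  Riemann oracle to well under 1% for band-limited envelopes; the
  acceptance suite checks this property explicitly.
* Regular-grid linear interpolation is used for stride normalization; it is
  exact for constant and linear envelopes and clamps (rather than
  extrapolates) at the recording tail, where at most one sample can be
  missing.
* A constant EMG record has zero envelope by construction (the bias is the
  signal); series shorter than three padding lengths, sampling rates at or
  below twice the cutoff, unsegmentable acceleration traces, missing Dry
  Fast reference trials and dead channels (zero reference maximum) are all
  explicit errors rather than silent degradation.
* Ties $s = l$ in the ratio-weighted index need no tie-break: the formula is
  symmetric at equality.

## Problem sizes used by the test and acceptance suites

The packaged checks are sized to run comfortably on one CPU: unit tests use
cohorts of 1-8 participants with 3-10 strides per trial; the effect-recovery
check uses 6 TD + 6 CP participants, one limb, 10 strides per trial;
segmentation fidelity uses 50 full-length default trials (150 strides each);
and the operating characteristics of the Environment test use 200 null
cohorts plus 50 effect cohorts of 10 participants x 6 conditions x 6
strides, run through the complete raw-signal pipeline. These sizes are the
package's own choices for fast, reproducible verification; nothing prevents
re-running any of them at larger scale.

## Known limitations

* The common-area and ratio-weighted indices are magnitude-dependent, so
  they inherit any normalization bias; the antagonist-fraction index is
  scale-free but blind to timing. Disagreement among them on the same data
  is expected and is, in fact, the phenomenon the analysis is designed to
  expose.
* Only whole-cycle indices are computed. Sub-phase analysis (loading
  response, midstance, ...) would require gait events beyond initial
  contact, which foot-mounted accelerometry at 142 Hz does not reliably
  provide.
* The outlier rule assumes approximately symmetric stride-time scatter; a
  heavy-tailed stride distribution inflates the SD and can mask moderate
  outliers (the 3-SD rule is kept because it is the convention being
  modelled).
* Tukey-adjusted post-hoc pairwise comparisons and effect-size measures are
  out of scope; the descriptive percent-change contrasts plus the model
  ladder cover the package's analysis surface.
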