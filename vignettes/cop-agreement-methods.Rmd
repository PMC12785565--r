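---
title: "Methods: validating textile-sensor CoP against a force platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating textile-sensor CoP against a force platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copagree)
```

## Scope and model

`copagree` quantifies how well a six-sensor textile sock reproduces the
centre-of-pressure (CoP) trajectory measured by a force platform during
squat-type balance exercises. The package treats each *waveform pair* —
one sock and one platform recording of the same trial, one axis
(mediolateral X or anteroposterior Y) — as the unit of analysis, and
`cop_agreement()` is the per-pair fit around which everything else is
arranged.

### CoP from conductances

The sock's six knitted sensors sit at sock-local positions
`e0 = (50, 100), e1 = (−50, 100), e2 = (50, 0), e3 = (−50, 0),
e4 = (25, −100), e5 = (−25, −100)` mm (forefoot, midfoot, heel pairs; the
centroid is the origin). Sensor conductance `U_i` rises with local plantar
pressure, and the CoP is the conductance-weighted mean of the position
vectors,

$$\mathrm{CoP} = \frac{\sum_i U_i\, e_i}{\sum_i U_i}.$$

Two consequences shape the implementation. The formula is homogeneous of
degree zero in `U`, so conductance units (µS vs mS) never matter and the
kΩ→mS reciprocal conversion (`resistance_to_conductance()`) is provided
purely for completeness. And the result is a convex combination of the
`e_i`, so every valid sample lies in the sensors' convex hull — a property
the test suite asserts on random frames. A frame with zero total
conductance has no defined CoP; it is flagged invalid rather than raising
an error, because real recordings contain no-contact intervals (the
leg-lift marker, swing phases), and aborting a series on its first such
frame would be wrong. The sensor coordinates are *relative*: the
reconstruction describes the direction and pattern of load shift, not
anatomical position, which is why the downstream comparison is made on
mean-centred waveforms.

The coordinates are configurable (`sensor_geometry()`), with the printed
layout as the immutable default; this is what lets the simulator apply
placement jitter and per-participant foot scaling while the analysis side
keeps reconstructing with the nominal layout, reproducing the
placement-error mechanism of a real sock. The sign convention (positive X
toward e0/e2/e4) is shared by both feet; a `mirror` flag re-expresses a
left foot anatomically when needed. Nothing here calibrates absolute
pressure (kPa) or total force — out of scope by design.

### Preprocessing

The platform samples at 125 Hz; the sock hardware samples each channel at
up to 200 Hz. Both series are linearly interpolated onto a uniform grid
(`resample_cop()`), by default 125 Hz — resampling *down* to the slower
instrument rather than manufacturing sock samples beyond the platform's
information content. Interpolation never extrapolates beyond the valid
input range, and flagged-invalid gaps longer than `max_gap` (default
0.2 s) stay invalid instead of being bridged.

The instruments have one clock offset, not two, so a single lag is
estimated (`align_cop()`) and applied to both axes: an exhaustive search
over integer-sample shifts within ±`max_lag` (default 5 s), maximising the
Pearson correlation of the overlapping segments on the axis with the
larger platform variance, ties broken toward the smallest |lag|. We chose
exhaustive integer-lag correlation over feature matching (peak picking)
because it is deterministic, testable, and recovers sub-sample-accurate
lags to within one sample interval — the property suite requires ≥ 99%
recovery over 200 seeded trials at SNR ≥ 10. The 3 s leg-lift marker at
the start of each set (`detect_lift_marker()`: total conductance below a
tenth of its trial median for ≥ 2 s) is available to seed or sanity-check
the search window but is not required by it.

After alignment both series are cropped to the largest contiguous
mutually-valid run (keeping the timeline uniform) and mean-centred over
that full overlap. Centring is essential, not cosmetic: the platform
reports absolute coordinates relative to its own origin, so its mean
encodes where the participant stood; the sock's mean encodes how the sock
was donned. Only centred excursions are comparable. The removed means are
retained on the `aligned_pair` so absolute-scale analyses remain possible.

### Agreement statistics

For each pair with values `s_i` (sock) and `p_i` (platform), `i = 1..N`:

* **RMSE** `= sqrt(mean((s_i − p_i)^2))`, reported absolutely (mm) and as
  a fraction of `Δq`, the span between the 2.5% and 97.5% quantiles of the
  platform waveform. A mean-based relative error is impossible after
  centring (the mean is zero by construction); the quantile span of the
  reference instrument is the natural yardstick. Both the quantile pair
  and the reference waveform are configurable, since reasonable
  conventions differ (e.g. 5/95%).
* **Bland–Altman**: differences `d_i = s_i − p_i`; bias `⟨d⟩`; limits of
  agreement `⟨d⟩ ± 1.96 S(d)` at confidence level 0.95, with `S(d)` the
  sample (N−1) standard deviation. The multiplier is fixed at the
  conventional 1.96 at level 0.95 (the exact normal quantile is used for
  any other level). The fraction of points outside the limits is reported;
  ≈ 5% is expected under approximate normality.
* **Lin's CCC** `= ρ · χ` with accuracy coefficient
  `χ = 2/(v² + ω + 1/ω)`, `v² = (μ_s − μ_p)²/(s_s s_p)`,
  `ω = s_s/s_p`. This moments form is the implementation; the test suite
  independently checks it against the covariance form
  `2 cov(s,p)/(s_s² + s_p² + (μ_s − μ_p)²)` to 1e−10 on a thousand random
  pairs. Always `|CCC| ≤ |ρ|`, with equality exactly when means and scales
  agree; on centred pairs `v² ≈ 0` and `χ` reduces to its scale term.
* **Fisher-transform CI**: `λ = atanh(CCC)` with variance
  `σ_λ² = (1/(n−2)) [ (1−ρ²)CCC²/((1−CCC²)ρ²) +
  2CCC³(1−CCC)v²/(ρ(1−CCC²)²) − CCC⁴v⁴/(2ρ²(1−CCC²)²) ]`, interval
  `tanh(λ ∓ 1.96 σ_λ)`. In the centred equal-variance case this collapses
  to `σ_λ² = 1/(n−2)` exactly, which the tests assert. Degenerate inputs
  are flagged, not fudged: `|CCC| = 1` yields the point interval,
  `ρ = 0` an undefined interval. `n` is the number of time points in the
  pair; CoP samples are autocorrelated, so this `n` overstates the
  effective sample size and the intervals should be read as optimistic —
  a known limitation of the approach, noted rather than corrected here.
* **Classification**: a strict scale (≥ 0.99 almost perfect, 0.95–0.99
  substantial, 0.90–0.95 moderate, else poor) for replacement-grade
  claims, and a loose scale (≥ 0.80 high, 0.60–0.80 moderate, 0.40–0.60
  fair, else poor) for tracking-grade claims. Lower bounds are inclusive.
  The loose scale's bottom band is everything below 0.40, closing the gap
  a literal reading of the published band edges would leave at
  [0.30, 0.40).

`ccc_by_segment()` re-centres and re-fits within user-given segments. Its
purpose is diagnostic: an abrupt change of foot position on the platform
(a side-step) splits a recording into two baselines, wrecking the
whole-waveform CCC even when the sock tracks relative motion well within
each baseline.

## The simulator

The generator exists so that every stage has a ground truth. Its defaults
encode the study conditions of the measurement protocol, fixed once:

* **Design** (`study_design()`): 10 participants × 4 foot-conditions
  (single-leg squat right/left; both-leg squat with heel raise, right/left
  foot) × 2 sock applications, two axes analysed → 160 waveform pairs per
  modality.
* **Trials** (`trial_spec()`): 10 single-leg repetitions at 60 beats/min
  (one per beat, 10 s) or 30 s of continuous both-leg squats, each
  preceded by a 3 s leg-lift marker with zero load.
* **Trajectories** (`simulate_true_cop()`): a sinusoidal anteroposterior
  excursion at the tempo frequency plus slower mediolateral sway plus
  band-limited noise (moving-average-smoothed Gaussian, 0.2 s window,
  2 mm sd). Default amplitudes keep single-leg X within ±20 mm and
  both-leg Y within −50..+60 mm, the excursion ranges typical of these
  exercises. This is a phenomenological generator matching amplitude and
  periodicity, not a biomechanical simulation — passing tests say the
  *pipeline* is correct, not that real squats look exactly like this.
* **Sock forward model** (`simulate_sock()`): the trial's total load is
  split over the six sensors barycentrically (below), then
  `u = baseline + min(sensitivity · pressure, saturation) + noise`,
  clipped at zero. Per application, sensitivities are drawn uniformly
  from 0.5–3.0 µS/kPa (the knitted sensors' spread, dominated by how the
  sock is strained when donned) and sensor positions are jittered
  (2 mm sd). Saturation is a hard clip at a conductance ceiling — the
  phenomenon is reported for these sensors, its functional form is not,
  and a clip is the simplest shape that reproduces the observed
  compression of large excursions.
* **Platform model** (`simulate_platform()`): truth delayed by the drawn
  inter-instrument lag (U(−0.5, 0.5) s), plus a per-trial placement
  offset (U(−30, 30) mm per axis), Gaussian noise (0.5 mm sd), and an
  optional side-step offset from a given onset. Foot-off-plate intervals
  are flagged invalid.
* Per participant, a foot-scale factor U(0.9, 1.1) scales the *actual*
  sensor geometry while the analysis reconstructs with the nominal one —
  the inter-individual foot-morphology effect.

Instrument noise magnitudes are not published for either device; the
values above were chosen once as plausible bench figures that exercise
every error mechanism, and are deliberately not tuned to reproduce any
empirical agreement table.

### Barycentric load distribution

Inverting the CoP formula (one point → six pressures) is under-determined.
The generator uses barycentric weights over the triangle of sensors
containing the target point (fan triangulation of the hull anchored at the
first hull vertex; first containing triangle wins — fully deterministic),
all other sensors zero. The payoff is exactness: feeding the pressures
back through the CoP summation reproduces the target to machine precision,
so with an ideal sensor model (`ideal_sensor_model()`: unit sensitivities,
no baseline/noise/saturation/jitter) the truth → conductances → CoP round
trip is exact to well below 1e−9 mm, giving the pipeline a sharp
correctness oracle. The cost is realism — real plantar pressure spreads
over more than three sensors — which is acceptable because the forward
model's purpose is consistency with the reconstruction formula, not
tissue mechanics.

## Numerical choices and degenerate inputs

* Sample (N−1) standard deviations throughout; CCC clamped to [−1, 1]
  against floating-point excursions.
* Alignment requires ≥ 3 overlapping samples and errors on zero-variance
  segments ("flat signal") rather than returning an arbitrary lag.
* `resample_cop()` requires ≥ 2 valid samples; `normalize_cop()` ≥ 1.
* Zero reference span makes the relative RMSE undefined (flagged), never
  infinite; the absolute RMSE is still returned.
* Tie-breaks: alignment lags by smallest |lag|; triangle assignment by
  hull order; both documented so reruns are bit-reproducible.
* All simulation functions take seeds, restore the caller's RNG state,
  and derive per-trial child seeds from the study master seed, so a study
  is a pure function of its seed.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data: the full default study (80 trials, 160 pairs, ~13–33 s of signal per
trial at 125 Hz) for the enumeration and summary checks, and reduced
designs (1–2 participants) where a property is per-trial anyway. The
Monte-Carlo checks use 1,000 random pairs (CCC oracle), 10,000 samples
(Bland–Altman coverage) and 200 trials (lag recovery) — sizes at which the
asserted tolerances are comfortably stable across seeds.

## Known limitations

* The CCC interval treats time points as independent; autocorrelation
  makes the stated CIs optimistic.
* The trajectory generator is phenomenological; it does not model fatigue
  drift, double-support load sharing, or footwear (the protocol is
  shoeless by design).
* The barycentric forward model concentrates pressure on three sensors; a
  Gaussian-spread alternative would look more physiological but breaks
  the exact round-trip oracle, so it is not the default.
* Repeated-measures extensions (within-participant pooling of CCC or
  limits of agreement) are out of scope; each waveform pair is analysed
  independently.
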