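---
title: "Models and methods behind ionpore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ionpore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpore)
```

`ionpore` characterizes ion-conducting membrane pores from two kinds of
data: single-channel currents recorded in planar lipid bilayers under
voltage clamp, and ion-permeation events extracted from
molecular-dynamics style trajectories. This vignette documents the
models, the defaults and their rationale, the numerical choices, and the
limits of what the synthetic-data tests establish.

## Conventions

The membrane voltage is the potential of the *cis* chamber (the side the
protein is added to) with the *trans* chamber held at ground. All
equilibrium potentials follow the same convention,

$$E_{ion} = \frac{RT}{zF}\,\ln\frac{[ion]_{trans}}{[ion]_{cis}},$$

so for a 510 mM (cis) / 210 mM (trans) KCl gradient the K⁺ equilibrium
potential is negative (−22.8 mV at 25 °C) and the Cl⁻ one positive. In
the permeation module, direction +1 means motion from the cis-equivalent
side of the membrane slab to the other side, and positive voltage drives
cations in the +1 direction; with these two conventions the
electrophysiological and computational conductances carry consistent
signs.

Concentrations are used as given, without activity corrections: bilayer
work in this concentration regime conventionally reports
concentration-based equilibrium potentials, and no activity coefficients
are available for the mixed conditions the package targets.

The thermal voltage is computed from the recording temperature
(`thermal_voltage(22)` → 25.43 mV), but every equation accepts an
explicit `rt_over_f` override. This matters in practice: published
analyses sometimes quote RT/F at the recording temperature while
computing Nernst predictions at 25 °C, and the override lets users
reproduce either choice exactly rather than having the package guess.

## Bi-ionic and two-ion permeability relations

For a bi-ionic condition (Ca²⁺ on one side, K⁺ on the other) the
Fatt–Ginsborg relation maps the reversal potential to a divalent /
monovalent permeability ratio:

$$\frac{P_{Ca}}{P_K} = \frac{[K^+]}{4\,[Ca^{2+}]}\;e^{x}\,(e^{x}+1),
  \qquad x = \frac{E_{rev}F}{RT}.$$

Transcriptions of this equation in the literature sometimes carry
typographical bracket errors; the form above is the standard one and is
the only self-consistent reading — it yields the fixed point
P_Ca/P_K = 1/2 at E_rev = 0 for equimolar solutions, which any correct
variant must satisfy. The inverse map `erev_for_fg_ratio()` solves the
quadratic in $y = e^x$ ($y^2 + y - 4r[Ca]/[K] = 0$) in closed form; the
round trip is exact to 10⁻⁹ relative tolerance and is asserted as a
property test.

For a pure KCl gradient, the two-ion GHK voltage equation is solved for
$r = P_{Cl}/P_K$:

$$E_{rev} = \frac{RT}{F}\ln
  \frac{[K]_{trans} + r\,[K]_{cis}}{[K]_{cis} + r\,[K]_{trans}}
  \;\Longrightarrow\;
  r = \frac{[K]_{trans} - q\,[K]_{cis}}{q\,[K]_{trans} - [K]_{cis}},
  \quad q = e^{E_{rev}F/RT}.$$

The solution is exact at both limits ($r = 0$ at the K⁺ Nernst
potential, $r = 1$ at zero) and a reversal potential outside the
interval bounded by the two Nernst potentials is a domain error rather
than a clamped value, because no non-negative permeability ratio exists
there. The closed form is verified against a bracketed root search in
the test suite, keeping the implementation and its oracle independent.

## The synthetic recording generator

The generator states a world with the statistical structure the analysis
assumes, nothing more:

* **Gating** is a continuous-time two-state Markov chain. Open and
  closed dwells are exponential with means $1/k_{close}$ and
  $1/k_{open}$; the initial state is stationary. Defaults
  $k_{open} = k_{close} = 50\,\mathrm{s^{-1}}$ give 20 ms mean dwells —
  long relative to the ~0.42 ms rise time of an 800 Hz analysis filter,
  so dead-time censoring is a small, calculable correction. Real gating
  kinetics of the pores this package targets are not published; these
  rates are conventions, recorded in trace metadata, not estimates.
* **Open-channel current** is ohmic, $i = \gamma(V - E_{rev})$, with an
  optional one-sided saturating variant
  $i = \gamma d/(1 + d/V_{1/2})$ for driving force $d > 0$ — the
  simplest form reproducing saturation seen only at large positive
  potentials. Sub-conductance states are excluded: the analysis targets
  a single main open level.
* **Noise** is white Gaussian at the sampling rate, then band-limited by
  the acquisition chain. The default pre-filter SD (0.15 pA) equals
  roughly 10% of the open amplitude at +80 mV for an 18.4 pS pore.
* **Acquisition chain**: 100 kHz digitization behind a 10 kHz 4-pole
  Bessel anti-alias filter, then an 800 Hz (−3 dB) digital analysis
  filter. Both filters are true 4-pole Bessel designs obtained by
  bilinear transform (with frequency prewarping) of the
  magnitude-normalized analog prototype, applied forward-only to match
  analog causality. The −3 dB point is verified by sine probe within
  ±0.5 dB, and the white-noise variance reduction against the filter's
  impulse-response energy within 10%.

What the generator deliberately omits: capacitance transients, baseline
drift, 1/f noise, multi-channel superposition, and sub-conductance
levels. A green recovery test therefore establishes that the estimator
chain is unbiased and precise *under the stated model*, not that it is
robust to every artifact of a real rig; level estimation will, for
example, happily report a drifting baseline as channel activity.

## Idealization

Level estimation automates what is traditionally done with cursors: an
all-points amplitude histogram (Freedman–Diaconis bin width; the IQR is
taken on a 10× decimated copy for traces above 10⁶ samples, where it is
statistically indistinguishable) is fitted with a two-component Gaussian
mixture by EM, initialized at the two most separated smoothed histogram
modes. The mixture means then seed a hard-assignment refinement — all
samples are split at the midpoint and per-side means/SDs taken — which
is exact for noiseless levels and has negligible truncation bias
whenever the separation exceeds the 3×-pooled-SD detectability bound
(below which the trace is declared channel-free).

Event detection is a half-amplitude threshold: crossings of the level
midpoint toggle the state, and any excursion shorter than the dead time
is merged into the enclosing event by a single sequential pass. The
default dead time is the conventional bandwidth-limited resolution
$0.3321/f_c$ (≈0.42 ms at 800 Hz). Events tile the analyzed interval
exactly and strictly alternate, which the tests assert as invariants.

Per-event amplitudes exclude a settle margin of one filter rise time
after each transition (when the event is at least three margins long),
mimicking cursor placement away from edges; the single-channel amplitude
is the duration-weighted open mean minus the duration-weighted closed
mean, making it translation-invariant and antisymmetric under trace
negation. On production-scale synthetic recordings this chain recovers
the generating amplitude to well under 1%.

## I/V fitting and selectivity

Amplitudes measured per (voltage, replicate) are fitted per replicate by
ordinary least squares over the points with |V| above an exclusion
half-window (default 20 mV — near zero driving force the open-channel
signal drowns in noise and amplitudes are unmeasurable, so the reversal
potential is necessarily an extrapolation; the fitted x-intercept
formalizes that). Replicates are aggregated as mean ± SD, matching the
way bilayer studies report n = 3–4 independent experiments. Event-count
weighting of replicates is exposed as data (each I/V point carries its
event count) but not imposed.

Junction potentials enter once, as a fixed offset on the voltage axis
(`corrected = command − junction`), which shifts the fitted E_rev
one-for-one and leaves the slope untouched; commutativity of correcting
and fitting is a property test. Computing the offset itself (e.g. by the
Henderson equation) is out of scope — it is an input.

Saturation detection extrapolates a reference line fitted on the
low-driving-force window (|V − E_rev| ≤ 50 mV) and flags a limb when
observed far-window amplitudes fall more than 15% below the line. Since
the window selection itself depends on E_rev — which a saturating limb
biases — the reference is iterated (select window → refit → re-derive
E_rev) until the selected set is stable, capped at 10 iterations. Both
thresholds are configurable; the defaults reproduce the qualitative
one-sided saturation pattern the generator's hyperbolic variant
produces.

## Permeation accounting

A crossing is counted by a two-plane hysteresis rule: an ion last seen
below the lower slab plane must next be seen above the upper plane (or
vice versa). Excursions into the slab that retreat count zero, so the
rule cannot double-count; no minimum residence time is required.
Trajectories are unwrapped first (frame-to-frame jumps larger than half
the box are treated as periodic images), and with a box length the slab
repeats periodically, so detection is invariant to adding whole box
lengths to any suffix of a trajectory — asserted as a property test.

Conductance is net charge over voltage×time,
$G = \sum_i z_i e\, d_i / (V t)$, so anions moving against cations add
constructively. Species contributions are reported both as |charge
flux| fractions (the default statistic) and as unsigned event-count
fractions; for monovalent-only mixtures the two coincide, and reporting
both sidesteps the ambiguity in how a "~12% anion contribution" might
be normalized.

The Poisson generator inverts the conductance bookkeeping: species $s$
with conductance share $w_s$ crosses at rate
$\lambda_s = w_s G |V| / (|z_s| e)$, all events carrying the
current-consistent direction. `conductance_from_crossings()` applied to
its output is therefore an exactly unbiased estimator of the target —
verified over 200 windows per condition at 4 and 15 pS, 100 and
350 mV. At MD-realistic scales (a 15 pS pore at 100 mV passes ~9.4 ions
per microsecond) single-window estimates scatter by >30%, which is why
published MD conductances from microsecond simulations carry large
uncertainties; the generator reproduces exactly this behaviour. It does
not model back-crossings, correlated transport, or the lag phase before
a pore becomes conductive.

## Numerical choices and degenerate inputs

* Filter design: the delay-normalized Bessel polynomial roots are
  rescaled to the numerically located −3 dB frequency (bisection to
  10⁻¹²), so the passband edge is exact by construction; coefficients
  are normalized to unit DC gain, and the filter is seeded with
  steady-state initial conditions at the first sample, so constant
  traces pass through unchanged.
* EM degeneracy (a vanishing component) falls back to the raw histogram
  mode pair; a unimodal trace raises a typed "no channel" condition
  rather than returning nonsense levels.
* A recording that never crosses threshold yields a single event; an
  event table without open events raises a typed "no amplitude"
  condition; an I/V set entirely inside the exclusion window raises
  "insufficient range". All such signals are classed conditions
  (`ionpore_*`), so pipelines can distinguish them from crashes.
* All randomness flows through explicit integer seeds; generators
  restore the caller's RNG state, and identical configurations produce
  byte-identical reports.

## Scaling of the test suite

Unit and property tests run on short recordings (2–10 s) to keep the
suite fast; the acceptance tests run the full production protocol — four
replicates of 60 s at ±40/60/80 mV, 100 kHz — exactly as a bilayer
experiment would be analyzed, and take a couple of minutes. The
parameter-recovery property (mean conductance within 5%, E_rev within
1.5 mV) is exercised at reduced duration in the unit suite and at full
scale in the acceptance suite.
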