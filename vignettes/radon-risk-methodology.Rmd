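---
title: "Methodology: occupancy-conditioned radon dose estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: occupancy-conditioned radon dose estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonrisk)
```

## The dose model and its assumptions

Radon exposure is the time integral of activity concentration,
$E = \int c(t)\,dt$ in Bq·m⁻³·h. A dose coefficient converts exposure to
effective dose. Two published conventions coexist and differ in what they
apply to:

* the **EEC** convention applies to equilibrium-equivalent exposure: the gas
  exposure must first be multiplied by the equilibrium factor $F$ (the
  progeny-to-gas activity ratio; 0.4 is the standard indoor assumption).
  The UNSCEAR population value is 9 nSv per Bq·m⁻³·h (EEC).
* the **GAS** convention applies to gas exposure directly, with $F$ already
  embedded. The ICRP-137-derived building/mine value is
  $6.7 \times 10^{-9}$ Sv per Bq·m⁻³·h, obtained from the PAEC coefficient
  of $3 \times 10^{-3}$ Sv per mJ·h·m⁻³ via the conversion constant
  $5.56 \times 10^{-6}$ mJ·m⁻³ per Bq·m⁻³ (EEC) and $F = 0.4$
  (`gas_coefficient_from_paec()`).

Note that the two conventions are *numerically inconsistent* with each
other: $0.4 \times 9 = 3.6$ nSv per gas Bq·m⁻³·h versus 6.7 nSv, a factor
of about 1.86. This discrepancy exists between the underlying published
values (epidemiological versus dosimetric derivations) and is deliberately
not reconciled here. The package default is the EEC convention
(9 nSv, $F = 0.4$), because the annual-dose reference and the four-level
indicator are defined with it; the GAS convention is available by
configuration and reproduces the classic employee-dose worked example
(250,000 Bq·m⁻³·h → 1.7 mSv). The `basis` field on `dose_coefficient()`
makes composing the two (applying $F$ twice) impossible by construction.

The annualized dose estimate from an annual mean concentration and a daily
average occupation (DAO) is

$$\mathrm{IAED} = \mathrm{AAMRC} \times F \times 365 \times \mathrm{DAO}
  \times 9\,\mathrm{nSv\,(Bq\,m^{-3}\,h)^{-1}},$$

with $\mathrm{AAO} = 365 \times \mathrm{DAO}$ annual occupied hours. The
reference point 40 Bq·m⁻³ at 7000 h/year (80% occupancy) gives 1.0 mSv.

## Classification boundaries

The four-level indicator is referenced to ICRP dose limits: 1 mSv/y
(public), 5 mSv/y (public, special situations), 20 mSv/y (occupational).
The stated band definitions pin the outer boundaries — green is "less than
or equal to" 1 mSv/y, red "above" 20 mSv/y — but leave exactly 5 and
exactly 20 ambiguous. We place both in the orange band:
$(-\infty,1],\,(1,5),\,[5,20],\,(20,\infty)$. At 5 mSv/y this is the more
protective choice (higher band); at 20 mSv/y a dose *at* the occupational
limit has not exceeded it, so it stays orange. The classifier is monotone
and partitions the non-negative reals; both properties are tested on dense
grids crossing every threshold.

## Windowed aggregation and its numerical choices

Detector readings are treated as **interval averages reported at the
interval start**: the series is piecewise constant, holding each value from
its timestamp to the next reading (left-hold). The final reading is held
for one trailing gap equal to the last inter-reading interval (zero for a
single-reading series) — a deterministic rule that avoids guessing a
detector cadence. Readings flagged `missing` contribute gaps.

The primary statistic is the **time-weighted mean** of this step function
restricted to the (masked) window, not the sample mean of readings — the
two differ under irregular sampling. `summary_stats()` additionally offers
the sample-based AM/SD and GM/GSD (the natural log-scale summaries for
log-normal radon data) for comparability with surveys that report either
convention; GM/GSD are reported as undefined when a zero concentration is
present.

All intervals are half-open $[start, end)$; timestamps are local wall-clock
civil times carried in a fixed offset. No daylight-saving arithmetic is
performed — a documented limitation, appropriate because occupancy
schedules are civil-time objects.

Four windows look back from the assessment instant: RT (1 h), VST (24 h),
ST (7 d), LT (≥ 90 d, default 90, configurable upward). RT is deliberately
**not** occupancy-conditioned: the real-time mean drives mitigation
(ventilation), which is meaningful whether or not anyone is present, and it
carries no risk level. For conditioned windows, DAO = occupied hours in the
window / days spanned; the window dose (IED) uses occupied hours at the
window mean; the annual estimate extrapolates the window's conditions to a
full year and is classified.

Two degenerate conditions are distinguished and reported, never raised as
errors: *no occupancy* (the schedule contributes zero time to the window)
and *no data* (the detector contributes zero time to a non-empty mask).
Windows whose data coverage of occupied time falls below a configurable
minimum (default 50%) are flagged low-confidence but still reported: a flag
preserves information without inventing imputation.

## Occupancy schedules

A schedule is a recurring weekly pattern of half-open occupied intervals
plus dated exceptions (holiday = unoccupied; special event = occupied, whole
day unless an interval is given). Intervals crossing midnight are split at
midnight with the tail attached to the following weekday; the split is
visible in mask output (a 22:00–02:00 night shift yields two intervals
totalling 4 h), which keeps mask intervals within calendar days and makes
the total-duration invariant trivial to audit.

The JSON dialect is deliberately single and schema-checked
(`{"weekly": [{"day": "Mon", "start": "09:00", "end": "17:00"}], "exceptions":
[{"date": "2021-12-25", "occupied": false}]}`); unknown fields are rejected
by name. Run configuration files are JSON for the same reason.

## The abacus

`build_abacus()` evaluates the annual dose over a concentration × occupancy
lattice (defaults 0–1270 Bq·m⁻³ × 0–24 h, the reference chart's stated
range; steps 10 Bq·m⁻³ × 0.25 h, chosen for smooth colour bands at trivial
cost). Cells reuse `iaed_from_dao()` directly, so grid and formula cannot
drift. `boundary_dao()` inverts the formula analytically,
$\mathrm{DAO} = \tau / (c \cdot F \cdot 365 \cdot k)$, clipping to the
24-hour day with an `unreachable` flag — at 10 Bq·m⁻³ even continuous
occupancy yields only 0.315 mSv/y, so no boundary exists. `abacus_lookup()`
re-evaluates exactly rather than interpolating: the chart is a
visualization, not the computation. Colour hex codes (green `#2ca02c`,
yellow `#ffd700`, orange `#ff8c00`, red `#d62728`) are fixed for
reproducible figures.

## What the synthetic generator emulates — and what it does not

Indoor radon concentrations are empirically log-normal, summarized by
geometric mean and geometric standard deviation. `generate_series()` draws

$$\ln c_t = \ln\mathrm{GM} + A\sin(2\pi\,\mathrm{hour}/24 + \phi_d)
          + B\sin(2\pi\,\mathrm{day}/365 + \phi_s) + \varepsilon,\quad
  \varepsilon \sim N(0, \ln\mathrm{GSD}),$$

with amplitudes expressed as fractions of the log-mean and phases defaulting
to a ~03:00 diurnal peak and a mid-January seasonal peak (concentrations
build up at night and in winter when buildings are closed — which is also
why the three-month measurement convention targets winter). Amplitude
defaults are 0 so that distributional tests see pure log-normality. The
generator is seeded and restores the caller's RNG stream.

It does **not** emulate autocorrelated noise (draws are independent given
the deterministic modulation), pressure-driven transients, detector response
lag, or calibration drift. A green test against synthetic fixtures
therefore establishes the correctness of the aggregation arithmetic under
the stated distributional model, not robustness to real-sensor artefacts.

Occupancy presets encode the standard annual conventions: `office` is
weekdays 09:00–17:00 (2088 h in a 261-weekday year, the ~2000 h workplace
convention); `dwelling` is every day 00:00–08:00 plus 13:00–24:00 — 19 h/day,
6935 h/year, the ~7000 h living-area convention, chosen as a simple daily
pattern rather than an unverifiable weekday/weekend split; `continuous` is
24/7.

Scenario expectations are frozen from closed-form arithmetic, not from
running the pipeline: e.g. `mitigation_drop` (600 Bq·m⁻³ for 60 days, then
30 after remediation, continuous occupancy) has a long-term mean of
(60·600 + 30·30)/90 = 410 Bq·m⁻³ → 12.9 mSv/y (orange), while recent
windows at 30 Bq·m⁻³ → 0.95 mSv/y (green).

## Survey margin of error

For communicating survey-based results the package includes the
normal-approximation half-width with finite-population correction,
$z\sqrt{p(1-p)/n}\,\sqrt{(N-n)/(N-1)}$; $z$ is computed from the normal
quantile function for any confidence level (1.959964… at 95%), not
hard-coded. 873 responses from a population of 6 million give 3.32%, i.e.
3% at whole-percent precision.

## Reporting precision and units

All internal dose arithmetic is in Sv at full precision; mSv appears only at
the reporting and classification boundary (thresholds are converted once).
Human-facing reports echo doses at 2 significant figures, mirroring standard
practice; the machine-readable JSON report carries full precision plus the
complete resolved configuration, so every number in it is reproducible from
the report alone.

## Known limitations

* No daylight-saving or time-zone arithmetic; timestamps are civil
  wall-clock instants.
* The left-hold interpolation is exact for interval-averaging detectors but
  biased for instantaneous samplers with long gaps.
* The annual estimate is an extrapolation ("if these conditions held for a
  year"); short windows with atypical occupancy can legitimately swing it.
* Epidemiological modelling beyond ERR = RR − 1 is out of scope, as are
  mitigation hardware control and geological radon-potential mapping.
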