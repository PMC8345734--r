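# radonrisk

Occupancy-conditioned indoor radon dose estimation and four-level risk
classification.

## The problem

Radon (Rn-222) is a radioactive noble gas that accumulates indoors and is
the dominant natural source of ionizing-radiation exposure. Continuous
IoT detectors now produce dense concentration time series, but concentration
alone does not tell a building manager how much dose occupants actually
receive: that depends on *when the space is occupied*. `radonrisk` is for
building managers, occupational-health practitioners and environmental-health
researchers who need to turn a raw concentration series plus an occupancy
schedule into defensible dose estimates and a communicable risk level.

## The model

Radon exposure is the time integral of concentration (Bq·m⁻³·h). Effective
dose applies a dose coefficient; the package carries the coefficient's
*basis* in its type so the equilibrium factor F (progeny-to-gas ratio,
0.4 indoors) can never be applied twice:

- **EEC basis** (UNSCEAR population convention): dose = exposure × F ×
  9 nSv/(Bq·m⁻³·h)
- **GAS basis** (ICRP-137-derived workplace convention): dose = exposure ×
  6.7×10⁻⁹ Sv/(Bq·m⁻³·h), F already embedded

The annualized dose estimate from a mean concentration (AAMRC) and a daily
average occupation (DAO, h/day) is

    IAED (mSv/y) = AAMRC × F × 365 × DAO × 9 nSv·(Bq·m⁻³·h)⁻¹

and is classified on the IRREI scale referenced to ICRP dose limits:
**1 green** (≤ 1 mSv/y, public limit), **2 yellow** (1–5 mSv/y),
**3 orange** (5–20 mSv/y, up to the occupational limit), **4 red**
(> 20 mSv/y).

The assessment pipeline evaluates four look-back windows: **RT** (last hour,
not occupancy-conditioned — it drives mitigation such as ventilation),
**VST** (last 24 h), **ST** (last week) and **LT** (at least the last
90 days), each occupancy-conditioned window yielding AMRC, occupied hours,
DAO, window dose (IED), annualized dose (IAED) and risk level.

## Worked example

```r
library(radonrisk)

# constant 300 Bq/m^3 with 8 h/day occupancy, 91 days of readings
sc <- scenario("worked_example_yellow")
assess(sc$series, sc$schedule, sc$config)
#> <irrei_assessment> as of 2021-04-05T00:00:00
#>   RT  : mean 300 Bq/m^3 (last hour, all time)
#>   VST : AMRC 300 Bq/m^3, DAO 8.0 h, IED 0.0086 mSv, annual 3.2 mSv/y -> IRREI 2 (yellow)
#>   ST  : AMRC 300 Bq/m^3, DAO 8.0 h, IED 0.06 mSv, annual 3.2 mSv/y -> IRREI 2 (yellow)
#>   LT  : AMRC 300 Bq/m^3, DAO 8.0 h, IED 0.78 mSv, annual 3.2 mSv/y -> IRREI 2 (yellow)
```

Every conditioned window sees a mean of 300 Bq·m⁻³ over 8 occupied hours per
day; annualized that is 300 × 0.4 × 365 × 8 × 9×10⁻⁹ × 1000 = 3.15 mSv/y,
which falls in the 1–5 mSv/y band: level 2, yellow. The classic
employee-dose arithmetic is equally direct:

```r
exposure <- cumulative_exposure(c(500, 1000), c(300, 100))  # 250000 Bq.m-3.h
cfg <- dose_model_config(coefficient = dose_coefficient(6.7e-9, "GAS"))
signif(effective_dose(exposure, cfg), 2)                    # 0.0017 Sv = 1.7 mSv
```

The reference abacus (dose over a concentration × occupancy lattice, with
colour bands and threshold boundary curves):

```r
ab <- build_abacus()                 # 0-1270 Bq/m^3 x 0-24 h
abacus_lookup(ab, 300, 8)            # $iaed 3.1536, $level 2, $color "yellow"
export_abacus(ab, "abacus.csv", "csv")
export_abacus(ab, "abacus.png", "figure")
```

A command-line front end is installed at
`system.file("cli", "radonrisk.R", package = "radonrisk")` with `assess`,
`simulate` and `abacus` subcommands.

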