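# Closed-form dose and risk arithmetic: exposure integrals, effective dose,
# annualized dose (IAED), four-level classification, ERR/RR, and conversion
# between progeny-based (PAEC) and gas-based dose coefficients.

# mJ.m-3 of potential alpha energy per Bq.m-3 of equilibrium-equivalent radon
# concentration. Standard conversion constant; not configurable.
PAEC_PER_BQ_EEC <- 5.56e-6

IRREI_COLORS <- c("green", "yellow", "orange", "red")

#' Dose coefficient with an explicit exposure basis
#'
#' A radon dose coefficient converts cumulative exposure (Bq m^-3 h) to
#' effective dose (Sv). Published coefficients come in two conventions and
#' they must never be mixed:
#'
#' * `"EEC"`: the coefficient applies to *equilibrium-equivalent* exposure;
#'   the gas exposure must first be multiplied by the equilibrium factor F.
#'   The UNSCEAR population value is 9 nSv per Bq m^-3 h (EEC).
#' * `"GAS"`: the coefficient applies to gas exposure directly; an
#'   equilibrium factor is already embedded and must NOT be applied again.
#'   The ICRP-137-derived workplace value is 6.7e-9 Sv per Bq m^-3 h.
#'
#' Carrying the basis in the object makes double application of F impossible
#' by construction.
#'
#' @param value Dose per unit exposure, Sv per Bq m^-3 h. Must be positive.
#' @param basis `"EEC"` or `"GAS"`.
#' @return An object of class `dose_coefficient`.
#' @examples
#' dose_coefficient(9e-9, "EEC")
#' dose_coefficient(6.7e-9, "GAS")
#' @export
dose_coefficient <- function(value, basis = c("EEC", "GAS")) {
  basis <- match.arg(basis)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop("dose coefficient `value` must be a single positive number (Sv per Bq m^-3 h)",
         call. = FALSE)
  structure(list(value = as.numeric(value), basis = basis),
            class = "dose_coefficient")
}

#' @export
print.dose_coefficient <- function(x, ...) {
  cat(sprintf("<dose_coefficient> %.3g Sv per Bq m^-3 h (%s basis)\n",
              x$value, x$basis))
  invisible(x)
}

#' Dosimetric configuration for radon risk assessment
#'
#' Bundles the conventions that turn a radon exposure into an annual dose and
#' a risk level: the equilibrium factor F between radon gas and its progeny,
#' the dose coefficient (with its basis, see [dose_coefficient()]), the
#' annualization constants, and the classification thresholds.
#'
#' The defaults reproduce the UNSCEAR reference calculation
#' 40 Bq m^-3 x 0.4 x 7000 h x 9 nSv = 1.0 mSv: F = 0.4, EEC coefficient
#' 9 nSv per Bq m^-3 h, 365 days/year, thresholds 1 / 5 / 20 mSv per year.
#'
#' @param equilibrium_factor F, dimensionless, in (0, 1]. 0.4 is the standard
#'   indoor assumption.
#' @param coefficient A [dose_coefficient()].
#' @param days_per_year Days used when annualizing a daily occupancy.
#' @param hours_per_year_full Hours in a full year (cap on annual occupancy).
#' @param thresholds_mSv Strictly increasing positive triple: the
#'   green/yellow, yellow/orange and orange/red annual-dose boundaries in mSv.
#' @param min_coverage Windows whose data coverage of occupied time falls
#'   below this fraction are flagged low-confidence by [assess()].
#' @return An object of class `dose_model_config`.
#' @examples
#' cfg <- dose_model_config()
#' iaed_from_aao(40, 7000, cfg)  # 1.0 mSv at 2 s.f.
#' @export
dose_model_config <- function(equilibrium_factor = 0.4,
                              coefficient = dose_coefficient(9e-9, "EEC"),
                              days_per_year = 365,
                              hours_per_year_full = 8760,
                              thresholds_mSv = c(1, 5, 20),
                              min_coverage = 0.5) {
  if (!is.numeric(equilibrium_factor) || length(equilibrium_factor) != 1L ||
      equilibrium_factor <= 0 || equilibrium_factor > 1)
    stop("`equilibrium_factor` must be in (0, 1]", call. = FALSE)
  if (!inherits(coefficient, "dose_coefficient"))
    stop("`coefficient` must be a dose_coefficient()", call. = FALSE)
  if (length(thresholds_mSv) != 3L || any(!is.finite(thresholds_mSv)) ||
      any(thresholds_mSv <= 0) || any(diff(thresholds_mSv) <= 0))
    stop("`thresholds_mSv` must be a strictly increasing positive triple",
         call. = FALSE)
  if (!is.numeric(min_coverage) || min_coverage < 0 || min_coverage > 1)
    stop("`min_coverage` must be in [0, 1]", call. = FALSE)
  structure(list(
    equilibrium_factor = as.numeric(equilibrium_factor),
    coefficient = coefficient,
    days_per_year = as.numeric(days_per_year),
    hours_per_year_full = as.numeric(hours_per_year_full),
    thresholds_mSv = as.numeric(thresholds_mSv),
    min_coverage = as.numeric(min_coverage)
  ), class = "dose_model_config")
}

#' @export
print.dose_model_config <- function(x, ...) {
  cat("<dose_model_config>\n")
  cat(sprintf("  equilibrium factor F : %g\n", x$equilibrium_factor))
  cat(sprintf("  coefficient          : %.3g Sv per Bq m^-3 h (%s basis)\n",
              x$coefficient$value, x$coefficient$basis))
  cat(sprintf("  annualization        : %g days, %g h full year\n",
              x$days_per_year, x$hours_per_year_full))
  cat(sprintf("  thresholds (mSv/y)   : %s\n",
              paste(x$thresholds_mSv, collapse = " / ")))
  invisible(x)
}

#' Cumulative radon gas exposure
#'
#' Exposure is the time integral of concentration: each segment contributes
#' concentration x duration, and the total is their sum, in Bq m^-3 h.
#'
#' @param concentration Numeric vector of radon activity concentrations,
#'   Bq m^-3, all non-negative.
#' @param duration_h Numeric vector of exposure durations in hours, same
#'   length, all non-negative.
#' @return Total exposure in Bq m^-3 h (0 for empty input).
#' @examples
#' cumulative_exposure(c(500, 1000), c(300, 100))  # 250000
#' @export
cumulative_exposure <- function(concentration, duration_h) {
  if (length(concentration) != length(duration_h))
    stop("`concentration` and `duration_h` must have equal length", call. = FALSE)
  if (length(concentration) == 0L) return(0)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(duration_h)) || any(duration_h < 0))
    stop("all durations must be finite and >= 0", call. = FALSE)
  sum(as.numeric(concentration) * as.numeric(duration_h))
}

#' Effective dose from cumulative exposure
#'
#' Applies the configured dose coefficient. Under a `"GAS"`-basis coefficient
#' the dose is `exposure * value`; under `"EEC"` the gas exposure is first
#' converted to equilibrium-equivalent exposure, giving
#' `exposure * F * value`. Linear in exposure.
#'
#' @param exposure Gas exposure in Bq m^-3 h, >= 0.
#' @param config A [dose_model_config()].
#' @return Effective dose in Sv.
#' @examples
#' cfg_gas <- dose_model_config(coefficient = dose_coefficient(6.7e-9, "GAS"))
#' effective_dose(250000, cfg_gas)  # 0.0017 Sv at 2 s.f.
#' @export
effective_dose <- function(exposure, config = dose_model_config()) {
  stopifnot(inherits(config, "dose_model_config"))
  if (any(!is.finite(exposure)) || any(exposure < 0))
    stop("`exposure` must be finite and >= 0", call. = FALSE)
  f <- switch(config$coefficient$basis,
              GAS = 1,
              EEC = config$equilibrium_factor)
  exposure * f * config$coefficient$value
}

#' Indoor annual effective dose from annual occupancy hours
#'
#' The annual-dose reference form: mean concentration times equilibrium
#' factor times annual occupied hours times the dose coefficient, reported
#' in mSv per year. With the defaults,
#' `iaed_from_aao(40, 7000)` reproduces the 1.0 mSv reference value.
#'
#' @param aamrc Annual arithmetic mean radon concentration, Bq m^-3, >= 0.
#' @param aao_hours Annual average occupancy in hours, within
#'   `[0, hours_per_year_full]`.
#' @param config A [dose_model_config()].
#' @return Dose in mSv per year. Vectorized over `aamrc` and `aao_hours`.
#' @export
iaed_from_aao <- function(aamrc, aao_hours, config = dose_model_config()) {
  stopifnot(inherits(config, "dose_model_config"))
  if (any(!is.finite(aamrc)) || any(aamrc < 0))
    stop("`aamrc` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(aao_hours)) || any(aao_hours < 0) ||
      any(aao_hours > config$hours_per_year_full))
    stop(sprintf("`aao_hours` must lie in [0, %g]", config$hours_per_year_full),
         call. = FALSE)
  1e3 * effective_dose(aamrc * aao_hours, config)
}

#' Indoor annual effective dose from daily average occupation
#'
#' The abacus form: annual occupancy is `days_per_year * dao`, so
#' `iaed_from_dao(c, d)` equals `iaed_from_aao(c, 365 * d)` with the default
#' calendar. Linear in both arguments.
#'
#' @param aamrc Annual arithmetic mean radon concentration, Bq m^-3, >= 0.
#' @param dao Daily average occupation, hours per day, within `[0, 24]`.
#' @param config A [dose_model_config()].
#' @return Dose in mSv per year. Vectorized.
#' @examples
#' iaed_from_dao(300, 8)  # 3.154 mSv -> level 2 (yellow)
#' @export
iaed_from_dao <- function(aamrc, dao, config = dose_model_config()) {
  stopifnot(inherits(config, "dose_model_config"))
  if (any(!is.finite(dao)) || any(dao < 0) || any(dao > 24))
    stop("`dao` must lie in [0, 24] hours per day", call. = FALSE)
  iaed_from_aao(aamrc, config$days_per_year * dao, config)
}

#' Classify an annual dose on the four-level risk scale
#'
#' Maps an annual effective dose onto the integer scale 1-4 with the colour
#' code green / yellow / orange / red. With the default thresholds
#' (1, 5, 20 mSv per year) the bands are: level 1 for dose <= 1; level 2 for
#' dose in (1, 5); level 3 for dose in \[5, 20\]; level 4 for dose > 20.
#' Exactly 5 falls in the orange band and exactly 20 stays orange (the
#' boundary doses sit in the occupational band, not above it); 1 is green
#' ("less than or equal to" the public limit). The map is monotone and
#' partitions the non-negative reals.
#'
#' @param iaed Annual effective dose(s), mSv per year, >= 0.
#' @param config A [dose_model_config()] (supplies the thresholds).
#' @return An `irrei_level` object: integer vector of levels with colours
#'   attached; `level()` and `risk_color()` extract the pieces.
#' @examples
#' classify_irrei(c(0.5, 3.154, 10, 25))
#' @export
classify_irrei <- function(iaed, config = dose_model_config()) {
  stopifnot(inherits(config, "dose_model_config"))
  if (any(!is.finite(iaed)) || any(iaed < 0))
    stop("`iaed` must be finite and >= 0 (mSv per year)", call. = FALSE)
  tau <- config$thresholds_mSv
  lev <- ifelse(iaed <= tau[1], 1L,
         ifelse(iaed <  tau[2], 2L,
         ifelse(iaed <= tau[3], 3L, 4L)))
  irrei_level(as.integer(lev))
}

#' Construct a risk-level object
#'
#' @param level Integer vector with values in 1:4.
#' @return An `irrei_level` vector; colours follow the fixed bijection
#'   1 = green, 2 = yellow, 3 = orange, 4 = red.
#' @export
irrei_level <- function(level) {
  level <- as.integer(level)
  if (any(is.na(level) | level < 1L | level > 4L))
    stop("`level` must be an integer in 1..4", call. = FALSE)
  structure(level, class = "irrei_level")
}

#' @export
print.irrei_level <- function(x, ...) {
  cat(sprintf("IRREI %d (%s)\n", unclass(x), risk_color(x)), sep = "")
  invisible(x)
}

#' @export
`[.irrei_level` <- function(x, i) irrei_level(unclass(x)[i])

#' @rdname irrei_level
#' @param x An `irrei_level` object.
#' @export
level <- function(x) as.integer(unclass(x))

#' @rdname irrei_level
#' @export
risk_color <- function(x) IRREI_COLORS[as.integer(unclass(x))]

#' Excess relative risk from relative risk
#'
#' The epidemiological identity ERR = RR - 1: the amount by which the risk of
#' an exposed group exceeds that of an unexposed one, relative to the latter.
#'
#' @param rr Relative risk, dimensionless, >= 0.
#' @return Excess relative risk (may be negative for protective RR < 1).
#' @export
err_from_rr <- function(rr) {
  if (any(!is.finite(rr)) || any(rr < 0))
    stop("`rr` must be finite and >= 0", call. = FALSE)
  rr - 1
}

#' Convert a PAEC dose coefficient to a gas-basis coefficient
#'
#' ICRP dose coefficients are stated per unit potential-alpha-energy exposure
#' (Sv per mJ h m^-3). Converting to radon gas exposure requires the PAEC of
#' unit equilibrium-equivalent concentration (5.56e-6 mJ m^-3 per Bq m^-3
#' EEC) and the equilibrium factor F linking gas to progeny:
#' `value = paec_coeff * 5.56e-6 * f`. The ICRP-137 building/mine value of
#' 3e-3 Sv per mJ h m^-3 with F = 0.4 gives 6.7e-9 Sv per Bq m^-3 h
#' at 2 significant figures.
#'
#' @param paec_coeff Dose per unit PAEC exposure, Sv per mJ h m^-3, > 0.
#' @param f Equilibrium factor in (0, 1].
#' @return A `"GAS"`-basis [dose_coefficient()] (F is embedded; do not apply
#'   it again).
#' @export
gas_coefficient_from_paec <- function(paec_coeff, f) {
  if (!is.numeric(paec_coeff) || length(paec_coeff) != 1L ||
      !is.finite(paec_coeff) || paec_coeff <= 0)
    stop("`paec_coeff` must be a single positive number", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f > 1)
    stop("`f` must be in (0, 1]", call. = FALSE)
  dose_coefficient(paec_coeff * PAEC_PER_BQ_EEC * f, basis = "GAS")
}
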