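# The reference abacus: annual effective dose evaluated over a mean
# concentration x daily occupancy lattice, with the four colour bands and
# their analytic boundary curves. A reader overlays a window's measured
# (AMRC, DAO) point on the chart and reads off dose and risk level.

ABACUS_HEX <- c(green = "#2ca02c", yellow = "#ffd700",
                orange = "#ff8c00", red = "#d62728")

#' Build the dose abacus grid
#'
#' Evaluates the annual effective dose (via [iaed_from_dao()]) and the risk
#' level on every cell of an (AAMRC x DAO) lattice. The default axes span
#' 0-1270 Bq m^-3 by 0-24 h, the reference chart's range.
#'
#' @param aamrc_axis Ascending mean concentrations, Bq m^-3.
#' @param dao_axis Ascending daily occupations, hours in `[0, 24]`.
#' @param config A [dose_model_config()].
#' @return An `abacus_grid`: the axes, the `iaed` matrix (mSv per year,
#'   rows = aamrc, cols = dao), the `level` matrix, and the config.
#' @examples
#' ab <- build_abacus(seq(0, 1270, 10), seq(0, 24, 0.25))
#' abacus_lookup(ab, 300, 8)
#' @export
build_abacus <- function(aamrc_axis = seq(0, 1270, by = 10),
                         dao_axis = seq(0, 24, by = 0.25),
                         config = dose_model_config()) {
  stopifnot(inherits(config, "dose_model_config"))
  if (is.unsorted(aamrc_axis, strictly = TRUE) || any(aamrc_axis < 0))
    stop("`aamrc_axis` must be strictly ascending and >= 0", call. = FALSE)
  if (is.unsorted(dao_axis, strictly = TRUE) ||
      any(dao_axis < 0) || any(dao_axis > 24))
    stop("`dao_axis` must be strictly ascending within [0, 24]", call. = FALSE)
  iaed <- outer(aamrc_axis, dao_axis,
                function(c, d) iaed_from_dao(c, d, config))
  lev <- matrix(level(classify_irrei(as.vector(iaed), config)),
                nrow = length(aamrc_axis),
                dimnames = list(aamrc_axis, dao_axis))
  dimnames(iaed) <- dimnames(lev)
  structure(list(aamrc_axis = aamrc_axis, dao_axis = dao_axis,
                 iaed = iaed, level = lev, config = config),
            class = "abacus_grid")
}

#' @export
print.abacus_grid <- function(x, ...) {
  cat(sprintf("<abacus_grid> %d x %d cells, AAMRC %g-%g Bq/m^3, DAO %g-%g h\n",
              length(x$aamrc_axis), length(x$dao_axis),
              min(x$aamrc_axis), max(x$aamrc_axis),
              min(x$dao_axis), max(x$dao_axis)))
  invisible(x)
}

#' Daily occupation at which a dose threshold is reached
#'
#' Inverts the annual-dose formula in its occupancy argument: the DAO at
#' which a given mean concentration reaches a threshold dose,
#' `threshold / (aamrc * F * days_per_year * coefficient)`. Values beyond a
#' 24-hour day are clipped to 24 and flagged unreachable: at that
#' concentration the threshold cannot be crossed.
#'
#' @param aamrc Mean concentration(s), Bq m^-3, strictly positive.
#' @param threshold_mSv Annual dose threshold, mSv per year.
#' @param config A [dose_model_config()].
#' @return Numeric vector of DAO hours clipped to `[0, 24]`, with attribute
#'   `unreachable` (logical) marking clipped entries.
#' @examples
#' boundary_dao(100, 1)  # ~7.61 h
#' @export
boundary_dao <- function(aamrc, threshold_mSv, config = dose_model_config()) {
  if (any(!is.finite(aamrc)) || any(aamrc <= 0))
    stop("`aamrc` must be > 0: a zero concentration has no finite boundary",
         call. = FALSE)
  if (!is.numeric(threshold_mSv) || any(threshold_mSv <= 0))
    stop("`threshold_mSv` must be > 0", call. = FALSE)
  rate_per_hour <- iaed_from_dao(aamrc, 1, config)  # mSv/y per DAO hour
  dao <- threshold_mSv / rate_per_hour
  unreachable <- dao > 24
  structure(pmin(dao, 24), unreachable = unreachable)
}

#' Evaluate the abacus at an arbitrary point
#'
#' Re-evaluates the dose formula exactly at `(amrc, dao)` -- no
#' interpolation -- so on-lattice points match their grid cell to machine
#' precision and off-lattice points are exact too. The point must lie within
#' the grid's axis ranges.
#'
#' @param abacus An [build_abacus()] grid.
#' @param amrc Mean concentration, Bq m^-3.
#' @param dao Daily occupation, hours.
#' @return List with `iaed` (mSv per year), `level` (integer 1-4) and
#'   `color`.
#' @export
abacus_lookup <- function(abacus, amrc, dao) {
  stopifnot(inherits(abacus, "abacus_grid"))
  rng_c <- range(abacus$aamrc_axis); rng_d <- range(abacus$dao_axis)
  if (any(amrc < rng_c[1]) || any(amrc > rng_c[2]) ||
      any(dao < rng_d[1]) || any(dao > rng_d[2]))
    stop(sprintf(
      "point outside abacus range AAMRC [%g, %g] Bq/m^3 x DAO [%g, %g] h",
      rng_c[1], rng_c[2], rng_d[1], rng_d[2]), call. = FALSE)
  iaed <- iaed_from_dao(amrc, dao, abacus$config)
  lev <- classify_irrei(iaed, abacus$config)
  list(iaed = iaed, level = level(lev), color = risk_color(lev))
}

#' Export the abacus as CSV or figure
#'
#' CSV export writes the grid in long format (`aamrc`, `dao`, `iaed_mSv`,
#' `level`, `color`), one row per cell. Figure export draws the filled
#' colour bands with the labelled threshold boundary curves to a PNG.
#'
#' @param abacus An [build_abacus()] grid.
#' @param path Destination file.
#' @param format `"csv"` or `"figure"`.
#' @return `path`, invisibly.
#' @export
export_abacus <- function(abacus, path, format = c("csv", "figure")) {
  stopifnot(inherits(abacus, "abacus_grid"))
  format <- match.arg(format)
  if (format == "csv") {
    long <- expand.grid(aamrc = abacus$aamrc_axis, dao = abacus$dao_axis,
                        KEEP.OUT.ATTRS = FALSE)
    long$iaed_mSv <- as.vector(abacus$iaed)
    long$level <- as.vector(abacus$level)
    long$color <- IRREI_COLORS[long$level]
    ok <- tryCatch({
      utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed to write abacus CSV to ", path, ": ",
           conditionMessage(ok), call. = FALSE)
  } else {
    ok <- tryCatch({
      grDevices::png(path, width = 900, height = 700, res = 110)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot_abacus(abacus)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed to write abacus figure to ", path, ": ",
           conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Draw the abacus on the current graphics device
#'
#' @param abacus An [build_abacus()] grid.
#' @return Invisibly, the abacus.
#' @export
plot_abacus <- function(abacus) {
  stopifnot(inherits(abacus, "abacus_grid"))
  cfg <- abacus$config
  graphics::image(abacus$aamrc_axis, abacus$dao_axis, abacus$level,
                  col = unname(ABACUS_HEX), zlim = c(0.5, 4.5),
                  xlab = "Annual arithmetic mean radon concentration (Bq/m^3)",
                  ylab = "Daily average occupation (h)",
                  main = "Annual effective dose bands",
                  useRaster = TRUE)
  cs <- abacus$aamrc_axis[abacus$aamrc_axis > 0]
  for (i in seq_along(cfg$thresholds_mSv)) {
    tau <- cfg$thresholds_mSv[i]
    b <- boundary_dao(cs, tau, cfg)
    show <- !attr(b, "unreachable")
    if (any(show)) {
      graphics::lines(cs[show], b[show], lwd = 2)
      k <- which(show)[ceiling(sum(show) / 2)]
      graphics::text(cs[k], b[k], sprintf("%g mSv/y", tau), pos = 3, cex = 0.8)
    }
  }
  invisible(abacus)
}
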