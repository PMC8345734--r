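# Radon concentration time series from a continuous detector: construction,
# CSV ingestion, and the piecewise-constant (left-hold) view used by the
# time-weighted aggregations.

#' Construct a radon concentration series
#'
#' A time-ordered set of detector readings for one compartment. Readings are
#' interval averages reported at their interval start: the series is treated
#' as piecewise constant, holding each value from its timestamp until the
#' next reading (the final reading is held for one trailing inter-reading
#' gap). Readings flagged `"missing"` mark gaps: their time interval is
#' excluded from all aggregation.
#'
#' @param timestamp Reading instants (anything [as_instant()] accepts),
#'   strictly increasing after sorting; duplicates are rejected.
#' @param concentration Radon activity concentrations, Bq m^-3, non-negative
#'   wherever the flag is not `"missing"`.
#' @param quality_flag Optional per-reading flag, one of `"ok"`, `"suspect"`,
#'   `"missing"` (default `"ok"`).
#' @param compartment_id Opaque label for the monitored space.
#' @return An object of class `radon_series` (a data frame with attributes).
#' @export
radon_series <- function(timestamp, concentration, quality_flag = NULL,
                         compartment_id = "compartment") {
  ts <- as_instant(timestamp)
  conc <- as.numeric(concentration)
  n <- length(ts)
  if (n == 0L) stop("a radon series needs at least one reading", call. = FALSE)
  if (length(conc) != n) stop("timestamp/concentration length mismatch", call. = FALSE)
  if (is.null(quality_flag)) quality_flag <- rep("ok", n)
  quality_flag <- as.character(quality_flag)
  quality_flag[is.na(quality_flag) | quality_flag == ""] <- "ok"
  bad_flag <- !quality_flag %in% c("ok", "suspect", "missing")
  if (any(bad_flag))
    stop("invalid quality_flag at row(s) ",
         paste(utils::head(which(bad_flag), 3), collapse = ", "), call. = FALSE)
  ord <- order(ts)
  ts <- ts[ord]; conc <- conc[ord]; quality_flag <- quality_flag[ord]
  if (anyDuplicated(ts))
    stop("duplicate timestamps in series (first at row ",
         which(duplicated(ts))[1], " after sorting)", call. = FALSE)
  live <- quality_flag != "missing"
  bad <- live & (!is.finite(conc) | conc < 0)
  if (any(bad))
    stop("negative or non-finite concentration at row(s) ",
         paste(utils::head(which(bad), 3), collapse = ", "),
         " (after sorting)", call. = FALSE)
  if (!any(live))
    stop("series has no non-missing readings", call. = FALSE)
  out <- data.frame(timestamp = ts, concentration = conc,
                    quality_flag = quality_flag)
  structure(out, class = c("radon_series", "data.frame"),
            compartment_id = as.character(compartment_id))
}

#' @export
print.radon_series <- function(x, ...) {
  cat(sprintf("<radon_series> %d readings, compartment \"%s\", %s .. %s\n",
              nrow(x), attr(x, "compartment_id"),
              format_instant(x$timestamp[1]),
              format_instant(x$timestamp[nrow(x)])))
  NextMethod()
}

#' Read a radon series from CSV
#'
#' Expects a header with columns `timestamp` (ISO-8601) and `concentration`
#' (Bq m^-3), plus an optional `quality_flag`. Rows are sorted by time;
#' duplicate timestamps, unparseable timestamps and negative concentrations
#' are rejected with the offending row named.
#'
#' @param path CSV file path.
#' @param compartment_id Label for the series (default: file base name).
#' @return A [radon_series()].
#' @export
read_series <- function(path, compartment_id = NULL) {
  if (!file.exists(path)) stop("readings file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("timestamp", "concentration") %in% names(df)))
    stop("CSV must have columns `timestamp` and `concentration`: ", path,
         call. = FALSE)
  conc <- suppressWarnings(as.numeric(df$concentration))
  flag <- if ("quality_flag" %in% names(df)) df$quality_flag else NULL
  live <- if (is.null(flag)) rep(TRUE, nrow(df)) else flag != "missing"
  bad <- live & (is.na(conc) | conc < 0)
  if (any(bad))
    stop("invalid concentration in ", path, " at data row(s) ",
         paste(utils::head(which(bad), 3), collapse = ", "), call. = FALSE)
  radon_series(df$timestamp, conc, quality_flag = flag,
               compartment_id = compartment_id %||%
                 sub("\\.[^.]*$", "", basename(path)))
}

#' Write a radon series to CSV
#'
#' Inverse of [read_series()]: ISO-8601 timestamps, full-precision
#' concentrations, and the quality flag column.
#'
#' @param series A [radon_series()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "radon_series"))
  out <- data.frame(timestamp = format_instant(series$timestamp),
                    concentration = format(series$concentration, digits = 15,
                                           trim = TRUE, scientific = FALSE),
                    quality_flag = series$quality_flag)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Piecewise-constant observed segments of a series: data frame with numeric
# epoch columns start/end and the held concentration. Each reading is held
# until the next; the last is held for one trailing gap equal to the final
# inter-reading interval (zero for a single-reading series). Missing-flagged
# readings produce no segment (a gap).
series_segments <- function(series) {
  ts <- as.numeric(series$timestamp)
  n <- length(ts)
  tail_gap <- if (n >= 2L) ts[n] - ts[n - 1L] else 0
  starts <- ts
  ends <- c(ts[-1L], ts[n] + tail_gap)
  keep <- series$quality_flag != "missing" & ends > starts
  data.frame(start = starts[keep], end = ends[keep],
             concentration = series$concentration[keep])
}
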