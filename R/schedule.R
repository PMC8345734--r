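# Occupancy schedules (the building manager's "specific occupation period"):
# recurring weekly occupied intervals plus dated exceptions, expanded into
# concrete half-open occupied intervals on demand.

WEEKDAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

# "HH:MM" (or numeric hours) -> numeric hours in [0, 24]
parse_hm <- function(x) {
  if (is.numeric(x)) {
    h <- as.numeric(x)
  } else {
    m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad))
      stop("time of day must be \"HH:MM\": ", paste(x[bad], collapse = ", "),
           call. = FALSE)
    h <- vapply(m, function(p) as.numeric(p[2]) + as.numeric(p[3]) / 60, 1)
  }
  if (any(!is.finite(h)) || any(h < 0) || any(h > 24))
    stop("time of day must lie in [0, 24] hours", call. = FALSE)
  h
}

format_hm <- function(h) sprintf("%02d:%02d", floor(h), round((h - floor(h)) * 60))

# weekday name or 1..7 (Monday = 1) -> integer 1..7
parse_day <- function(x) {
  if (is.numeric(x)) {
    d <- as.integer(x)
  } else {
    d <- match(substr(as.character(x), 1, 3), WEEKDAY_NAMES)
  }
  if (any(is.na(d) | d < 1L | d > 7L))
    stop("weekday must be Mon..Sun or 1..7 (Monday = 1)", call. = FALSE)
  d
}

#' Parse a timestamp as a local wall-clock instant
#'
#' Accepts `POSIXct`, `Date`, or ISO-8601-like strings
#' (`"2021-01-04T09:00:00"`, with `"T"` or a space, seconds optional, or a
#' bare date). All instants in this package are civil wall-clock times
#' represented in a single fixed offset (no daylight-saving arithmetic);
#' building schedules are civil-time objects.
#'
#' @param x Vector to parse.
#' @return `POSIXct` vector (tz `"UTC"` as the fixed-offset carrier).
#' @export
as_instant <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), tz = "UTC",
                                                origin = "1970-01-01"))
  if (inherits(x, "Date")) return(as.POSIXct(format(x), tz = "UTC"))
  x <- as.character(x)
  x <- sub("T", " ", x, fixed = TRUE)
  out <- tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                              "%Y-%m-%d")),
    error = function(e) rep(as.POSIXct(NA), length(x)))
  if (any(is.na(out) & !is.na(x)))
    stop("unparseable timestamp(s): ",
         paste(utils::head(x[is.na(out)], 3), collapse = ", "), call. = FALSE)
  out
}

format_instant <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Build an occupancy schedule
#'
#' An occupancy schedule is the recurring weekly pattern of occupied
#' intervals, plus dated exceptions: a holiday (`occupied = FALSE`) removes
#' all occupancy on that date, a special event (`occupied = TRUE`) occupies
#' the given interval (whole day by default) instead of the weekly pattern.
#'
#' Intervals are half-open `[start, end)` in local wall-clock hours.
#' Intervals that cross midnight (`end <= start`, e.g. 22:00-02:00) are split
#' at midnight, with the tail attached to the following weekday. Overlapping
#' intervals within one weekday are rejected.
#'
#' @param weekly Data frame with columns `day` (Mon..Sun or 1..7), `start`,
#'   `end` (`"HH:MM"` or numeric hours). An empty data frame (or `NULL`)
#'   means never occupied by default.
#' @param exceptions Optional data frame with columns `date` (coercible to
#'   `Date`), `occupied` (logical), and optionally `start`, `end` for
#'   occupied exceptions (defaults: whole day).
#' @return An object of class `occupancy_schedule`.
#' @examples
#' office <- occupancy_schedule(data.frame(
#'   day = c("Mon", "Tue", "Wed", "Thu", "Fri"),
#'   start = "09:00", end = "17:00"))
#' occupied_hours(office, "2021-01-04", "2021-01-11")  # one work week: 40 h
#' @export
occupancy_schedule <- function(weekly = NULL, exceptions = NULL) {
  if (is.null(weekly) || NROW(weekly) == 0L) {
    weekly <- data.frame(day = integer(), start = numeric(), end = numeric())
  } else {
    weekly <- as.data.frame(weekly)
    if (!all(c("day", "start", "end") %in% names(weekly)))
      stop("`weekly` needs columns day, start, end", call. = FALSE)
    weekly <- data.frame(day = parse_day(weekly$day),
                         start = parse_hm(weekly$start),
                         end = parse_hm(weekly$end))
    if (any(weekly$start == weekly$end))
      stop("zero-length weekly interval (start == end)", call. = FALSE)
    cross <- weekly$end < weekly$start | weekly$end == 0
    if (any(cross)) {
      head_part <- weekly[cross, , drop = FALSE]
      tail_part <- head_part
      tail_part$day <- head_part$day %% 7L + 1L
      tail_part$start <- 0
      head_part$end <- 24
      tail_part <- tail_part[tail_part$end > 0, , drop = FALSE]
      weekly <- rbind(weekly[!cross, , drop = FALSE], head_part, tail_part)
    }
    weekly <- weekly[order(weekly$day, weekly$start), , drop = FALSE]
    rownames(weekly) <- NULL
    for (d in unique(weekly$day)) {
      iv <- weekly[weekly$day == d, , drop = FALSE]
      if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)]))
        stop("overlapping weekly intervals on ", WEEKDAY_NAMES[d], call. = FALSE)
    }
  }
  if (is.null(exceptions) || NROW(exceptions) == 0L) {
    exceptions <- data.frame(date = as.Date(character()), occupied = logical(),
                             start = numeric(), end = numeric())
  } else {
    exceptions <- as.data.frame(exceptions)
    if (!all(c("date", "occupied") %in% names(exceptions)))
      stop("`exceptions` needs columns date, occupied", call. = FALSE)
    exceptions <- data.frame(
      date = as.Date(exceptions$date),
      occupied = as.logical(exceptions$occupied),
      start = if ("start" %in% names(exceptions)) parse_hm(exceptions$start) else 0,
      end = if ("end" %in% names(exceptions)) parse_hm(exceptions$end) else 24)
    if (anyDuplicated(exceptions$date))
      stop("duplicate exception dates", call. = FALSE)
    if (any(exceptions$occupied & exceptions$end <= exceptions$start))
      stop("occupied exception must have end > start", call. = FALSE)
  }
  structure(list(weekly = weekly, exceptions = exceptions),
            class = "occupancy_schedule")
}

#' @export
print.occupancy_schedule <- function(x, ...) {
  cat("<occupancy_schedule>\n")
  if (nrow(x$weekly) == 0L) {
    cat("  weekly: never occupied\n")
  } else {
    for (i in seq_len(nrow(x$weekly)))
      cat(sprintf("  %s %s-%s\n", WEEKDAY_NAMES[x$weekly$day[i]],
                  format_hm(x$weekly$start[i]), format_hm(x$weekly$end[i])))
  }
  if (nrow(x$exceptions) > 0L)
    cat(sprintf("  exceptions: %d dated override(s)\n", nrow(x$exceptions)))
  invisible(x)
}

#' Occupied intervals of a schedule within a time range
#'
#' Expands the recurring pattern (with exceptions applied) into the concrete
#' occupied intervals intersecting `[t0, t1)`. The returned intervals are
#' disjoint, sorted and clipped to the range; their total length is the
#' occupied time.
#'
#' @param schedule An [occupancy_schedule()].
#' @param t0,t1 Range bounds (anything [as_instant()] accepts), `t0 < t1`.
#' @return Data frame with `POSIXct` columns `start`, `end` (half-open).
#' @export
occupancy_mask <- function(schedule, t0, t1) {
  stopifnot(inherits(schedule, "occupancy_schedule"))
  t0 <- as_instant(t0); t1 <- as_instant(t1)
  if (!(t0 < t1)) stop("`t0` must be earlier than `t1`", call. = FALSE)
  dates <- seq(as.Date(format(t0, tz = "UTC")),
               as.Date(format(t1, tz = "UTC")), by = "day")
  starts <- numeric(0); ends <- numeric(0)
  exc <- schedule$exceptions
  for (d in seq_along(dates)) {
    date <- dates[d]
    midnight <- as.numeric(as.POSIXct(format(date), tz = "UTC"))
    ei <- if (nrow(exc)) which(exc$date == date) else integer(0)
    if (length(ei)) {
      if (!exc$occupied[ei]) next
      s <- exc$start[ei]; e <- exc$end[ei]
    } else {
      wd <- as.integer(format(date, "%u"))
      iv <- schedule$weekly[schedule$weekly$day == wd, , drop = FALSE]
      if (nrow(iv) == 0L) next
      s <- iv$start; e <- iv$end
    }
    starts <- c(starts, midnight + s * 3600)
    ends <- c(ends, midnight + e * 3600)
  }
  starts <- pmax(starts, as.numeric(t0))
  ends <- pmin(ends, as.numeric(t1))
  keep <- ends > starts
  out <- data.frame(
    start = as.POSIXct(starts[keep], tz = "UTC", origin = "1970-01-01"),
    end = as.POSIXct(ends[keep], tz = "UTC", origin = "1970-01-01"))
  out[order(out$start), , drop = FALSE]
}

#' Occupied hours and daily average occupation over a range
#'
#' `occupied_hours()` sums the occupied interval lengths within `[t0, t1)`;
#' `daily_average_occupation()` divides by the number of days in the range,
#' giving the DAO in hours per day (in `[0, 24]`).
#'
#' @inheritParams occupancy_mask
#' @return Hours (scalar), or hours per day for
#'   `daily_average_occupation()`.
#' @export
occupied_hours <- function(schedule, t0, t1) {
  m <- occupancy_mask(schedule, t0, t1)
  if (nrow(m) == 0L) return(0)
  sum(as.numeric(m$end) - as.numeric(m$start)) / 3600
}

#' @rdname occupied_hours
#' @export
daily_average_occupation <- function(schedule, t0, t1) {
  t0 <- as_instant(t0); t1 <- as_instant(t1)
  days <- (as.numeric(t1) - as.numeric(t0)) / 86400
  occupied_hours(schedule, t0, t1) / days
}

#' Read or write an occupancy schedule as JSON
#'
#' The canonical dialect is
#' `{"weekly": [{"day": "Mon", "start": "09:00", "end": "17:00"}, ...],
#'   "exceptions": [{"date": "2021-12-25", "occupied": false}, ...]}`.
#' Unknown top-level fields are rejected so typos fail loudly.
#'
#' @param path File path.
#' @param schedule An [occupancy_schedule()].
#' @return `read_schedule()` returns an [occupancy_schedule()];
#'   `write_schedule()` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  extra <- setdiff(names(obj), c("weekly", "exceptions"))
  if (length(extra))
    stop("unknown schedule field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  occupancy_schedule(weekly = obj$weekly, exceptions = obj$exceptions)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "occupancy_schedule"))
  w <- schedule$weekly
  obj <- list(weekly = data.frame(day = WEEKDAY_NAMES[w$day],
                                  start = format_hm(w$start),
                                  end = format_hm(w$end)))
  if (nrow(schedule$exceptions) > 0L) {
    e <- schedule$exceptions
    obj$exceptions <- data.frame(date = format(e$date), occupied = e$occupied,
                                 start = format_hm(e$start),
                                 end = format_hm(e$end))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
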