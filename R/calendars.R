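# Calendars of time-dependent covariates ---------------------------------
#
# Three calendars drive the time-dependent covariates: wolf-killing policy
# (full protection vs liberalized killing), season (winter Oct-Mar vs summer
# Apr-Sep) and census-method era (1979-1994, 1995-2000, 2001-2012). Each is a
# set of ordered, contiguous, non-overlapping date segments carrying an
# integer level. Segment dates are inclusive on both ends; the spell-splitting
# convention in [split_spells()] turns them into half-open analysis intervals.

.study_start <- as.Date("1979-01-01")
.study_end <- as.Date("2012-04-14")

#' Study window covered by the default calendars
#'
#' @return Date vector of length 2 (first and last covered date).
#' @export
study_window <- function() c(.study_start, .study_end)

.make_cal <- function(name, starts, ends, levels) {
  data.frame(
    calendar = name,
    start_date = as.Date(starts),
    end_date = as.Date(ends),
    level = as.integer(levels),
    stringsAsFactors = FALSE
  )
}

#' Default wolf-killing policy calendar
#'
#' One initial full-protection segment (1979 through 2003-03-31) followed by
#' 11 alternating segments: six liberalized-killing periods (ESA downlisting
#' anchored at 2003-04-01, lethal-take sub-permit periods in 2005 and 2006,
#' and delisting periods in 2007, 2009 and 2012) interleaved with returns to
#' full protection, ending at the administrative close of the study on
#' 2012-04-14. Total liberalized durations are 670 days (downlisting),
#' 263 days (sub-permits) and 701 days (delisting). Interior dates of the
#' post-2003 periods are configuration, not code: edit the returned data frame
#' (or a CSV written with [write_calendars()]) to use other anchors.
#'
#' @return Calendar data frame with columns `calendar`, `start_date`,
#'   `end_date`, `level` (policy: 0 = full protection, 1 = liberalized).
#' @export
policy_calendar <- function() {
  starts <- c(
    "1979-01-01", # full protection under the ESA
    "2003-04-01", # downlisting to threatened (670 d)
    "2005-01-30",
    "2005-04-01", # sub-permits for take, 2005 (128 d)
    "2005-08-07",
    "2006-04-01", # sub-permits for take, 2006 (135 d)
    "2006-08-14",
    "2007-03-12", # delisting, 2007-2008 (567 d)
    "2008-09-29",
    "2009-05-04", # delisting, 2009 (56 d)
    "2009-06-29",
    "2012-01-28" # delisting, 2012 (78 d)
  )
  ends <- c(as.character(as.Date(starts[-1]) - 1), "2012-04-14")
  .make_cal("policy", starts, ends, rep(c(0L, 1L), 6))
}

#' Default season calendar
#'
#' Winter spans October through March (level 1), summer April through
#' September (level 0), clipped to the study window.
#'
#' @return Calendar data frame (see [policy_calendar()]).
#' @export
season_calendar <- function() {
  # boundaries: every Apr 1 and Oct 1 inside the window
  years <- 1979:2012
  bounds <- sort(as.Date(c(
    paste0(years, "-04-01"),
    paste0(years, "-10-01")
  )))
  bounds <- bounds[bounds > .study_start & bounds <= .study_end]
  starts <- c(.study_start, bounds)
  ends <- c(bounds - 1, .study_end)
  keep <- starts <= ends
  starts <- starts[keep]
  ends <- ends[keep]
  lev <- as.integer(format(starts, "%m") %in% c("10", "11", "12", "01", "02", "03"))
  .make_cal("season", starts, ends, lev)
}

#' Default census-method calendar
#'
#' Three census-method eras: 1979-1994 (level 1), 1995-2000 (level 2) and
#' 2001-2012 (level 3). By default the covariate is time-dependent, splitting
#' histories at 1995-01-01 and 2001-01-01; [split_spells()] also offers an
#' endpoint-year assignment (one level per animal).
#'
#' @return Calendar data frame (see [policy_calendar()]).
#' @export
census_calendar <- function() {
  .make_cal(
    "census",
    c("1979-01-01", "1995-01-01", "2001-01-01"),
    c("1994-12-31", "2000-12-31", "2012-04-14"),
    1:3
  )
}

#' Default calendar set
#'
#' @return A single data frame stacking [policy_calendar()],
#'   [season_calendar()] and [census_calendar()], validated.
#' @export
default_calendars <- function() {
  cal <- rbind(policy_calendar(), season_calendar(), census_calendar())
  validate_calendars(cal)
  cal
}

#' Validate a calendar set
#'
#' Checks that each named calendar has ordered, non-overlapping, contiguous
#' segments covering a common window, with levels in the allowed range for the
#' known calendar names.
#'
#' @param calendars Calendar data frame (columns `calendar`, `start_date`,
#'   `end_date`, `level`).
#' @return Invisibly, the calendar data frame. Errors on violation.
#' @export
validate_calendars <- function(calendars) {
  need <- c("calendar", "start_date", "end_date", "level")
  if (!all(need %in% names(calendars))) {
    .cr_stop("calendar table must have columns calendar, start_date, end_date, level",
      class = "wolfcr_calendar_error"
    )
  }
  for (nm in unique(calendars$calendar)) {
    seg <- calendars[calendars$calendar == nm, ]
    seg <- seg[order(seg$start_date), ]
    if (any(seg$end_date < seg$start_date)) {
      .cr_stop(sprintf("calendar '%s': segment with end before start", nm),
        class = "wolfcr_calendar_error"
      )
    }
    if (nrow(seg) > 1) {
      gaps <- as.integer(seg$start_date[-1]) - as.integer(seg$end_date[-nrow(seg)])
      if (any(gaps != 1)) {
        .cr_stop(sprintf("calendar '%s': segments not contiguous", nm),
          class = "wolfcr_calendar_error"
        )
      }
    }
  }
  invisible(calendars)
}

# coverage window common to all calendars in the set
.cal_window <- function(calendars) {
  by_cal <- split(calendars, calendars$calendar)
  lo <- max(as.Date(vapply(by_cal, function(s) min(s$start_date), numeric(1)),
    origin = "1970-01-01"
  ))
  hi <- min(as.Date(vapply(by_cal, function(s) max(s$end_date), numeric(1)),
    origin = "1970-01-01"
  ))
  c(lo, hi)
}

#' Look up calendar levels on given dates
#'
#' @param calendars Calendar data frame.
#' @param name Calendar name (`"policy"`, `"season"` or `"census"`).
#' @param dates Date vector.
#' @return Integer vector of levels; errors if a date is uncovered.
#' @export
calendar_level <- function(calendars, name, dates) {
  seg <- calendars[calendars$calendar == name, ]
  if (nrow(seg) == 0L) {
    .cr_stop(sprintf("no calendar named '%s'", name), class = "wolfcr_calendar_error")
  }
  seg <- seg[order(seg$start_date), ]
  idx <- findInterval(as.integer(as.Date(dates)), as.integer(seg$start_date))
  bad <- idx < 1L | as.Date(dates) > seg$end_date[pmax(idx, 1L)]
  if (any(bad)) {
    .cr_stop(sprintf("date(s) outside coverage of calendar '%s'", name),
      class = "wolfcr_coverage_error"
    )
  }
  seg$level[idx]
}

#' Read and write calendar CSV files
#'
#' Calendar CSVs carry columns `calendar`, `start_date`, `end_date`, `level`,
#' dates in ISO 8601 (YYYY-MM-DD).
#'
#' @param path Path to a CSV file.
#' @return `read_calendars()` returns a validated calendar data frame.
#' @export
read_calendars <- function(path) {
  cal <- read.csv(path, stringsAsFactors = FALSE)
  cal$start_date <- as.Date(cal$start_date)
  cal$end_date <- as.Date(cal$end_date)
  cal$level <- as.integer(cal$level)
  validate_calendars(cal)
  cal
}

#' @rdname read_calendars
#' @param calendars Calendar data frame to write.
#' @export
write_calendars <- function(calendars, path) {
  out <- calendars
  out$start_date <- format(out$start_date, "%Y-%m-%d")
  out$end_date <- format(out$end_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
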