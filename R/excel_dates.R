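# Excel 1900-system serial date arithmetic.
#
# Spreadsheets store dates internally as integer serials counting days from
# the 1900 epoch (serial 1 = 1 Jan 1900).  The 1900 system inherits a
# deliberate Lotus 1-2-3 bug: serial 60 is the phantom 29 Feb 1900, a date
# that does not exist in the Gregorian calendar.  Consequently serials >= 61
# are offset by one relative to the true day count.  Gene symbols that get
# autoconverted to dates surface as these five-digit serials when a date
# cell is later reformatted as number or text.

.XLSX_SERIAL_MAX <- 2958465L # 31 Dec 9999

#' Convert an Excel 1900-system serial number to a calendar date
#'
#' Serial 1 maps to 1900-01-01. Serial 60 is the phantom 29 Feb 1900 created
#' by the Lotus 1-2-3 leap-year bug; it corresponds to no real date and is
#' rejected. For serials >= 61 the mapping is `as.Date("1899-12-30") +
#' serial`; for serials <= 59 it is `as.Date("1899-12-31") + serial`.
#'
#' @param serial integer vector of serial numbers, each in
#'   `[1, 2958465]` and not equal to 60.
#' @param system date system; only `"1900"` is implemented. `"1904"`
#'   (legacy Mac Excel) is accepted as a flag but not supported.
#' @return a `Date` vector.
#' @examples
#' excel_serial_to_date(1)      # 1900-01-01
#' excel_serial_to_date(43709)  # 2019-09-01
#' @export
excel_serial_to_date <- function(serial, system = c("1900", "1904")) {
  system <- match.arg(system)
  if (system == "1904") {
    stop("the 1904 date system is not implemented; only 1900 is supported")
  }
  serial <- as.numeric(serial)
  if (any(!is.finite(serial) | serial != floor(serial))) {
    stop("invalid serial: serials must be whole numbers (time-of-day ",
         "fractions are out of scope)")
  }
  bad <- serial < 1 | serial > .XLSX_SERIAL_MAX
  if (any(bad)) {
    stop("invalid serial: ", paste(serial[bad][1]),
         " is outside [1, ", .XLSX_SERIAL_MAX, "]")
  }
  if (any(serial == 60)) {
    stop("invalid serial: 60 is the phantom 29 Feb 1900 and maps to no ",
         "real calendar date")
  }
  epoch_hi <- as.Date("1899-12-30") # compensates for the phantom leap day
  epoch_lo <- as.Date("1899-12-31")
  out <- as.Date(ifelse(serial >= 61, epoch_hi + serial, epoch_lo + serial),
                 origin = "1970-01-01")
  out
}

#' Convert a calendar date to its Excel 1900-system serial number
#'
#' Inverse of [excel_serial_to_date()]: `date_to_serial(serial_to_date(s))
#' == s` for every valid serial.
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts), each
#'   element between 1900-01-01 and 9999-12-31.
#' @return integer vector of serials.
#' @examples
#' excel_date_to_serial(as.Date("1900-01-01")) # 1
#' excel_date_to_serial(as.Date("2019-09-01")) # 43709
#' @export
excel_date_to_serial <- function(date) {
  date <- as.Date(date)
  if (any(is.na(date))) stop("out-of-range: undecodable date")
  lo <- as.Date("1900-01-01")
  hi <- as.Date("9999-12-31")
  if (any(date < lo | date > hi)) {
    stop("out-of-range: dates must lie in [1900-01-01, 9999-12-31]")
  }
  cut <- as.Date("1900-03-01")
  serial <- ifelse(date >= cut,
                   as.integer(date - as.Date("1899-12-30")),
                   as.integer(date - as.Date("1899-12-31")))
  as.integer(serial)
}

#' Date-parsing dialect configuration
#'
#' Controls how ambiguous display dates are interpreted.
#'
#' @param day_first for slash dates like `3/1/2016`: `FALSE` (default)
#'   reads month/day/year, `TRUE` reads day/month/year. When the first two
#'   fields are both <= 12, the alternative parse is recorded in the result
#'   (`$alt`) either way, so downstream reporting is not misled.
#' @param year_pivot two-digit years `00`..`(pivot-1)` expand to 2000s,
#'   `pivot`..`99` to 1900s. Default 30 (so "Jan-41" is January 1941).
#' @return a list with class `"date_dialect"`.
#' @export
date_dialect <- function(day_first = FALSE, year_pivot = 30L) {
  stopifnot(year_pivot >= 0, year_pivot <= 100)
  structure(list(day_first = isTRUE(day_first),
                 year_pivot = as.integer(year_pivot)),
            class = "date_dialect")
}

.expand_yy <- function(yy, pivot) {
  ifelse(yy < pivot, 2000L + yy, 1900L + yy)
}

# English month tokens used when *parsing* rendered display dates.
# (Locale tables matter when simulating conversion of gene names; the dates
# a scanner meets in files are rendered with English month abbreviations.)
.parse_month_tokens <- local({
  tok <- c(stats::setNames(1:12, tolower(month.abb)),
           stats::setNames(1:12, tolower(month.name)),
           sept = 9L)
  tok[order(-nchar(names(tok)))]
})

.match_month_token <- function(x) {
  i <- match(tolower(x), names(.parse_month_tokens))
  unname(.parse_month_tokens[i])
}

#' Parse a display-format date string
#'
#' Recognizes the date renderings that spreadsheet autoconversion produces
#' in gene columns: `d-mmm` ("3-Mar"), `mmm-d` ("Mar-3", "Mar-03"),
#' `mmm-yy` ("Jan-41"), slash dates ("3/1/2016", "5/1", field order set by
#' `dialect`), and ISO dates ("2016-03-01"). Anything else returns `NULL`.
#'
#' @param text a single trimmed cell string.
#' @param dialect a [date_dialect()].
#' @return `NULL`, or a list of class `"display_date"` with elements
#'   `day`, `month`, `year` (each possibly `NA`), `source_format` (one of
#'   `d-mmm`, `mmm-d`, `mmm-yy`, `slash`, `iso`) and `alt` (the alternative
#'   day/month reading of an ambiguous slash date, or `NULL`).
#' @examples
#' parse_display_date("3-Mar")   # day 3, month 3
#' parse_display_date("Jan-41")  # month 1, year 1941
#' parse_display_date("TP53")    # NULL
#' @export
parse_display_date <- function(text, dialect = date_dialect()) {
  stopifnot(length(text) == 1L)
  x <- trimws(text)
  if (!nzchar(x)) return(NULL)

  dd <- function(day = NA_integer_, month, year = NA_integer_, fmt,
                 alt = NULL) {
    structure(list(day = as.integer(day), month = as.integer(month),
                   year = as.integer(year), source_format = fmt, alt = alt),
              class = "display_date")
  }

  # iso: yyyy-mm-dd
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{1,2})-([0-9]{1,2})$", x))[[1]]
  if (length(m)) {
    y <- as.integer(m[2]); mo <- as.integer(m[3]); d <- as.integer(m[4])
    if (mo >= 1 && mo <= 12 && d >= 1 && d <= 31)
      return(dd(d, mo, y, "iso"))
    return(NULL)
  }

  # slash: a/b[/y]
  m <- regmatches(x, regexec(
    "^([0-9]{1,2})/([0-9]{1,2})(/([0-9]{2}|[0-9]{4}))?$", x))[[1]]
  if (length(m)) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    y <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
    if (!is.na(y) && y < 100) y <- .expand_yy(y, dialect$year_pivot)
    first_day <- dialect$day_first
    d <- if (first_day) a else b
    mo <- if (first_day) b else a
    # fall back to the only consistent reading when the preferred one is
    # impossible (e.g. 25/3 under month-first)
    if ((mo < 1 || mo > 12) && b >= 1 && b <= 12 && a <= 31) {
      d <- a; mo <- b; first_day <- TRUE
    } else if ((mo < 1 || mo > 12 || d > 31) && a >= 1 && a <= 12 && b <= 31) {
      d <- b; mo <- a; first_day <- FALSE
    }
    if (mo < 1 || mo > 12 || d < 1 || d > 31) return(NULL)
    alt <- NULL
    if (a <= 12 && b <= 12 && a != b) {
      alt <- list(day = mo, month = d) # the other field order
    }
    return(dd(d, mo, y, "slash", alt))
  }

  # d-mmm: "3-Mar"
  m <- regmatches(x, regexec("^([0-9]{1,2})-([A-Za-z]+)$", x))[[1]]
  if (length(m)) {
    mo <- .match_month_token(m[3])
    d <- as.integer(m[2])
    if (!is.na(mo) && d >= 1 && d <= 31) return(dd(d, mo, fmt = "d-mmm"))
    return(NULL)
  }

  # mmm-d ("Mar-3", "Mar-03") or mmm-yy ("Jan-41", "Mar-2016")
  m <- regmatches(x, regexec("^([A-Za-z]+)-([0-9]{1,4})$", x))[[1]]
  if (length(m)) {
    mo <- .match_month_token(m[2])
    if (is.na(mo)) return(NULL)
    n <- as.integer(m[3])
    nd <- nchar(m[3])
    if (nd >= 3) {
      if (nd == 4) return(dd(month = mo, year = n, fmt = "mmm-yy"))
      return(NULL)
    }
    if (n >= 1 && n <= 31)
      return(dd(n, mo, fmt = "mmm-d"))
    # 0 or 32..99: a two-digit year
    return(dd(month = mo, year = .expand_yy(n, dialect$year_pivot),
              fmt = "mmm-yy"))
  }

  NULL
}

#' Is an integer token a plausible spreadsheet date serial?
#'
#' The screen treats five-digit numbers found in gene columns as likely
#' internal-date-format errors. The default window accepts any five-digit
#' value (10000--99999); pass a narrower window to restrict to recent
#' decades.
#'
#' @param serial integer vector.
#' @param window length-2 numeric, inclusive bounds.
#' @return logical vector.
#' @examples
#' is_candidate_serial(43709) # TRUE
#' is_candidate_serial(9999)  # FALSE: not five digits
#' @export
is_candidate_serial <- function(serial, window = c(10000L, 99999L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  s <- suppressWarnings(as.numeric(serial))
  !is.na(s) & s == floor(s) & s >= window[1] & s <= window[2] & s != 60
}
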