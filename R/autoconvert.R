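# Deterministic simulation of spreadsheet autoconversion.
#
# The simulator models the text-file-open import path: each cell string is
# tested, in order, against (1) the month-token + number rule that turns
# gene names like SEPT7 or MARCH3 into dates, (2) explicit display-date
# strings (3/1/2016, 3-Mar, 2016-03-01) which are dates already, and
# (3) the scientific-notation rule that turns RIKEN-style identifiers like
# 2310009E13 into floating-point numbers.  Everything else passes through
# unchanged.  Month tables are locale-specific: an Excel running in Dutch
# also recognizes "mei", so MEI1 becomes May-01 there.

#' Construct a month table
#'
#' @param locale locale tag, e.g. `"english"`.
#' @param tokens named integer vector: month-name token (case-insensitive)
#'   -> month number 1..12. Tokens must be unique within the table.
#' @param render how this locale renders a converted day-date:
#'   `"d-mmm"` gives "7-Sep" (English default), `"mmm-dd"` gives "Sep-07"
#'   (observed for the non-English locale conversions AGO2 -> Aug-02 and
#'   MEI1 -> May-01). Two-digit years always render as mmm-yy ("Jan-41").
#' @return an object of class `"month_table"`.
#' @export
month_table <- function(locale, tokens, render = c("d-mmm", "mmm-dd")) {
  render <- match.arg(render)
  if (is.null(names(tokens)) || any(!nzchar(names(tokens)))) {
    stop("tokens must be a named vector")
  }
  nm <- tolower(names(tokens))
  if (anyDuplicated(nm)) {
    # identical duplicates (e.g. "may" as both full name and abbreviation)
    # collapse; conflicting mappings are an error
    first <- !duplicated(nm)
    if (any(tokens != tokens[match(nm, nm)])) {
      stop("month tokens must map to a unique month within a table")
    }
    tokens <- tokens[first]
    nm <- nm[first]
    names(tokens) <- nm
  }
  if (any(tokens < 1 | tokens > 12)) stop("month numbers must be 1..12")
  tok <- stats::setNames(as.integer(tokens), nm)
  tok <- tok[order(-nchar(nm))] # longest-token-first matching
  structure(list(locale = locale, tokens = tok, render = render),
            class = "month_table")
}

#' Bundled month tables
#'
#' The English table carries full month names, the 3-letter abbreviations
#' and the extra token "sept". The locale tables carry the tokens evidenced
#' to cause conversions in published supplementary files: Italian / Spanish
#' / Portuguese "ago(sto)" (August), Dutch "mei" (May), Finnish
#' "tammi(kuu)" (January).
#'
#' @param locales which tables to return, a subset of
#'   `c("english", "it_es_pt", "dutch", "finnish")`.
#' @return a list of [month_table()] objects.
#' @export
month_tables <- function(locales = "english") {
  all <- list(
    english = month_table("english",
      c(stats::setNames(1:12, tolower(month.name)),
        stats::setNames(1:12, tolower(month.abb)),
        sept = 9L),
      render = "d-mmm"),
    it_es_pt = month_table("it_es_pt",
      c(ago = 8L, agosto = 8L), render = "mmm-dd"),
    dutch = month_table("dutch",
      c(mei = 5L), render = "mmm-dd"),
    # "tamm" included: spreadsheets accept unambiguous month-name
    # prefixes, which is how TAMM41 becomes Jan-41
    finnish = month_table("finnish",
      c(tamm = 1L, tammi = 1L, tammikuu = 1L), render = "mmm-dd")
  )
  bad <- setdiff(locales, names(all))
  if (length(bad)) stop("unknown locale table(s): ", paste(bad, collapse = ", "))
  all[locales]
}

.SEPARATORS <- "[-/. ]?"

.render_date <- function(day, month, render) {
  if (render == "mmm-dd") sprintf("%s-%02d", month.abb[month], day)
  else sprintf("%d-%s", day, month.abb[month])
}

.render_year <- function(month, year) {
  sprintf("%s-%02d", month.abb[month], year %% 100L)
}

.conversion_result <- function(input, outcome, display = input,
                               day = NA_integer_, month = NA_integer_,
                               year = NA_integer_, value = NA_real_,
                               locale = NA_character_) {
  structure(list(input = input, outcome = outcome, display = display,
                 day = as.integer(day), month = as.integer(month),
                 year = as.integer(year), value = value, locale = locale),
            class = "conversion_result")
}

#' @export
print.conversion_result <- function(x, ...) {
  cat(sprintf("\"%s\" -> %s%s\n", x$input, x$outcome,
              if (x$outcome == "unchanged") "" else paste0(" \"", x$display, "\"")))
  invisible(x)
}

# try the month-token + number rule against one table; NULL if no match
.match_month_rule <- function(x, table, dialect) {
  for (tok in names(table$tokens)) {
    mo <- table$tokens[[tok]]
    # month token then number: SEPT7, TAMM41, jun-1, MARCH.3
    pat <- paste0("^", tok, .SEPARATORS, "([0-9]{1,3})$")
    m <- regmatches(x, regexec(pat, x, ignore.case = TRUE))[[1]]
    if (!length(m)) {
      # number then month token: 1-MAR
      pat <- paste0("^([0-9]{1,3})", .SEPARATORS, tok, "$")
      m <- regmatches(x, regexec(pat, x, ignore.case = TRUE))[[1]]
    }
    if (length(m)) {
      n <- as.integer(m[2])
      if (n >= 1 && n <= 31) {
        return(.conversion_result(x, "date",
                                  .render_date(n, mo, table$render),
                                  day = n, month = mo,
                                  locale = table$locale))
      }
      if (n >= 32 && n <= 99) {
        y <- .expand_yy(n, dialect$year_pivot)
        return(.conversion_result(x, "date", .render_year(mo, y),
                                  month = mo, year = y,
                                  locale = table$locale))
      }
      # n = 0 or >= 100: not a plausible day or two-digit year
    }
  }
  NULL
}

#' Simulate spreadsheet autoconversion of one cell string
#'
#' Applies, in order: the month-token + number rule (a month token,
#' optionally separated by "-", "/", ".", or a space from an integer n:
#' n in 1..31 becomes a day-of-month date, n in 32..99 a two-digit-year
#' date; number-then-token likewise), recognition of explicit display-date
#' strings, and the scientific rule (digits E digits becomes a float).
#' Strings matching none of these are returned unchanged.
#'
#' Tables are tried in the order given; with overlapping tokens the first
#' matching table wins and a message notes the tie.
#'
#' @param text one non-empty cell string.
#' @param tables list of [month_table()]s, e.g. [month_tables()].
#' @param dialect a [date_dialect()] (controls two-digit-year expansion).
#' @return a `conversion_result`: list with `outcome` (one of `unchanged`,
#'   `date`, `scientific`, `numeric`), `display` (the rendered string; for
#'   `unchanged` it equals the input), and the parsed `day`/`month`/`year`
#'   or numeric `value`.
#' @examples
#' simulate_autoconversion("SEPT7")$display   # "7-Sep"
#' simulate_autoconversion("TP53")$outcome    # "unchanged"
#' simulate_autoconversion("2310009E13")$value # 2.310009e19
#' @export
simulate_autoconversion <- function(text, tables = month_tables(),
                                    dialect = date_dialect()) {
  stopifnot(length(text) == 1L)
  x <- trimws(text)
  if (!nzchar(x)) stop("text must be non-empty after trimming")
  if (inherits(tables, "month_table")) tables <- list(tables)

  hits <- Filter(Negate(is.null),
                 lapply(tables, .match_month_rule, x = x, dialect = dialect))
  if (length(hits) > 1L) {
    message("simulate_autoconversion: \"", x, "\" matches ",
            length(hits), " month tables; first wins (",
            hits[[1]]$locale, ")")
  }
  if (length(hits)) return(hits[[1]])

  # explicit date strings (already dates; spreadsheets retype these too)
  pd <- parse_display_date(x, dialect)
  if (!is.null(pd)) {
    disp <- if (!is.na(pd$day) && !is.na(pd$month)) {
      .render_date(pd$day, pd$month, "d-mmm")
    } else {
      .render_year(pd$month, pd$year)
    }
    return(.conversion_result(x, "date", disp, day = pd$day,
                              month = pd$month, year = pd$year))
  }

  # scientific: digits [.] E digits, e.g. RIKEN clone ids 2310009E13
  if (grepl("^[0-9]+(\\.[0-9]+)?[Ee][0-9]+$", x)) {
    v <- as.numeric(sub("[Ee]", "e", x))
    return(.conversion_result(x, "scientific",
                              display = sprintf("%.2E", v), value = v))
  }

  .conversion_result(x, "unchanged")
}

#' Screen a gene-name catalogue for autoconversion-vulnerable symbols
#'
#' Runs [simulate_autoconversion()] over every name and returns the subset
#' that would be converted, in input order. When `taxon` labels are given,
#' per-taxon conversion counts are attached as the `"taxon_counts"`
#' attribute (the screen run per annotation catalogue, counting date
#' conversions per taxon).
#'
#' @param names character vector of gene names.
#' @param tables list of [month_table()]s.
#' @param taxon optional character vector, one label per name.
#' @param dialect a [date_dialect()].
#' @return data.frame with columns `name`, `taxon` (if given), `outcome`,
#'   `display`, `day`, `month`, `year`; one row per converted name.
#' @export
screen_gene_list <- function(names, tables = month_tables(), taxon = NULL,
                             dialect = date_dialect()) {
  if (!length(names)) stop("names must be non-empty")
  if (!is.null(taxon)) stopifnot(length(taxon) == length(names))
  res <- lapply(names, simulate_autoconversion, tables = tables,
                dialect = dialect)
  conv <- vapply(res, function(r) r$outcome != "unchanged", logical(1))
  out <- data.frame(
    name = names[conv],
    outcome = vapply(res[conv], `[[`, character(1), "outcome"),
    display = vapply(res[conv], `[[`, character(1), "display"),
    day = vapply(res[conv], `[[`, integer(1), "day"),
    month = vapply(res[conv], `[[`, integer(1), "month"),
    year = vapply(res[conv], `[[`, integer(1), "year"),
    stringsAsFactors = FALSE)
  if (!is.null(taxon)) {
    out <- cbind(taxon = taxon[conv], out)
    attr(out, "taxon_counts") <- table(taxon[conv])
  }
  out
}

#' Evaluate a month-minus-number protein name as date arithmetic
#'
#' Some spreadsheets evaluate names like "jun-1" as the first day of the
#' month minus the number of days: "jun-1" becomes May-31. Matches the
#' pattern month-token "-" integer; anything else returns `NULL`.
#'
#' @param text one string.
#' @param tables list of [month_table()]s supplying the tokens.
#' @param year reference year used to resolve month lengths ("mar-1" is
#'   Feb-28 in a common year, Feb-29 in a leap year). Default 2001, a
#'   common year; purely a convention, documented rather than inferred.
#' @return `NULL`, or a list with `day`, `month`, `year` and `display`
#'   (mmm-dd, e.g. "May-31").
#' @examples
#' evaluate_name_arithmetic("jun-1")$display # "May-31"
#' @export
evaluate_name_arithmetic <- function(text, tables = month_tables(),
                                     year = 2001L) {
  stopifnot(length(text) == 1L)
  x <- trimws(text)
  if (inherits(tables, "month_table")) tables <- list(tables)
  for (tb in tables) {
    for (tok in names(tb$tokens)) {
      pat <- paste0("^", tok, "-([0-9]+)$")
      m <- regmatches(x, regexec(pat, x, ignore.case = TRUE))[[1]]
      if (length(m)) {
        n <- as.integer(m[2])
        d0 <- as.Date(sprintf("%04d-%02d-01", year, tb$tokens[[tok]]))
        d <- d0 - n
        lt <- as.POSIXlt(d)
        return(list(day = lt$mday, month = lt$mon + 1L,
                    year = lt$year + 1900L,
                    display = sprintf("%s-%02d", month.abb[lt$mon + 1L],
                                      lt$mday)))
      }
    }
  }
  NULL
}
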