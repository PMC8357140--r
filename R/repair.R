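# Reverse-mapping flagged cells back to candidate gene symbols.
#
# A flagged "1-Mar" decodes to day 1 of March; every month token that maps
# to March is recombined with the day (padded and unpadded, concatenated
# and hyphenated) and the results are filtered against the dictionary, so
# fabrications never survive. Repairs are suggestions written to a side
# report -- files are never modified in place, because silent modification
# is the root problem being audited.

# candidate strings for (month, n) where n is a day or two-digit year
.candidate_strings <- function(month, n, tables) {
  toks <- unlist(lapply(tables, function(tb) {
    names(tb$tokens)[tb$tokens == month]
  }), use.names = FALSE)
  if (!length(toks)) return(character(0))
  variants <- unique(c(sprintf("%d", n), sprintf("%02d", n)))
  out <- c(outer(toupper(toks), variants, paste0),          # SEPT7, AGO02
           outer(toupper(toks), variants,
                 function(a, b) paste0(a, "-", b)))          # JUN-1
  unique(as.character(out))
}

#' Candidate symbols for one flagged cell
#'
#' Decodes the record to a month plus day or two-digit year (five-digit
#' serials are first decoded through [excel_serial_to_date()]), generates
#' token + number candidate strings over every month table, and keeps the
#' ones present in the dictionary, most-specific (unpadded, concatenated)
#' first. When the dictionary carries a rename table, modernized symbols
#' (e.g. SEPT1 -> SEPTIN1) are appended after their vulnerable originals.
#'
#' @param record one flagged cell: a one-row slice of a `scan_report`'s
#'   `records` data.frame, or any list with `error_class` and the decoded
#'   `day`/`month`/`year`/`serial` fields.
#' @param dict a [gene_dictionary()].
#' @param tables list of [month_table()]s to draw tokens from.
#' @return character vector of candidate symbols (possibly empty; an
#'   undecodable record yields `character(0)`, never an error).
#' @examples
#' d <- gene_dictionary("MARCH1", renames = c(MARCH1 = "MARCHF1"))
#' rec <- classify_cell("1-Mar")
#' candidates_for(rec, d) # "MARCH1" "MARCHF1"
#' @export
candidates_for <- function(record, dict, tables = month_tables()) {
  stopifnot(inherits(dict, "gene_dictionary"))
  if (inherits(tables, "month_table")) tables <- list(tables)
  if (is.data.frame(record)) record <- as.list(record[1, ])

  month <- record$month
  day <- record$day
  year <- record$year
  if (identical(record$error_class, "five-digit-serial") &&
      !is.null(record$serial) && !is.na(record$serial)) {
    d <- tryCatch(as.POSIXlt(excel_serial_to_date(record$serial)),
                  error = function(e) NULL)
    if (is.null(d)) return(character(0))
    month <- d$mon + 1L
    day <- d$mday
  }
  if (is.null(month) || is.na(month)) return(character(0))

  cand <- character(0)
  if (!is.null(day) && !is.na(day)) {
    cand <- c(cand, .candidate_strings(month, day, tables))
  }
  if (!is.null(year) && !is.na(year)) {
    cand <- c(cand, .candidate_strings(month, year %% 100L, tables))
  }
  cand <- unique(cand)
  keep <- cand[is_symbol(cand, dict)]
  # map back to the dictionary's original spelling
  hits <- unname(dict$symbols[normalize_symbol(keep)])
  if (!is.null(dict$renames)) {
    renamed <- unname(dict$renames[normalize_symbol(hits)])
    hits <- c(hits, renamed[!is.na(renamed)])
  }
  unique(hits)
}

#' Annotate a scan report with repair suggestions
#'
#' Fills each record's `candidates` column (semicolon-separated) and a
#' `repair_status` column: `unambiguous` (exactly one vulnerable-symbol
#' candidate), `ambiguous` (more than one), `unresolvable` (none).
#' Modernized renames do not count toward ambiguity -- they accompany
#' their original.
#'
#' @param report a `scan_report`.
#' @param dict a [gene_dictionary()].
#' @param tables list of [month_table()]s.
#' @return the report with annotated `records`; summary counts are
#'   attached as attribute `"repair_summary"` (`unambiguous`, `ambiguous`,
#'   `unresolvable`).
#' @export
suggest_fixes <- function(report, dict, tables = month_tables()) {
  stopifnot(inherits(report, "scan_report"))
  rec <- report$records
  status <- character(nrow(rec))
  cands <- character(nrow(rec))
  ren <- if (is.null(dict$renames)) character(0) else unname(dict$renames)
  for (k in seq_len(nrow(rec))) {
    cc <- candidates_for(rec[k, ], dict, tables)
    primary <- setdiff(cc, ren)
    cands[k] <- paste(cc, collapse = ";")
    status[k] <- if (length(primary) == 1L) "unambiguous"
                 else if (length(primary) > 1L) "ambiguous"
                 else "unresolvable"
  }
  rec$candidates <- cands
  rec$repair_status <- if (nrow(rec)) status else character(0)
  report$records <- rec
  attr(report, "repair_summary") <- c(
    unambiguous = sum(status == "unambiguous"),
    ambiguous = sum(status == "ambiguous"),
    unresolvable = sum(status == "unresolvable"))
  report
}

#' Write the repair annotations as TSV
#'
#' @param report an annotated `scan_report` from [suggest_fixes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repair_report <- function(report, path) {
  stopifnot(inherits(report, "scan_report"))
  rec <- report$records
  cols <- intersect(c("file", "sheet", "column", "row", "raw",
                      "error_class", "day", "month", "year", "serial",
                      "candidates", "repair_status"), names(rec))
  utils::write.table(rec[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
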