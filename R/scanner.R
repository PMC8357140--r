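# The core screen: find gene-symbol columns, flag suspected conversions.
#
# Two-stage, mirroring the corpus screen it automates: (1) a column is a
# gene list when it holds at least five recognized gene symbols (intact
# symbols only -- converted cells do not count toward the threshold);
# (2) every other cell of a qualifying column is classified against the
# supported error formats: rendered dates (d-mmm, mmm-d, mmm-yy, slash,
# ISO), scientific notation, and five-digit internal date serials.

#' Scanner configuration
#'
#' @param min_hits minimum count of intact symbol cells for a column to
#'   qualify as a gene list (default 5).
#' @param dialect a [date_dialect()].
#' @param serial_window plausibility window for five-digit serials, passed
#'   to [is_candidate_serial()].
#' @param transposed also scan row-wise (horizontal gene lists). Off by
#'   default: the screen this mirrors detected vertical lists only.
#' @return a list of class `"scan_config"`.
#' @export
scan_config <- function(min_hits = 5L, dialect = date_dialect(),
                        serial_window = c(10000L, 99999L),
                        transposed = FALSE) {
  structure(list(min_hits = as.integer(min_hits), dialect = dialect,
                 serial_window = serial_window,
                 transposed = isTRUE(transposed)),
            class = "scan_config")
}

#' Find gene-list columns in a table
#'
#' A column qualifies iff at least `min_hits` of its cells are intact
#' dictionary symbols. Converted cells do not count: a short, fully
#' converted column is undetectable (known limitation, documented).
#'
#' @param table an `ss_table` from [read_tables()].
#' @param dict a [gene_dictionary()].
#' @param min_hits qualification threshold (default 5).
#' @return integer vector of qualifying column indices (1-based).
#' @export
detect_gene_columns <- function(table, dict, min_hits = 5L) {
  stopifnot(inherits(table, "ss_table"))
  if (table$n_rows == 0L || table$n_cols == 0L) return(integer(0))
  hits <- colSums(matrix(is_symbol(table$cells, dict),
                         nrow = table$n_rows))
  which(hits >= min_hits)
}

.CLASS_FROM_FORMAT <- c(`d-mmm` = "d-mmm", `mmm-d` = "mmm-d",
                        `mmm-yy` = "mmm-yy", slash = "slash-date",
                        iso = "iso-date")

#' Classify one cell as a suspected gene-name error
#'
#' Tests, in order: dictionary membership (intact symbols are never
#' flagged), display-date formats via [parse_display_date()], scientific
#' notation, five-digit serial tokens, and finally the cell's underlying
#' date serial if the file stored a true date. Returns `NULL` for anything
#' that is not a suspected error.
#'
#' @param raw raw display string of the cell.
#' @param serial_tag underlying date serial when the cell is date-typed
#'   (`NA` otherwise).
#' @param dialect a [date_dialect()].
#' @param dict optional [gene_dictionary()]; when supplied, cells that are
#'   intact symbols return `NULL` before any pattern is tried (the bundled
#'   dictionary deliberately holds names like "jun-1" that would otherwise
#'   parse as dates).
#' @param serial_window passed to [is_candidate_serial()].
#' @return `NULL`, or a list with `error_class` (one of `d-mmm`, `mmm-d`,
#'   `mmm-yy`, `slash-date`, `iso-date`, `scientific`,
#'   `five-digit-serial`), `day`, `month`, `year`, `serial`, `value`.
#' @examples
#' classify_cell("3-Mar")$error_class  # "d-mmm"
#' classify_cell("43709")$error_class  # "five-digit-serial"
#' classify_cell("TP53")               # NULL
#' @export
classify_cell <- function(raw, serial_tag = NA_real_,
                          dialect = date_dialect(), dict = NULL,
                          serial_window = c(10000L, 99999L)) {
  x <- trimws(raw)
  if (!nzchar(x)) return(NULL)
  if (!is.null(dict) && is_symbol(x, dict)) return(NULL)

  hit <- function(error_class, day = NA_integer_, month = NA_integer_,
                  year = NA_integer_, serial = NA_real_, value = NA_real_) {
    list(error_class = error_class, day = as.integer(day),
         month = as.integer(month), year = as.integer(year),
         serial = serial, value = value)
  }

  pd <- parse_display_date(x, dialect)
  if (!is.null(pd)) {
    cls <- .CLASS_FROM_FORMAT[[pd$source_format]]
    s <- if (!is.na(serial_tag)) serial_tag else NA_real_
    return(hit(cls, pd$day, pd$month, pd$year, serial = s))
  }

  if (grepl("^[0-9]+(\\.[0-9]+)?[Ee][+-]?[0-9]+$", x)) {
    return(hit("scientific", value = as.numeric(x)))
  }

  # five-digit serial: literal five digits, no leading zero (a serial with
  # a leading zero would never be rendered that way)
  if (grepl("^[1-9][0-9]{4}$", x)) {
    s <- as.integer(x)
    if (is_candidate_serial(s, serial_window) && s != 60L) {
      d <- as.POSIXlt(excel_serial_to_date(s))
      return(hit("five-digit-serial", d$mday, d$mon + 1L, d$year + 1900L,
                 serial = as.numeric(s)))
    }
  }

  # date-typed cell whose display text did not parse (unusual render)
  if (!is.na(serial_tag) && serial_tag != 60 && serial_tag >= 1 &&
      serial_tag <= 2958465 && serial_tag == floor(serial_tag)) {
    d <- as.POSIXlt(excel_serial_to_date(serial_tag))
    return(hit("five-digit-serial", d$mday, d$mon + 1L, d$year + 1900L,
               serial = serial_tag))
  }

  NULL
}

.empty_records <- function() {
  data.frame(file = character(0), sheet = character(0),
             column = integer(0), row = integer(0), raw = character(0),
             error_class = character(0), day = integer(0),
             month = integer(0), year = integer(0), serial = numeric(0),
             value = numeric(0), candidates = character(0),
             stringsAsFactors = FALSE)
}

.new_scan_report <- function(records, files_screened,
                             files_with_gene_lists, files_affected,
                             skipped = character(0)) {
  pc <- if (nrow(records)) table(records$error_class) else
    table(character(0))
  structure(list(files_screened = files_screened,
                 files_with_gene_lists = files_with_gene_lists,
                 files_affected = files_affected,
                 records = records,
                 per_class_counts = pc,
                 skipped = skipped),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf(paste0("<scan_report> %d file(s) screened, %d with gene ",
                     "lists, %d affected; %d flagged cell(s)\n"),
              x$files_screened, x$files_with_gene_lists, x$files_affected,
              nrow(x$records)))
  if (nrow(x$records)) {
    tab <- x$per_class_counts
    cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Scan one file for gene-name errors
#'
#' Runs the full pipeline: [sniff_file_type()] -> [read_tables()] ->
#' [detect_gene_columns()] -> [classify_cell()] over every cell of every
#' qualifying column. A file of unknown type is counted as screened and
#' recorded in `$skipped`, never an error.
#'
#' @param path file to scan.
#' @param dict a [gene_dictionary()].
#' @param config a [scan_config()].
#' @return a `scan_report`: counts (`files_screened`,
#'   `files_with_gene_lists`, `files_affected`), a `records` data.frame
#'   (one row per flagged cell: file, sheet, 1-based column and row, raw
#'   text, error class, decoded day/month/year/serial/value), and
#'   `per_class_counts`.
#' @export
scan_file <- function(path, dict, config = scan_config()) {
  stopifnot(inherits(dict, "gene_dictionary"))
  type <- tryCatch(sniff_file_type(path), error = function(e) "unknown")
  if (type == "unknown") {
    message("scan_file: skipping ", basename(path), " (unknown file type)")
    return(.new_scan_report(.empty_records(), 1L, 0L, 0L,
                            skipped = path))
  }
  tables <- read_tables(path)
  recs <- list()
  has_gene_list <- FALSE
  for (tb in tables) {
    grids <- list(list(cells = tb$cells, serial = tb$serial,
                       transposed = FALSE))
    if (config$transposed) {
      grids <- c(grids, list(list(cells = t(tb$cells), serial = t(tb$serial),
                                  transposed = TRUE)))
    }
    for (g in grids) {
      gtb <- .new_table(g$cells, g$serial, tb$source_path, tb$sheet_name)
      cols <- detect_gene_columns(gtb, dict, config$min_hits)
      if (length(cols)) has_gene_list <- TRUE
      for (j in cols) {
        for (i in seq_len(gtb$n_rows)) {
          cl <- classify_cell(gtb$cells[i, j], gtb$serial[i, j],
                              config$dialect, dict, config$serial_window)
          if (!is.null(cl)) {
            row <- if (g$transposed) j else i
            col <- if (g$transposed) i else j
            recs[[length(recs) + 1L]] <- data.frame(
              file = path, sheet = tb$sheet_name, column = col, row = row,
              raw = gtb$cells[i, j], error_class = cl$error_class,
              day = cl$day, month = cl$month, year = cl$year,
              serial = cl$serial, value = cl$value,
              candidates = NA_character_, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else .empty_records()
  .new_scan_report(records, 1L, as.integer(has_gene_list),
                   as.integer(nrow(records) > 0L))
}

#' Scan several files and merge the reports
#'
#' @param paths file paths.
#' @param dict a [gene_dictionary()].
#' @param config a [scan_config()].
#' @return a merged `scan_report`.
#' @export
scan_files <- function(paths, dict, config = scan_config()) {
  reports <- lapply(paths, scan_file, dict = dict, config = config)
  merge_scan_reports(reports)
}

#' @rdname scan_files
#' @param reports a list of `scan_report` objects.
#' @export
merge_scan_reports <- function(reports) {
  stopifnot(all(vapply(reports, inherits, logical(1), "scan_report")))
  records <- do.call(rbind, c(lapply(reports, `[[`, "records"),
                              list(.empty_records())))
  .new_scan_report(
    records,
    sum(vapply(reports, `[[`, integer(1), "files_screened")),
    sum(vapply(reports, `[[`, integer(1), "files_with_gene_lists")),
    sum(vapply(reports, `[[`, integer(1), "files_affected")),
    skipped = unlist(lapply(reports, `[[`, "skipped")))
}

#' Roll per-file scan reports up to publications
#'
#' A publication is affected iff at least one of its files is affected;
#' it "has gene lists" iff at least one file does.
#'
#' @param reports list of single-file `scan_report`s.
#' @param publication character vector, one publication id per report.
#' @return data.frame with one row per publication: `publication`,
#'   `n_files`, `n_files_with_gene_lists`, `n_files_affected`,
#'   `has_gene_list`, `affected`; totals attached as attribute `"totals"`.
#' @export
rollup_publications <- function(reports, publication) {
  stopifnot(length(reports) == length(publication))
  if (any(is.na(publication) | !nzchar(publication))) {
    stop("grouping error: every file needs a publication id")
  }
  screened <- vapply(reports, `[[`, integer(1), "files_screened")
  withgl <- vapply(reports, `[[`, integer(1), "files_with_gene_lists")
  affected <- vapply(reports, `[[`, integer(1), "files_affected")
  agg <- function(x) as.integer(tapply(x, publication, sum))
  pubs <- sort(unique(publication))
  out <- data.frame(
    publication = pubs,
    n_files = agg(screened),
    n_files_with_gene_lists = agg(withgl),
    n_files_affected = agg(affected),
    stringsAsFactors = FALSE)
  out$has_gene_list <- out$n_files_with_gene_lists > 0L
  out$affected <- out$n_files_affected > 0L
  attr(out, "totals") <- c(
    publications_screened = length(pubs),
    publications_with_gene_lists = sum(out$has_gene_list),
    publications_affected = sum(out$affected),
    files_affected = sum(out$n_files_affected))
  out
}

#' Write a human-review report of flagged cells with context
#'
#' The automated screen over a real corpus yields some false positives; in
#' place of manual re-opening of every file, this emits each flagged cell
#' together with its three nearest neighbours in the column so a human can
#' audit the call quickly.
#'
#' @param report a `scan_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_review_report <- function(report, path) {
  stopifnot(inherits(report, "scan_report"))
  rec <- report$records
  ctx <- character(nrow(rec))
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(rec))) {
    key <- rec$file[k]
    tabs <- if (!is.null(cache[[key]])) cache[[key]] else {
      cache[[key]] <- tryCatch(read_tables(key), error = function(e) NULL)
      cache[[key]]
    }
    ctx[k] <- ""
    if (!is.null(tabs)) {
      tb <- Filter(function(t) t$sheet_name == rec$sheet[k], tabs)
      if (length(tb)) {
        tb <- tb[[1]]
        i <- rec$row[k]; j <- rec$column[k]
        nb <- setdiff(max(1L, i - 2L):min(tb$n_rows, i + 2L), i)
        ctx[k] <- paste(tb$cells[nb, j], collapse = " | ")
      }
    }
  }
  out <- cbind(rec[, c("file", "sheet", "column", "row", "raw",
                       "error_class")],
               context = ctx)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
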