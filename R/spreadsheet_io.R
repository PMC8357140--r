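# Reading spreadsheet and delimited files into rectangular string tables.
#
# File types are sniffed by content, never by suffix: supplementary "xls"
# files in the wild are frequently TSVs with a misleading extension, and
# the screen must treat them as text. Cell values are surfaced as raw
# display strings (no silent re-typing); true date cells additionally carry
# their underlying 1900-system serial so the scanner can flag them whatever
# the display format.

#' Sniff a file's type from its magic bytes
#'
#' ZIP signature (`PK\\x03\\x04`) -> `"xlsx"`; OLE compound-document
#' signature -> `"xls"`; otherwise NUL-free line-oriented content ->
#' `"delimited-text"`; anything else -> `"unknown"`. The suffix is never
#' consulted.
#'
#' @param path file path.
#' @return one of `"xlsx"`, `"xls"`, `"delimited-text"`, `"unknown"`.
#' @export
sniff_file_type <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 4096L)
  if (!length(head)) return("unknown")
  if (length(head) >= 4 &&
      identical(head[1:4], as.raw(c(0x50, 0x4B, 0x03, 0x04)))) {
    return("xlsx")
  }
  ole <- as.raw(c(0xD0, 0xCF, 0x11, 0xE0, 0xA1, 0xB1, 0x1A, 0xE1))
  if (length(head) >= 8 && identical(head[1:8], ole)) return("xls")
  if (any(head == as.raw(0))) return("unknown")
  # printable, line-oriented text
  txt <- rawToChar(head)
  Encoding(txt) <- "latin1"
  "delimited-text"
}

.new_table <- function(cells, serial, source_path, sheet_name) {
  structure(list(source_path = source_path, sheet_name = sheet_name,
                 cells = cells, serial = serial,
                 n_rows = nrow(cells), n_cols = ncol(cells)),
            class = "ss_table")
}

#' @export
print.ss_table <- function(x, ...) {
  cat(sprintf("<ss_table> %s [%s]: %d x %d\n",
              basename(x$source_path), x$sheet_name, x$n_rows, x$n_cols))
  invisible(x)
}

# render a numeric preserving integer-ness (43709, not "43709.0" / 4.4e4)
.num_to_display <- function(x) {
  if (is.finite(x) && x == floor(x) && abs(x) < 1e15) {
    format(x, scientific = FALSE, trim = TRUE)
  } else {
    as.character(x)
  }
}

.cell_to_display <- function(cell) {
  if (is.null(cell) || length(cell) == 0L || is.na(cell[1])) {
    return(list(text = "", serial = NA_real_))
  }
  if (inherits(cell, c("Date", "POSIXct", "POSIXt"))) {
    d <- as.Date(cell)
    s <- tryCatch(excel_date_to_serial(d), error = function(e) NA_real_)
    lt <- as.POSIXlt(d)
    return(list(text = sprintf("%d-%s", lt$mday, month.abb[lt$mon + 1L]),
                serial = as.numeric(s)))
  }
  if (is.numeric(cell)) {
    return(list(text = .num_to_display(cell), serial = NA_real_))
  }
  list(text = as.character(cell), serial = NA_real_)
}

.read_excel_tables <- function(path) {
  sheets <- readxl::excel_sheets(path)
  lapply(sheets, function(sh) {
    df <- tryCatch(
      suppressMessages(readxl::read_excel(path, sheet = sh,
                                          col_names = FALSE,
                                          col_types = "list")),
      error = function(e) stop("parse error in ", basename(path),
                               " sheet '", sh, "': ",
                               conditionMessage(e)))
    nr <- nrow(df); nc <- ncol(df)
    cells <- matrix("", nrow = nr, ncol = nc)
    serial <- matrix(NA_real_, nrow = nr, ncol = nc)
    for (j in seq_len(nc)) {
      col <- df[[j]]
      for (i in seq_len(nr)) {
        v <- .cell_to_display(col[[i]])
        cells[i, j] <- v$text
        serial[i, j] <- v$serial
      }
    }
    .new_table(cells, serial, path, sh)
  })
}

# split text lines on a delimiter without quote interpretation (raw display
# text is preserved; normalization strips quotes later)
.read_delim_table <- function(path) {
  txt <- tryCatch(readLines(path, warn = FALSE, encoding = "UTF-8"),
                  error = function(e) stop("I/O error reading ", path, ": ",
                                           conditionMessage(e)))
  if (any(is.na(nchar(txt, allowNA = TRUE)))) {
    # invalid UTF-8: fall back to latin1
    message("read_tables: ", basename(path),
            " is not valid UTF-8; falling back to latin1")
    txt <- readLines(path, warn = FALSE)
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
  }
  txt <- txt[cumsum(nzchar(txt)) > 0 | nzchar(txt)] # keep interior blanks
  if (!length(txt)) {
    return(.new_table(matrix(character(0), 0, 0),
                      matrix(numeric(0), 0, 0), path, "sheet1"))
  }
  delim <- .detect_delimiter(txt)
  rows <- strsplit(txt, delim, fixed = TRUE)
  nc <- max(lengths(rows), 1L)
  cells <- t(vapply(rows, function(r) {
    length(r) <- nc
    r[is.na(r)] <- ""
    r
  }, character(nc)))
  if (nc == 1L) cells <- matrix(cells, ncol = 1L)
  .new_table(cells, matrix(NA_real_, nrow(cells), ncol(cells)),
             path, "sheet1")
}

# tab first, then comma: choose the delimiter giving a consistent, >1
# column count; fall back to tab
.detect_delimiter <- function(lines) {
  probe <- utils::head(lines, 50L)
  for (d in c("\t", ",")) {
    n <- lengths(strsplit(probe, d, fixed = TRUE))
    if (all(n == n[1]) && n[1] > 1L) return(d)
  }
  for (d in c("\t", ",")) {
    if (any(grepl(d, probe, fixed = TRUE))) return(d)
  }
  "\t"
}

#' Read a spreadsheet or delimited file into string tables
#'
#' Dispatches on [sniff_file_type()]: XLSX/XLS via readxl (one table per
#' sheet), delimited text via a raw line splitter (one table, ragged rows
#' padded to the maximum width). Numeric cells are rendered preserving
#' integer-ness ("43709", never "43709.0"); date-typed cells are rendered
#' d-mmm and tagged with their 1900-system serial in the `serial` matrix.
#'
#' @param path file path.
#' @return list of `ss_table` objects: each has `$cells` (character
#'   matrix of display text), `$serial` (numeric matrix, `NA` except under
#'   date-typed cells), `$sheet_name`, `$source_path`, `$n_rows`,
#'   `$n_cols`.
#' @export
read_tables <- function(path) {
  type <- sniff_file_type(path)
  switch(type,
         xlsx = ,
         xls = .read_excel_tables(path),
         `delimited-text` = list(.read_delim_table(path)),
         stop("unknown file type (not xlsx/xls/delimited text): ", path))
}

#' Write a table out as normalized TSV
#'
#' Mirrors the extract-to-tabular step of a corpus screen (one TSV per
#' sheet). Purely an export; never mutates the source file.
#'
#' @param table an `ss_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  stopifnot(inherits(table, "ss_table"))
  lines <- apply(table$cells, 1L, paste, collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}
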