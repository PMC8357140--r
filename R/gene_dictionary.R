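# Gene-symbol dictionaries: load, normalize, query.
#
# The scanner decides that a spreadsheet column is a gene list by counting
# cells that match a symbol dictionary, so the dictionary is fully
# pluggable: the bundled fixture covers a few hundred symbols (vulnerable
# and safe) and a full-organism set is user-supplied, e.g. extracted from a
# GTF annotation.

#' Normalize a gene symbol for dictionary matching
#'
#' Trims whitespace, strips one layer of surrounding single or double
#' quotes, and upper-cases. Hyphens and dots are preserved so that the
#' protein name "jun-1" stays distinct from the symbol "JUN1".
#' Normalization is idempotent.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_symbol <- function(x) {
  x <- trimws(as.character(x))
  x <- sub('^"(.*)"$', "\\1", x)
  x <- sub("^'(.*)'$", "\\1", x)
  toupper(trimws(x))
}

#' Construct a gene dictionary
#'
#' @param symbols character vector of gene symbols (any case; duplicates
#'   after normalization are collapsed, first spelling kept).
#' @param renames optional named character vector mapping old symbol ->
#'   modern symbol (e.g. `c(SEPT1 = "SEPTIN1")`); keys and values are
#'   normalized.
#' @param species free-text species label.
#' @return an object of class `"gene_dictionary"`.
#' @export
gene_dictionary <- function(symbols, renames = NULL,
                            species = "unspecified") {
  symbols <- symbols[nzchar(trimws(symbols))]
  norm <- normalize_symbol(symbols)
  keep <- !duplicated(norm)
  if (!is.null(renames)) {
    if (is.null(names(renames)) || any(!nzchar(names(renames))) ||
        any(!nzchar(renames))) {
      stop("renames must be a named character vector with non-empty ",
           "old and new symbols")
    }
    renames <- stats::setNames(normalize_symbol(renames),
                               normalize_symbol(names(renames)))
  }
  structure(list(symbols = stats::setNames(symbols[keep], norm[keep]),
                 renames = renames,
                 species = species),
            class = "gene_dictionary")
}

#' @export
print.gene_dictionary <- function(x, ...) {
  cat(sprintf("<gene_dictionary> %d symbols (%s), %d renames\n",
              length(x$symbols), x$species,
              length(x$renames)))
  invisible(x)
}

#' @export
length.gene_dictionary <- function(x) length(x$symbols)

#' Load gene symbols from a delimited text file
#'
#' @param path CSV or TSV file.
#' @param column column to read: a name (requires a header row) or a
#'   1-based index. With an index, a header row is assumed absent unless
#'   `header = TRUE`.
#' @param header logical; `NA` (default) means `TRUE` when `column` is a
#'   name, `FALSE` when it is an index.
#' @param renames optional rename table, as for [gene_dictionary()].
#' @param species species label.
#' @return a [gene_dictionary()].
#' @export
load_gene_symbols <- function(path, column = 1L, header = NA,
                              renames = NULL, species = "unspecified") {
  if (!file.exists(path)) stop("load error: no such file: ", path)
  if (is.na(header)) header <- is.character(column)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, sep = delim, header = header,
                      colClasses = "character", quote = "\"'",
                      comment.char = "", fill = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("load error reading ", path, ": ",
                             conditionMessage(e)))
  if (is.character(column)) {
    if (!column %in% names(df)) {
      stop("load error: no column named '", column, "' in ", path)
    }
    vals <- df[[column]]
  } else {
    if (ncol(df) < column) {
      stop("load error: file has ", ncol(df), " columns, need ", column)
    }
    vals <- df[[column]]
  }
  vals <- vals[nzchar(trimws(vals))]
  if (!length(vals)) stop("empty-dictionary error: no symbols in ", path)
  gene_dictionary(vals, renames = renames, species = species)
}

#' Load an old-to-new symbol rename table
#'
#' @param path two-column TSV (old symbol, new symbol), no header.
#' @return named character vector, old -> new.
#' @export
load_rename_table <- function(path) {
  if (!file.exists(path)) stop("load error: no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("load error: rename table needs two columns")
  stats::setNames(df[[2]], df[[1]])
}

#' The bundled fixture dictionary
#'
#' A few hundred symbols spanning date-vulnerable names (SEPT1..SEPT14,
#' MARCH1..MARCH11, DEC1, OCT4, AGO2, MEI1, TAMM41, "jun-1", ...) and safe
#' controls (TP53, NCF1, ...), with the matching modernization renames
#' (SEPT1 -> SEPTIN1, MARCH1 -> MARCHF1, ...). Intended for tests and small
#' demonstrations; real screens should supply an organism dictionary.
#'
#' @return a [gene_dictionary()].
#' @export
bundled_dictionary <- function() {
  sym <- system.file("extdata", "gene_symbols_fixture.tsv",
                     package = "genescreen", mustWork = TRUE)
  ren <- system.file("extdata", "gene_renames_fixture.tsv",
                     package = "genescreen", mustWork = TRUE)
  load_gene_symbols(sym, column = "symbol",
                    renames = load_rename_table(ren),
                    species = "synthetic fixture (human-like)")
}

#' Extract gene names from a GTF annotation file
#'
#' Reads gene-typed records (column 3 == "gene") and collects unique
#' `gene_name` attribute values, preserving original case; the normalized
#' forms are attached as the `normalized` attribute. Lines that do not have
#' nine tab-separated fields are skipped and counted in a message.
#'
#' @param path GTF file.
#' @return character vector of unique gene names (attribute `normalized`
#'   carries their normalized forms).
#' @export
extract_names_from_gtf <- function(path) {
  if (!file.exists(path)) stop("load error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 9L
  if (any(!ok)) {
    message("extract_names_from_gtf: skipped ", sum(!ok),
            " malformed line(s) in ", basename(path))
  }
  fields <- fields[ok]
  is_gene <- vapply(fields, function(f) f[3] == "gene", logical(1))
  attrs <- vapply(fields[is_gene], `[`, character(1), 9L)
  m <- regmatches(attrs, regexec('gene_name "([^"]*)"', attrs))
  names_raw <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                      character(1))
  names_raw <- names_raw[!is.na(names_raw) & nzchar(names_raw)]
  if (!length(names_raw)) {
    stop("empty-extraction error: no gene_name attributes in ", path)
  }
  out <- names_raw[!duplicated(normalize_symbol(names_raw))]
  attr(out, "normalized") <- normalize_symbol(out)
  out
}

#' Test cells for dictionary membership
#'
#' @param cell character vector of raw cell strings.
#' @param dict a [gene_dictionary()].
#' @return logical vector: is the normalized cell a known symbol?
#' @examples
#' d <- gene_dictionary(c("TP53", "NCF1"))
#' is_symbol(c("Tp53 ", "7-Sep", ""), d) # TRUE FALSE FALSE
#' @export
is_symbol <- function(cell, dict) {
  stopifnot(inherits(dict, "gene_dictionary"))
  normalize_symbol(cell) %in% names(dict$symbols)
}
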