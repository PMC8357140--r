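# Synthetic corpora with ground-truth manifests, and offline
# supplementary-link extraction from saved article HTML.
#
# The generator is the package's test surface for the end-to-end screen:
# it writes a seeded corpus of TSV and XLSX files whose gene columns are
# drawn from a dictionary, injects autoconversion errors at known
# positions with a configurable class mix, and records every injection in
# a manifest. A scan of the corpus must recover the manifest exactly.

.DEFAULT_CLASS_MIX <- c(`d-mmm` = 0.832, `five-digit-serial` = 0.157,
                        `slash-date` = 0.009, scientific = 0.002)

# classify the dictionary once: which symbols convert, and how
.vulnerability_profile <- function(dict, tables, dialect) {
  syms <- unname(dict$symbols)
  res <- lapply(syms, simulate_autoconversion, tables = tables,
                dialect = dialect)
  outcome <- vapply(res, `[[`, character(1), "outcome")
  list(symbols = syms, results = res, outcome = outcome,
       day_vuln = which(outcome == "date" &
                          !vapply(res, function(r) is.na(r$day), logical(1))),
       year_vuln = which(outcome == "date" &
                           vapply(res, function(r) is.na(r$day), logical(1))),
       sci_vuln = which(outcome == "scientific"),
       safe = which(outcome == "unchanged"))
}

# render one injected error; returns list(display, class, original)
.inject_error <- function(class, prof, serial_year, slash_year) {
  pick <- function(idx) {
    i <- idx[sample.int(length(idx), 1L)]
    list(sym = prof$symbols[i], res = prof$results[[i]])
  }
  if (class == "scientific") {
    p <- pick(prof$sci_vuln)
    return(list(display = p$res$display, class = "scientific",
                original = p$sym))
  }
  if (class == "mmm-yy") {
    p <- pick(prof$year_vuln)
    return(list(display = p$res$display, class = "mmm-yy",
                original = p$sym))
  }
  p <- pick(prof$day_vuln)
  m <- p$res$month; d <- p$res$day
  disp <- switch(class,
    `d-mmm` = sprintf("%d-%s", d, month.abb[m]),
    `mmm-d` = sprintf("%s-%02d", month.abb[m], d),
    `slash-date` = sprintf("%d/%d/%d", m, d, slash_year),
    `iso-date` = sprintf("%04d-%02d-%02d", serial_year, m, d),
    `five-digit-serial` = as.character(excel_date_to_serial(
      as.Date(sprintf("%04d-%02d-%02d", serial_year, m, d)))),
    stop("unknown error class in class_mix: ", class))
  list(display = disp, class = class, original = p$sym)
}

#' Generate a synthetic corpus with a ground-truth error manifest
#'
#' Writes `n_publications` publications of 1 or more supplementary files
#' each (TSV or XLSX, chosen at random) under `dir`. With probability
#' `gene_column_prob` a file carries a gene-symbol column drawn from
#' `dict`; each gene cell is, with probability `error_rate`, replaced by a
#' rendered conversion whose class is drawn from `class_mix`. At least
#' five intact symbols are always kept per gene column so the column
#' remains detectable. Every injection is recorded in
#' `<dir>/manifest.tsv`; generation is reproducible from `seed` (the
#' caller's RNG state is untouched).
#'
#' @param dir output directory (created if needed).
#' @param n_publications number of publications.
#' @param files_per_pub inclusive range (length 2) of files per
#'   publication.
#' @param gene_column_prob probability that a file has a gene column.
#'   Default 0.72, the observed share of supplementary spreadsheets that
#'   contain gene lists in a large PMC screen.
#' @param error_rate per-cell injection probability. Default 0.05.
#' @param class_mix named non-negative weights over error classes
#'   (`d-mmm`, `mmm-d`, `mmm-yy`, `slash-date`, `iso-date`, `scientific`,
#'   `five-digit-serial`). The default mirrors the error-type composition
#'   observed in published affected files: 83.2% d-mmm, 15.7% five-digit
#'   serial, 0.9% slash, 0.2% scientific.
#' @param dict a [gene_dictionary()]; default the bundled fixture.
#' @param tables month tables used to decide which symbols are vulnerable.
#' @param seed integer seed; required, for reproducibility.
#' @param xlsx_prob probability a file is XLSX rather than TSV.
#' @param serial_year,slash_year calendar years used to materialize
#'   five-digit serials / slash dates (a month-day conversion needs a year
#'   to become a serial; 2019 and 2016 sit inside the screened era).
#' @param dialect a [date_dialect()].
#' @return invisibly, a list: `dir`, `files` (data.frame: `file`,
#'   `publication`, `format`, `has_gene_column`), `manifest` (data.frame:
#'   `publication`, `file`, `sheet`, `column`, `row`, `error_class`,
#'   `original`, `display`).
#' @export
generate_corpus <- function(dir, n_publications = 10L,
                            files_per_pub = c(1L, 3L),
                            gene_column_prob = 0.72,
                            error_rate = 0.05,
                            class_mix = .DEFAULT_CLASS_MIX,
                            dict = bundled_dictionary(),
                            tables = month_tables(),
                            seed,
                            xlsx_prob = 0.3,
                            serial_year = 2019L,
                            slash_year = 2016L,
                            dialect = date_dialect()) {
  if (missing(seed)) stop("seed is required for reproducible generation")
  stopifnot(error_rate >= 0, error_rate <= 1, all(class_mix >= 0),
            sum(class_mix) > 0, length(files_per_pub) == 2L)
  if (is.null(names(class_mix))) stop("class_mix must be named")

  prof <- .vulnerability_profile(dict, tables, dialect)
  needs_day <- c("d-mmm", "mmm-d", "slash-date", "iso-date",
                 "five-digit-serial")
  if (any(class_mix[intersect(names(class_mix), needs_day)] > 0) &&
      !length(prof$day_vuln)) {
    stop("config error: class_mix requires date-vulnerable symbols but ",
         "the dictionary has none")
  }
  if (isTRUE(class_mix["scientific"] > 0) && !length(prof$sci_vuln)) {
    stop("config error: class_mix weights 'scientific' but the ",
         "dictionary has no scientific-vulnerable names")
  }
  if (isTRUE(class_mix["mmm-yy"] > 0) && !length(prof$year_vuln)) {
    stop("config error: class_mix weights 'mmm-yy' but the dictionary ",
         "has no year-vulnerable names")
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  safe_syms <- prof$symbols[prof$safe]
  mix <- class_mix / sum(class_mix)
  files <- list(); manifest <- list()

  for (p in seq_len(n_publications)) {
    pub <- sprintf("PUB%04d", p)
    nf <- sample(files_per_pub[1]:files_per_pub[2], 1L)
    for (f in seq_len(nf)) {
      fmt <- if (stats::runif(1) < xlsx_prob) "xlsx" else "tsv"
      fname <- file.path(dir, sprintf("%s_s%d.%s", pub, f, fmt))
      n_rows <- sample(12:28, 1L)
      has_gene <- stats::runif(1) < gene_column_prob
      note_col <- c("Note", sample(c("up", "down", "ns"), n_rows, TRUE))
      value_col <- c("logFC",
                     sprintf("%.3f", stats::rnorm(n_rows)))
      if (has_gene) {
        genes <- sample(safe_syms, n_rows, replace = n_rows > length(safe_syms))
        inject <- which(stats::runif(n_rows) < error_rate)
        # keep the column detectable: >= 5 intact symbols
        max_inject <- max(0L, n_rows - 5L)
        if (length(inject) > max_inject) {
          inject <- inject[seq_len(max_inject)]
        }
        for (i in inject) {
          cls <- sample(names(mix), 1L, prob = mix)
          inj <- .inject_error(cls, prof, serial_year, slash_year)
          genes[i] <- inj$display
          manifest[[length(manifest) + 1L]] <- data.frame(
            publication = pub, file = fname,
            sheet = if (fmt == "xlsx") "Sheet1" else "sheet1",
            column = 1L, row = i + 1L, # +1: header row
            error_class = inj$class, original = inj$original,
            display = inj$display, stringsAsFactors = FALSE)
        }
        cells <- cbind(c("Gene", genes), value_col, note_col)
      } else {
        cells <- cbind(c("ID", sprintf("probe_%04d",
                                       sample.int(9999, n_rows))),
                       value_col, note_col)
      }
      dimnames(cells) <- NULL
      if (fmt == "xlsx") {
        write_xlsx_fixture(stats::setNames(list(cells), "Sheet1"), fname)
      } else {
        writeLines(apply(cells, 1L, paste, collapse = "\t"), fname)
      }
      files[[length(files) + 1L]] <- data.frame(
        file = fname, publication = pub, format = fmt,
        has_gene_column = has_gene, stringsAsFactors = FALSE)
    }
  }

  files <- do.call(rbind, files)
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(publication = character(0), file = character(0),
               sheet = character(0), column = integer(0), row = integer(0),
               error_class = character(0), original = character(0),
               display = character(0), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(files, file.path(dir, "files.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(dir = dir, files = files, manifest = manifest))
}

#' Extract supplementary spreadsheet links from a saved article page
#'
#' Returns the `href` values of anchors pointing at `.xls` or `.xlsx`
#' files (case-insensitive suffix match), deduplicated, in document
#' order. Offline stand-in for a crawl: input is pre-saved HTML, no
#' network access anywhere in the package.
#'
#' @param path saved HTML file.
#' @return character vector of URLs (possibly empty).
#' @export
extract_supp_links <- function(path) {
  if (!file.exists(path)) stop("parse error: no such file: ", path)
  doc <- tryCatch(xml2::read_html(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  hrefs <- xml2::xml_attr(xml2::xml_find_all(doc, "//a[@href]"), "href")
  hrefs <- hrefs[grepl("\\.xlsx?$", hrefs, ignore.case = TRUE)]
  unique(hrefs)
}
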