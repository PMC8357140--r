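# Gene-column detection, cell classification, file scanning, rollups.

test_that("detect_gene_columns applies the five-symbol threshold", {
  d <- mini_dict()
  mk <- function(...) {
    cols <- list(...)
    cells <- do.call(cbind, cols)
    genescreen:::.new_table(cells, matrix(NA_real_, nrow(cells),
                                          ncol(cells)), "f", "s")
  }
  syms10 <- c("TP53", "NCF1", "MARCH1", "SEPT2", "DEC1", "OCT4", "BRCA1",
              "EGFR", "KRAS", "MYC")
  expect_identical(detect_gene_columns(mk(syms10), d), 1L)
  # 4 symbols + 6 numbers: below threshold
  expect_identical(detect_gene_columns(mk(c(syms10[1:4], as.character(1:6))),
                                       d), integer(0))
  # 5 symbols + 1 date cell: the intact symbols carry it
  expect_identical(detect_gene_columns(mk(c(syms10[1:5], "7-Sep")), d), 1L)
  # converted cells do not count toward the threshold
  expect_identical(detect_gene_columns(
    mk(c(syms10[1:4], "7-Sep", "1-Mar")), d), integer(0))
  expect_identical(detect_gene_columns(mk(syms10, as.character(1:10)), d),
                   1L)
})

test_that("classify_cell assigns the documented classes", {
  expect_identical(classify_cell("3-Mar")$error_class, "d-mmm")
  expect_identical(classify_cell("Mar-3")$error_class, "mmm-d")
  expect_identical(classify_cell("Jan-41")$error_class, "mmm-yy")
  expect_identical(classify_cell("3/1/2016")$error_class, "slash-date")
  expect_identical(classify_cell("2016-03-01")$error_class, "iso-date")
  expect_identical(classify_cell("9.33E+22")$error_class, "scientific")
  cl <- classify_cell("43709")
  expect_identical(cl$error_class, "five-digit-serial")
  expect_identical(c(cl$year, cl$month, cl$day), c(2019L, 9L, 1L))
  expect_null(classify_cell("TP53"))
  expect_null(classify_cell("gene expression"))
  expect_null(classify_cell(""))
  # leading-zero five-digit tokens are not serials (never rendered so)
  expect_null(classify_cell("04321"))
  # four and six digit numbers are not serials
  expect_null(classify_cell("9999"))
  expect_null(classify_cell("100000"))
  # a date-typed cell is flagged via its serial tag even if the display
  # text itself is unparseable
  cl2 <- classify_cell("weird", serial_tag = 43709)
  expect_identical(cl2$error_class, "five-digit-serial")
  expect_identical(cl2$month, 9L)
})

test_that("classify_cell never flags a bundled dictionary symbol", {
  d <- bundled_dictionary()
  for (s in unname(d$symbols)) {
    expect_null(classify_cell(s, dict = d), label = s)
  }
})

test_that("scan_file flags injected cells only in gene columns", {
  d <- mini_dict()
  syms <- c("TP53", "NCF1", "MARCH1", "SEPT2", "DEC1", "OCT4", "BRCA1",
            "EGFR", "KRAS", "MYC", "TP53", "NCF1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_tsv(f, syms, replace = c(2L, 5L, 9L),
                 with = c("7-Sep", "43709", "9.33E+22"))
  rep <- scan_file(f, d)
  expect_identical(rep$files_screened, 1L)
  expect_identical(rep$files_with_gene_lists, 1L)
  expect_identical(rep$files_affected, 1L)
  expect_identical(nrow(rep$records), 3L)
  expect_setequal(rep$records$error_class,
                  c("d-mmm", "five-digit-serial", "scientific"))
  expect_identical(sort(rep$records$row), c(3L, 6L, 10L)) # header offset
  expect_identical(sum(rep$per_class_counts), 3L)

  # dates outside gene columns are not the scanner's business
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("When\tWhat", paste(c("7-Sep", "1-Mar", "2-Apr", "43709",
                                     "9.33E+22"), "x", sep = "\t")), g)
  rep2 <- scan_file(g, d)
  expect_identical(nrow(rep2$records), 0L)
  expect_identical(rep2$files_with_gene_lists, 0L)
})

test_that("unknown file types are skipped, not crashed on", {
  d <- mini_dict()
  junk <- withr::local_tempfile()
  writeBin(as.raw(c(0x00, 0xFF, 0x00)), junk)
  expect_message(rep <- scan_file(junk, d), "skipping")
  expect_identical(rep$files_screened, 1L)
  expect_identical(rep$files_affected, 0L)
  expect_identical(rep$skipped, junk)
})

test_that("xlsx date-typed cells are flagged through their serial", {
  d <- mini_dict()
  f <- withr::local_tempfile(fileext = ".xlsx")
  syms <- c("Gene", "TP53", "NCF1", "MARCH1", "SEPT2", "DEC1", "OCT4", "")
  cells <- matrix(syms, ncol = 1)
  serial <- matrix(NA_real_, length(syms), 1)
  serial[8, 1] <- 43709 # SEPT1 converted and stored as a true date
  fx <- list(S1 = list(cells = cells, serial = serial))
  write_xlsx_fixture(fx, f)
  rep <- scan_file(f, d)
  expect_identical(nrow(rep$records), 1L)
  expect_identical(rep$records$raw, "1-Sep")
  expect_identical(rep$records$serial, 43709)
})

test_that("transposed scanning finds horizontal lists when asked", {
  d <- mini_dict()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("TP53", "NCF1", "MARCH1", "SEPT2", "DEC1", "7-Sep"),
                   collapse = "\t"), f)
  expect_identical(nrow(scan_file(f, d)$records), 0L)
  rep <- scan_file(f, d, scan_config(transposed = TRUE))
  expect_identical(nrow(rep$records), 1L)
  expect_identical(rep$records$row, 1L)
  expect_identical(rep$records$column, 6L)
})

test_that("publication rollups count affected publications correctly", {
  d <- mini_dict()
  syms <- c("TP53", "NCF1", "MARCH1", "SEPT2", "DEC1", "OCT4")
  mk <- function(repl) {
    f <- tempfile(fileext = ".tsv")
    write_gene_tsv(f, syms, replace = repl,
                   with = rep("7-Sep", length(repl)))
    scan_file(f, d)
  }
  reports <- list(mk(1L), mk(integer(0)), mk(2L), mk(integer(0)),
                  mk(integer(0)))
  roll <- rollup_publications(reports, c("P1", "P1", "P1", "P2", "P3"))
  expect_identical(nrow(roll), 3L)
  tot <- attr(roll, "totals")
  expect_identical(unname(tot["publications_affected"]), 1L)
  expect_identical(unname(tot["files_affected"]), 2L)
  expect_identical(roll$affected, c(TRUE, FALSE, FALSE))
  expect_error(rollup_publications(reports, c("P1", "P1", NA, "P2", "P3")),
               "grouping error")
  expect_error(rollup_publications(reports[1:2], "P1"), "length")
})

test_that("scan report invariants hold on a generated corpus", {
  dir <- withr::local_tempdir()
  res <- generate_corpus(dir, n_publications = 6, seed = 99,
                         error_rate = 0.1)
  reports <- lapply(res$files$file, scan_file, dict = bundled_dictionary())
  merged <- merge_scan_reports(reports)
  expect_true(merged$files_affected <= merged$files_with_gene_lists)
  expect_true(merged$files_with_gene_lists <= merged$files_screened)
  expect_identical(sum(merged$per_class_counts),
                   nrow(merged$records))
  # affected proportion invariant under file order
  merged2 <- merge_scan_reports(rev(reports))
  expect_identical(merged2$files_affected, merged$files_affected)
})

test_that("review report provides neighbouring-cell context", {
  d <- mini_dict()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_tsv(f, c("TP53", "NCF1", "MARCH1", "SEPT2", "DEC1", "OCT4"),
                 replace = 3L, with = "1-Mar")
  rep <- scan_file(f, d)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_review_report(rep, out)
  got <- utils::read.table(out, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_identical(nrow(got), 1L)
  expect_match(got$context, "NCF1")
  expect_match(got$context, "SEPT2")
})
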