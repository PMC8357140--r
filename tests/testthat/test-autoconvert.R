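# The autoconversion simulator and locale month tables.

test_that("month-token rule reproduces the documented conversions", {
  cases <- list(
    list("SEPT7", "date", "7-Sep", month_tables("english")),
    list("MARCH3", "date", "3-Mar", month_tables("english")),
    list("DEC1", "date", "1-Dec", month_tables("english")),
    list("OCT4", "date", "4-Oct", month_tables("english")),
    list("1-MAR", "date", "1-Mar", month_tables("english")),
    list("TAMM41", "date", "Jan-41", month_tables("finnish")),
    list("AGO2", "date", "Aug-02", month_tables("it_es_pt")),
    list("MEI1", "date", "May-01", month_tables("dutch")),
    list("TP53", "unchanged", "TP53", month_tables("english")),
    list("NCF1", "unchanged", "NCF1", month_tables("english")),
    list("Inf2", "unchanged", "Inf2", month_tables("english")))
  for (cc in cases) {
    r <- simulate_autoconversion(cc[[1]], cc[[4]])
    expect_identical(r$outcome, cc[[2]], label = cc[[1]])
    expect_identical(r$display, cc[[3]], label = cc[[1]])
  }
  # TAMM41 decodes to January 1941 under the default pivot
  r <- simulate_autoconversion("TAMM41", month_tables("finnish"))
  expect_identical(c(r$month, r$year), c(1L, 1941L))
})

test_that("scientific rule parses mantissa-exponent identifiers", {
  r <- simulate_autoconversion("2310009E13")
  expect_identical(r$outcome, "scientific")
  expect_equal(r$value, 2310009e13) # = 2.310009e19, numeric-literal oracle
  expect_identical(r$display, "2.31E+19")
  expect_identical(simulate_autoconversion("E13")$outcome, "unchanged")
  expect_identical(simulate_autoconversion("2310009E")$outcome, "unchanged")
})

test_that("day/year split: 1-31 day, 32-99 year, 0 and >=100 unchanged", {
  expect_identical(simulate_autoconversion("SEPT31")$display, "31-Sep")
  expect_identical(simulate_autoconversion("SEPT32")$display, "Sep-32")
  expect_identical(simulate_autoconversion("SEPT32")$year, 1932L)
  expect_identical(simulate_autoconversion("SEPT29")$year, NA_integer_)
  expect_identical(simulate_autoconversion("SEPT0")$outcome, "unchanged")
  expect_identical(simulate_autoconversion("SEPT100")$outcome, "unchanged")
})

test_that("separators -, /, ., space and none are all accepted", {
  for (s in c("", "-", "/", ".", " ")) {
    r <- simulate_autoconversion(paste0("SEPT", s, "7"))
    expect_identical(r$display, "7-Sep", label = paste0("sep='", s, "'"))
  }
  expect_identical(simulate_autoconversion("SEPT--7")$outcome, "unchanged")
})

test_that("no digit-free string is ever converted to a date", {
  d <- bundled_dictionary()
  pool <- c(unname(d$symbols), "march", "September", "tammikuu", "mei",
            "ago", "x-y", "Gene name")
  pool <- pool[!grepl("[0-9]", pool)]
  tabs <- month_tables(c("english", "it_es_pt", "dutch", "finnish"))
  for (s in pool) {
    expect_false(simulate_autoconversion(s, tabs)$outcome == "date",
                 label = s)
  }
})

test_that("simulate is deterministic and first table wins on overlap", {
  tabs <- month_tables(c("english", "dutch"))
  r1 <- simulate_autoconversion("MEI1", tabs)
  r2 <- simulate_autoconversion("MEI1", tabs)
  expect_identical(r1, r2)
  overlap <- list(month_table("a", c(mei = 5L)),
                  month_table("b", c(mei = 6L)))
  expect_message(r <- simulate_autoconversion("MEI1", overlap), "2 month")
  expect_identical(r$month, 5L)
})

test_that("screen_gene_list returns the converted subset in order", {
  box2 <- c("SEPT7", "DEC1", "OCT4", "MARCH3", "TP53", "NCF1", "Inf2")
  out <- screen_gene_list(box2)
  expect_identical(out$name, c("SEPT7", "DEC1", "OCT4", "MARCH3"))
  out2 <- screen_gene_list(c("MEI1", "TP53"), month_tables("dutch"),
                           taxon = c("D. rerio", "D. rerio"))
  expect_identical(out2$display, "May-01")
  expect_identical(as.integer(attr(out2, "taxon_counts")["D. rerio"]), 1L)
  expect_error(screen_gene_list(character(0)), "non-empty")
})

test_that("name arithmetic evaluates month minus days", {
  expect_identical(evaluate_name_arithmetic("jun-1")$display, "May-31")
  expect_identical(evaluate_name_arithmetic("jun-0")$display, "Jun-01")
  # calendar oracle: year-dependent month length at the February boundary
  expect_identical(evaluate_name_arithmetic("mar-1", year = 2001)$display,
                   "Feb-28")
  expect_identical(evaluate_name_arithmetic("mar-1", year = 2000)$display,
                   "Feb-29")
  expect_null(evaluate_name_arithmetic("jun1"))
  expect_null(evaluate_name_arithmetic("TP53"))
})

test_that("month_table validates tokens", {
  expect_error(month_table("x", c(1, 2)), "named")
  expect_error(month_table("x", c(jan = 13)), "1..12")
  expect_error(month_table("x", c(mei = 5, mei = 6)), "unique")
  tb <- month_table("x", c(may = 5, may = 5))
  expect_identical(unname(tb$tokens), 5L)
})
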