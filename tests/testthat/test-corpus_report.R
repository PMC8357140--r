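# Prevalence aggregation, composition and the JIF correlation.

make_pubs <- function(n_affected, n_with, group, key = "year") {
  out <- data.frame(
    g = rep(group, n_with),
    has_gene_list = TRUE,
    affected = c(rep(TRUE, n_affected), rep(FALSE, n_with - n_affected)),
    stringsAsFactors = FALSE)
  names(out)[1] <- key
  out
}

test_that("aggregate reproduces printed-table proportion arithmetic", {
  pubs <- rbind(make_pubs(282, 936, "2014"), make_pubs(609, 1577, "mm"),
                make_pubs(0, 10, "os"))
  s <- aggregate_corpus(pubs, "year")
  get <- function(g, col) s[s$group == g, col]
  expect_equal(get("2014", "proportion_display"), 30.1)
  expect_equal(get("mm", "proportion_display"), 38.6)
  expect_equal(get("os", "proportion_display"), 0.0)
  expect_equal(get("2014", "proportion"), 100 * 282 / 936, tolerance = 1e-12)
  # conservation: group totals equal ungrouped totals
  expect_identical(sum(s$n_with_gene_lists), nrow(pubs))
  expect_identical(sum(s$n_affected), sum(pubs$affected))
})

test_that("aggregate handles missing keys and zero-list groups", {
  pubs <- data.frame(year = c("2014", NA, "2015"),
                     has_gene_list = c(TRUE, TRUE, FALSE),
                     affected = c(TRUE, FALSE, FALSE))
  expect_message(s <- aggregate_corpus(pubs, "year"), "unknown")
  expect_true("unknown" %in% s$group)
  z <- s[s$group == "2015", ]
  expect_true(z$undefined)
  expect_identical(z$proportion, 0)
  expect_error(aggregate_corpus(pubs, "journal"), "not found")
})

test_that("round_half_up rounds half away from zero", {
  expect_identical(round_half_up(c(30.05, 30.04, -30.05), 1),
                   c(30.1, 30.0, -30.1))
  expect_identical(round_half_up(0.5, 0), 1)
})

test_that("error-class composition counts files once per class", {
  rec <- rbind(
    data.frame(file = sprintf("f%03d", 1:8), error_class = "d-mmm",
               month = NA_integer_),
    data.frame(file = sprintf("f%03d", c(1, 9, 10)),
               error_class = "five-digit-serial",
               month = c(3L, 9L, 6L)),
    # duplicate records in one file count once
    data.frame(file = "f001", error_class = "d-mmm", month = NA_integer_))
  comp <- error_class_composition(rec)
  expect_identical(comp$n_affected_files, 10L)
  cls <- comp$classes
  expect_identical(cls$n_files[cls$error_class == "d-mmm"], 8L)
  expect_identical(cls$n_files[cls$error_class == "five-digit-serial"], 3L)
  expect_equal(cls$pct[cls$error_class == "d-mmm"], 80)
  expect_identical(comp$n_multi_class_files, 1L) # f001 has two classes
  # 2 of 3 serial files decode to March or September
  expect_equal(comp$serial_march_sep_pct, 100 * 2 / 3)
  # composition of a synthetic corpus equals its injection manifest
  dir <- withr::local_tempdir()
  res <- generate_corpus(dir, n_publications = 12, seed = 21,
                         error_rate = 0.2)
  rep <- scan_files(res$files$file, bundled_dictionary())
  comp2 <- error_class_composition(rep$records)
  man_pairs <- unique(res$manifest[, c("file", "error_class")])
  man_tab <- table(man_pairs$error_class)
  for (k in comp2$classes$error_class) {
    expect_identical(comp2$classes$n_files[comp2$classes$error_class == k],
                     as.integer(man_tab[k]), label = k)
  }
})

test_that("empty composition is well-formed", {
  comp <- error_class_composition(
    data.frame(file = character(0), error_class = character(0),
               month = integer(0)))
  expect_identical(comp$n_affected_files, 0L)
  expect_true(is.na(comp$serial_march_sep_pct))
})

test_that("jif_correlation matches textbook formulas and handles bounds", {
  s <- data.frame(group = c("a", "b", "c"),
                  n_with_gene_lists = c(60, 70, 80),
                  proportion = c(10, 20, 30))
  jif <- c(a = 1, b = 2, c = 3)
  r <- jif_correlation(s, jif, min_articles = 50)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  r2 <- jif_correlation(transform(s, proportion = c(30, 20, 10)), jif)
  expect_equal(r2$pearson_r, -1)
  expect_error(jif_correlation(s[1:2, ], jif), "insufficient-data")
  expect_error(jif_correlation(s, jif, min_articles = 75),
               "insufficient-data")

  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    jj <- stats::setNames(stats::runif(n, 1, 60),
                          sprintf("j%02d", seq_len(n)))
    sm <- data.frame(group = names(jj),
                     n_with_gene_lists = sample(50:500, n, TRUE),
                     proportion = stats::runif(n, 0, 60))
    got <- jif_correlation(sm, jj, min_articles = 50)
    pe <- oracle_pearson(unname(jj), sm$proportion)
    sp <- oracle_spearman(unname(jj), sm$proportion)
    expect_equal(got$pearson_r, pe$r, tolerance = 1e-6)
    expect_equal(got$pearson_p, pe$p, tolerance = 1e-6)
    expect_equal(got$spearman_rho, sp$rho, tolerance = 1e-6)
    expect_equal(got$spearman_p, sp$p, tolerance = 1e-6)
  }
})
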