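# Independent oracles and fixture builders shared across tests.

# Day count from civil date, independent of R's Date machinery
# (era-based civil-calendar algorithm; days since 1970-01-01).
days_from_civil <- function(y, m, d) {
  y <- ifelse(m <= 2, y - 1L, y)
  era <- ifelse(y >= 0, y, y - 399L) %/% 400L
  yoe <- y - era * 400L
  doy <- (153L * (ifelse(m > 2, m - 3L, m + 9L)) + 2L) %/% 5L + d - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy
  era * 146097L + doe - 719468L
}

# Excel serial straight from the calendar oracle: serial - 2 equals the
# true day count since 1899-12-31 for serials >= 61 (phantom leap day).
oracle_serial_from_date <- function(date) {
  lt <- as.POSIXlt(date)
  n <- days_from_civil(lt$year + 1900L, lt$mon + 1L, lt$mday) -
    days_from_civil(1899L, 12L, 31L)
  ifelse(n >= 60L, n + 1L, n)
}

# Pearson r and its two-sided p from the textbook formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Spearman rho = Pearson on average ranks; p via the t approximation.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  o <- oracle_pearson(rx, ry)
  list(rho = o$r, p = o$p)
}

# a small well-formed GTF fixture
write_gtf_fixture <- function(path,
                              gene_names = c("SEPT4", "Actb", "Actb"),
                              with_names = TRUE,
                              malformed_lines = 0L) {
  lines <- "#!genome-build fixture-1.0"
  for (i in seq_along(gene_names)) {
    attrs <- sprintf('gene_id "G%04d";', i)
    if (with_names) {
      attrs <- paste0(attrs, sprintf(' gene_name "%s";', gene_names[i]))
    }
    lines <- c(lines,
               paste(c("1", "fixture", "gene", 1000 * i, 1000 * i + 500,
                       ".", "+", ".", attrs), collapse = "\t"),
               paste(c("1", "fixture", "exon", 1000 * i, 1000 * i + 200,
                       ".", "+", ".", attrs), collapse = "\t"))
  }
  if (malformed_lines > 0L) {
    lines <- c(lines, rep("only\tthree\tfields", malformed_lines))
  }
  writeLines(lines, path)
  path
}

mini_dict <- function(symbols = c("TP53", "NCF1", "MARCH1", "SEPT2",
                                  "DEC1", "OCT4", "BRCA1", "EGFR",
                                  "KRAS", "MYC"),
                      renames = NULL) {
  gene_dictionary(symbols, renames = renames, species = "test")
}

# a gene-column TSV fixture: header + symbols, with chosen rows replaced
write_gene_tsv <- function(path, symbols, replace = integer(0),
                           with = character(0)) {
  col <- symbols
  col[replace] <- with
  writeLines(c(paste("Gene", "Value", sep = "\t"),
               paste(col, seq_along(col), sep = "\t")), path)
  path
}
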