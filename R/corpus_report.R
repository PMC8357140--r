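# Corpus-level prevalence reporting: affected proportions by year /
# journal / species, error-class composition, and the JIF correlation.

#' Round half-up (printed-table convention)
#'
#' Printed prevalence tables round 30.05 up to 30.1; R's `round()` rounds
#' half to even. All internal comparisons use unrounded values -- this is
#' display only.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate publication rollups into grouped prevalence summaries
#'
#' @param publications data.frame with one row per publication, carrying
#'   logical columns `has_gene_list` and `affected` plus the grouping
#'   attribute named by `key` (e.g. `year`, `journal`, `species`).
#'   Publications missing the attribute are counted under `"unknown"` with
#'   a message.
#' @param key name of the grouping column.
#' @return data.frame with one row per group: `group`,
#'   `n_with_gene_lists`, `n_affected`, `proportion` (unrounded
#'   percentage), `proportion_display` (half-up, 1 decimal), and
#'   `undefined` (`TRUE` for groups with zero gene-list publications,
#'   whose proportion is reported as 0).
#' @examples
#' pubs <- data.frame(year = c(2014, 2014, 2015),
#'                    has_gene_list = TRUE,
#'                    affected = c(TRUE, FALSE, TRUE))
#' aggregate_corpus(pubs, "year")
#' @export
aggregate_corpus <- function(publications, key) {
  stopifnot(is.data.frame(publications),
            all(c("has_gene_list", "affected") %in% names(publications)))
  if (!key %in% names(publications)) {
    stop("grouping column '", key, "' not found")
  }
  g <- as.character(publications[[key]])
  missing <- is.na(g) | !nzchar(g)
  if (any(missing)) {
    message("aggregate_corpus: ", sum(missing),
            " publication(s) missing '", key, "'; grouped under 'unknown'")
    g[missing] <- "unknown"
  }
  groups <- sort(unique(g))
  n_gl <- vapply(groups, function(k) {
    sum(publications$has_gene_list[g == k])
  }, integer(1))
  n_af <- vapply(groups, function(k) {
    sum(publications$affected[g == k] & publications$has_gene_list[g == k])
  }, integer(1))
  prop <- ifelse(n_gl > 0, 100 * n_af / n_gl, 0)
  data.frame(group = groups,
             n_with_gene_lists = n_gl,
             n_affected = n_af,
             proportion = prop,
             proportion_display = round_half_up(prop, 1L),
             undefined = n_gl == 0L,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Error-class composition of a set of flagged records
#'
#' Counts affected *files* per error class (a file is counted once per
#' class it exhibits, so a file can appear under several classes and the
#' percentages can sum above 100; the overlap count is reported). For
#' five-digit-serial records it also reports the share of decoded dates
#' falling in March or September -- the signature of converted SEPT* and
#' MARCH* symbols.
#'
#' @param records a `scan_report`'s `records` data.frame (needs `file`,
#'   `error_class` and, for serials, `month`).
#' @return list with `classes` (data.frame: `error_class`, `n_files`,
#'   `pct` of affected files), `n_affected_files`, `n_multi_class_files`,
#'   and `serial_march_sep_pct` (`NA` when there are no serial records).
#' @export
error_class_composition <- function(records) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(list(classes = data.frame(error_class = character(0),
                                     n_files = integer(0),
                                     pct = numeric(0)),
                n_affected_files = 0L, n_multi_class_files = 0L,
                serial_march_sep_pct = NA_real_))
  }
  pairs <- unique(records[, c("file", "error_class")])
  n_files <- length(unique(records$file))
  tab <- table(pairs$error_class)
  classes <- data.frame(error_class = names(tab),
                        n_files = as.integer(tab),
                        pct = 100 * as.integer(tab) / n_files,
                        stringsAsFactors = FALSE)
  classes <- classes[order(-classes$n_files), , drop = FALSE]
  row.names(classes) <- NULL
  per_file <- table(pairs$file)
  fd <- records[records$error_class == "five-digit-serial", , drop = FALSE]
  ms <- if (nrow(fd)) {
    # per file: does any decoded serial fall in March or September?
    files_ms <- tapply(fd$month %in% c(3L, 9L), fd$file, any)
    100 * sum(files_ms) / length(files_ms)
  } else NA_real_
  list(classes = classes,
       n_affected_files = n_files,
       n_multi_class_files = sum(per_file > 1L),
       serial_march_sep_pct = ms)
}

#' Correlate affected proportion with journal impact factor
#'
#' Two-sided Pearson and Spearman tests on (JIF, proportion) pairs over
#' journals with at least `min_articles` gene-list publications and a
#' supplied impact factor. JIF values are user-supplied (a two-column
#' table or named vector); without them the analysis is unavailable.
#'
#' @param summaries output of [aggregate_corpus()] keyed by journal.
#' @param jif named numeric vector (journal -> JIF), or a two-column
#'   data.frame (journal, JIF).
#' @param min_articles minimum gene-list publication count (default 50).
#' @return list: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n` (journals used).
#' @export
jif_correlation <- function(summaries, jif, min_articles = 50L) {
  stopifnot(is.data.frame(summaries),
            all(c("group", "n_with_gene_lists", "proportion") %in%
                  names(summaries)))
  if (is.data.frame(jif)) {
    jif <- stats::setNames(as.numeric(jif[[2]]), as.character(jif[[1]]))
  }
  use <- summaries$n_with_gene_lists >= min_articles &
    summaries$group %in% names(jif)
  x <- jif[summaries$group[use]]
  y <- summaries$proportion[use]
  if (sum(use) < 3L) {
    stop("insufficient-data error: need >= 3 journals with >= ",
         min_articles, " gene-list publications and a JIF; have ",
         sum(use))
  }
  pe <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = sum(use))
}

#' Write grouped summaries and a machine-readable report
#'
#' Emits the summary table as TSV and, when `json` is given, a JSON
#' rollup in the style of an automated monthly prevalence report.
#'
#' @param summaries output of [aggregate_corpus()].
#' @param path TSV output path.
#' @param json optional JSON output path (requires the jsonlite package).
#' @return `path`, invisibly.
#' @export
write_corpus_summary <- function(summaries, path, json = NULL) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required for JSON output")
    }
    jsonlite::write_json(
      list(generated = format(Sys.time(), "%Y-%m-%d"),
           groups = summaries),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
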