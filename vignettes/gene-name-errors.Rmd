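---
title: "Auditing spreadsheet gene name errors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing spreadsheet gene name errors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genescreen)
```

## The problem

Spreadsheet programs retype pasted or imported text without notice.
Three re-typings corrupt gene lists in supplementary files:

1. **Date conversion.** A symbol matching *month-token + number* is read
   as a date: `SEPT7` → 7 September, `MARCH3` → 3 March. The month
   tokens are locale-dependent — an Excel in Dutch also reads `MEI1`
   (May-01), Italian/Spanish/Portuguese read `AGO2` (Aug-02), Finnish
   reads `TAMM41` (Jan-41, via the month *tammikuu*).
2. **Scientific notation.** Identifiers shaped *digits-E-digits* (RIKEN
   clones like `2310009E13`) are read as floats (`2.31E+19`).
3. **Internal date format.** A converted date whose cell is later
   reformatted as "number" or "text" is saved as its serial — a
   five-digit integer counting days in the 1900 date system. This third
   form is easy to miss and materially raises measured error
   prevalence when a screen knows to look for it.

`genescreen` models these conversions deterministically, scans files
for their fingerprints, proposes reversals, and aggregates results to
corpus level.

## The 1900 serial date system

Serial 1 is 1 Jan 1900. The system inherits the Lotus 1-2-3 bug: serial
60 is 29 Feb 1900, a date that does not exist, so serials ≥ 61 map as
`1899-12-30 + serial` while serials ≤ 59 map as `1899-12-31 + serial`.
Consequences adopted here:

* `excel_serial_to_date(60)` is an error, never a date — repairs must
  not invent the phantom leap day.
* The valid range is 1–2958465 (31 Dec 9999); fractional serials
  (time of day) and the legacy 1904 Mac offset are out of scope (the
  1904 flag exists but is not implemented).
* The phrase "days since 1 Jan 1900" is ambiguous at ±1 day; the
  standard convention serial 1 = 1900-01-01 is used. Five-digit serials
  are unaffected at the month level, which is what repair needs.

The tests check the implementation against an independent civil-calendar
day-count oracle on thousands of random serials, plus the full
round-trip `date_to_serial(serial_to_date(s)) = s`.

## The simulator

`simulate_autoconversion()` applies rules in a fixed order:

1. *Month-token + number* (either order, separator one of `-`, `/`,
   `.`, space, or nothing): n in 1–31 becomes a day-of-month; n in
   32–99 becomes a two-digit year; n = 0 or ≥ 100 leaves the string
   alone. The year split is what turns `TAMM41` into Jan-41 while
   `SEPT7` stays a day date.
2. Explicit display-date strings (`3/1/2016`, `3-Mar`, `2016-03-01`)
   are recognized as dates.
3. The scientific rule.
4. Otherwise unchanged.

Design choices worth knowing:

* **Rendering is a property of the month table.** Observed corpus
  errors render English-locale day dates as `d-mmm` (`7-Sep`) but
  non-English-locale conversions as `mmm-dd` (`Aug-02`, `May-01`);
  two-digit years always render `mmm-yy` with English abbreviations.
  This is the only scheme that reproduces all documented forms at once,
  so each table carries its render style.
* **Month tokens include evidenced prefixes.** The Finnish table
  carries `tamm` as well as `tammi`/`tammikuu`: spreadsheets accept
  unambiguous month-name prefixes, and `TAMM41` contains only four of
  the five letters of *tammi* before its digits.
* **Two-digit year pivot** is 30 (00–29 → 2000s, 30–99 → 1900s),
  configurable via `date_dialect()`; a common spreadsheet convention,
  otherwise arbitrary.
* The puzzling observed conversions `Inf2` → 3002 and `P2RY1` → 7 are
  **not** simulated; no defensible mechanism is known, and simulating
  an unexplained mapping would contaminate precision guarantees.
* `evaluate_name_arithmetic()` covers the formula-evaluation mode
  (`jun-1` = 1 June minus 1 day = May-31) separately from the default
  import path. It needs a reference year to size February; the default
  2001 (a common year) is a documented convention, not an inference.
* The simulator models the text-file-open import path with one code
  path; the typing/pasting distinctions between spreadsheet products
  are documentation, not separate simulations. Whether a particular
  product version converts mixed separators like `SEPT.7` varies; the
  separator set is explicit configuration, not a product claim.

## The scanner

* **Gene-list definition:** a column with ≥ 5 cells matching the
  symbol dictionary (`min_hits` in `scan_config()`). Only *intact*
  symbols count, mirroring the detect-then-screen order of the corpus
  screens this automates; a short fully-converted column is therefore
  invisible — a documented limitation rather than a tunable.
* Columns are scanned vertically; a `transposed` flag adds a
  horizontal pass for the lists the vertical-only convention misses.
* **Five-digit serials:** any token `[1-9][0-9]{4}` inside a gene
  column whose value decodes to a real date. Leading-zero tokens
  (`04321`) are not serials — a spreadsheet would render 4321. The
  default window (10000–99999) accepts any five-digit value; a narrower
  window restricting to recent decades is configurable. Majority-numeric
  columns still qualify when they hold ≥ 5 symbols; the screen's job is
  to flag, and the review report exists for human audit.
* **Dictionary-first classification:** `classify_cell()` consults the
  dictionary before any pattern, because legitimate names such as the
  protein `jun-1` would otherwise parse as dates. Intact dictionary
  symbols are never flagged (tested exhaustively over the bundled
  dictionary).
* **Slash-date ambiguity:** `3/1/2016` defaults to month-first; when
  both fields are ≤ 12 the alternative reading is recorded alongside,
  so downstream reporting can surface the ambiguity instead of hiding
  it.
* A file whose sniffed content is neither spreadsheet nor line-oriented
  text is counted as screened and skipped, never a crash; suffixes are
  never trusted (magic bytes only).

## Repair

Flagged cells are decoded to (month, day) or (month, two-digit year) —
five-digit serials via the date arithmetic above — then recombined with
every token of every active month table, zero-padded and not,
concatenated and hyphenated. Only strings present in the dictionary
survive, so fabrications are impossible by construction; modernized
renames (`SEPT1` → `SEPTIN1`, `MARCH1` → `MARCHF1`) ride along and do
not count toward ambiguity. For `mmm-yy` records the year digits
themselves are the candidate suffix (`Jan-41` → `TAMM41`); a separate
day interpretation is impossible since 32–99 exceeds any month. The
round-trip property — every vulnerable dictionary symbol survives
simulate → flag → repair — is tested exhaustively over the bundled
dictionary. Repairs are written to side reports; source files are never
modified, because silent modification is the pathology being audited.

## Corpus reporting

Affected proportions are exact integer ratios; display rounding is
half-up to one decimal, matching printed prevalence tables (R's
`round()` is half-to-even, hence the dedicated `round_half_up()`). All
test comparisons use unrounded values. Error-class composition counts
each file once per class it exhibits, so percentages may sum above 100;
the multi-class overlap count is reported rather than hidden. Journal
names are taken as-is (no alias normalization), and impact factors must
be user-supplied — without them the correlation is an error, not a
silent skip. Pearson and Spearman are two-sided via `cor.test()` (the
Spearman p from the t approximation, tie-safe average ranks) and are
property-tested against direct textbook-formula oracles to six
decimals.

One ambiguity in published prevalence tables is whether "files with
gene lists" counts sheets or files; this package counts files.

## The synthetic corpus generator

`generate_corpus()` is the package's stated world for end-to-end
validation; its defaults encode realistic corpus conditions:

* `gene_column_prob = 0.72` — the observed share of supplementary
  spreadsheets containing gene lists in a large literature screen.
* `class_mix = c("d-mmm" = 0.832, "five-digit-serial" = 0.157,
  "slash-date" = 0.009, "scientific" = 0.002)` — the observed
  error-type composition over affected files.
* `error_rate = 0.05` per vulnerable cell; file sizes 12–28 rows, 1–3
  files per publication, 30% XLSX — plausible supplementary-table
  shapes, chosen once.
* `serial_year = 2019`, `slash_year = 2016`: a month/day conversion
  needs a concrete year to become a serial or slash date; both sit
  inside the screened era.

Gene columns always retain at least five intact symbols so injected
files remain detectable; generation is byte-reproducible from `seed`
and leaves the caller's RNG untouched. XLSX fixtures are written by a
minimal built-in writer (inline strings + date-styled serial cells) and
read back through readxl, so write and read paths are independent.

What the generator does **not** emulate: multi-sheet workbooks with
heterogeneous layouts, merged cells, header blocks above the table,
horizontal gene lists, partially converted columns below the detection
threshold, non-UTF-8 encodings, and the false-positive-inducing
free-text columns of real supplementary files. A green end-to-end test
therefore establishes that the pipeline recovers *injected* errors of
the supported classes with precision and recall 1.0 — not that real
corpora are screened without false positives; that is what the review
report is for.

## Known limitations

* Fully converted short columns are undetectable (threshold counts
  intact symbols only).
* The simulator is a model of conversion behaviour, not an emulation of
  any specific product version; locale tables cover the evidenced
  locales (English, Italian/Spanish/Portuguese, Dutch, Finnish) and are
  user-extensible.
* Five-digit flagging trades precision for recall: a genuine count
  column inside a gene column's rows will be flagged for review.
* XLS reading relies on readxl's legacy parser; XLS writing is not
  supported (fixtures use XLSX/TSV).
* No network code anywhere: article harvesting consumes pre-saved HTML
  only.
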