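Package: genescreen
Title: Detect, Classify and Repair Spreadsheet Gene Name Errors
Version: 0.1.0
Authors@R: person("Deakin", "Curation", email = "curation@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing supplementary gene lists for spreadsheet
    autoconversion errors ("gene name errors"): gene symbols silently turned
    into dates (SEPT7 to 7-Sep), scientific-notation floats (2310009E13 to
    2.31E+19) or five-digit internal date serials (43709). Provides Excel
    1900-system serial date arithmetic, a deterministic simulator of
    spreadsheet autoconversion with locale-aware month tables, a scanner that
    finds gene-symbol columns in XLSX/XLS/CSV/TSV files and flags suspected
    conversions, a repair engine that reverse-maps flagged cells to candidate
    symbols, corpus-level prevalence reporting, and a synthetic-corpus
    generator with ground-truth error manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    readxl,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
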