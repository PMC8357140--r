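# A minimal XLSX writer for fixture generation.
#
# No XLSX-writing package is assumed; an XLSX file is a ZIP of small XML
# parts, and fixtures only need inline strings plus date-styled numeric
# cells, so the whole writer fits here. Entries are deflated with
# memCompress() (a zlib stream; the 2-byte header and Adler32 trailer are
# stripped to get raw deflate data) and the CRC32 the ZIP directory needs
# is computed here. The write path is independent of the readxl read path,
# so round-trip tests check one against the other.

.le <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                  endian = "little")

.crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L) # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1L] <- c
  }
  tab
})

# CRC-32 (IEEE), returned as 4 raw bytes little-endian
.crc32 <- function(data) {
  crc <- -1L # 0xFFFFFFFF
  bytes <- as.integer(data)
  for (b in bytes) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  as.raw(c(bitwAnd(crc, 255L),
           bitwAnd(bitwShiftR(crc, 8L), 255L),
           bitwAnd(bitwShiftR(crc, 16L), 255L),
           bitwAnd(bitwShiftR(crc, 24L), 255L)))
}

.deflate_parts <- function(data) {
  zl <- memCompress(data, type = "gzip") # R returns a zlib stream
  n <- length(zl)
  stopifnot(n >= 7, zl[1] == as.raw(0x78))
  list(deflate = zl[3:(n - 4L)],
       crc = .crc32(data),
       size = length(data))
}

# build a ZIP archive from a named list of raw vectors
.write_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  parts <- lapply(entries, .deflate_parts)
  pos <- 0L
  # local file headers + data
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    p <- parts[[i]]
    offsets[i] <- pos
    hdr <- c(.le(0x04034b50, 4), .le(20, 2), .le(0, 2), .le(8, 2),
             .le(0, 2), .le(0x21, 2), # fixed DOS time/date
             p$crc, .le(length(p$deflate), 4), .le(p$size, 4),
             .le(length(nm), 2), .le(0, 2))
    writeBin(c(hdr, nm, p$deflate), con)
    pos <- pos + length(hdr) + length(nm) + length(p$deflate)
  }
  cd_start <- pos
  # central directory
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    p <- parts[[i]]
    hdr <- c(.le(0x02014b50, 4), .le(20, 2), .le(20, 2), .le(0, 2),
             .le(8, 2), .le(0, 2), .le(0x21, 2),
             p$crc, .le(length(p$deflate), 4), .le(p$size, 4),
             .le(length(nm), 2), .le(0, 2), .le(0, 2), .le(0, 2),
             .le(0, 2), .le(0, 4), .le(offsets[i], 4))
    writeBin(c(hdr, nm), con)
    pos <- pos + length(hdr) + length(nm)
  }
  # end of central directory
  writeBin(c(.le(0x06054b50, 4), .le(0, 2), .le(0, 2),
             .le(length(entries), 2), .le(length(entries), 2),
             .le(pos - cd_start, 4), .le(cd_start, 4), .le(0, 2)), con)
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.col_letter <- function(j) {
  out <- ""
  while (j > 0L) {
    r <- (j - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

.sheet_xml <- function(cells, serial) {
  rows <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cs <- character(0)
    for (j in seq_len(ncol(cells))) {
      ref <- paste0(.col_letter(j), i)
      if (!is.na(serial[i, j])) {
        cs <- c(cs, sprintf('<c r="%s" s="1"><v>%s</v></c>', ref,
                            format(serial[i, j], scientific = FALSE)))
      } else if (nzchar(cells[i, j])) {
        cs <- c(cs, sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
                            ref, .xml_escape(cells[i, j])))
      }
    }
    rows[i] <- sprintf('<row r="%d">%s</row>', i, paste(cs, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/',
         'spreadsheetml/2006/main"><sheetData>',
         paste(rows, collapse = ""), "</sheetData></worksheet>")
}

#' Write a minimal XLSX file
#'
#' Fixture-grade writer: every sheet is a character matrix of display
#' strings written as inline strings, except cells with a non-`NA` entry in
#' the matching `serial` matrix, which are written as date-formatted
#' numeric cells (number format 14) holding the 1900-system serial --
#' exactly how a genuinely date-converted gene name is stored.
#'
#' @param sheets a named list; each element either a character matrix (or
#'   data.frame, coerced) or a list with elements `cells` (character
#'   matrix) and `serial` (numeric matrix, `NA` = not a date cell).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xlsx_fixture <- function(sheets, path) {
  if (is.null(names(sheets)) || any(!nzchar(names(sheets)))) {
    stop("sheets must be a named list")
  }
  norm <- lapply(sheets, function(s) {
    if (is.list(s) && !is.data.frame(s) && !is.null(s$cells)) {
      cells <- as.matrix(s$cells)
      serial <- s$serial
      if (is.null(serial)) serial <- matrix(NA_real_, nrow(cells), ncol(cells))
      list(cells = cells, serial = as.matrix(serial))
    } else {
      cells <- as.matrix(s)
      storage.mode(cells) <- "character"
      cells[is.na(cells)] <- ""
      list(cells = cells, serial = matrix(NA_real_, nrow(cells), ncol(cells)))
    }
  })
  ns <- length(norm)
  xmlns_main <- "http://schemas.openxmlformats.org/spreadsheetml/2006/main"
  xmlns_rel <- "http://schemas.openxmlformats.org/officeDocument/2006/relationships"

  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(ns)), collapse = ""),
    "</Types>")

  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>")

  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(ns), seq_len(ns)), collapse = ""),
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
            ns + 1L),
    "</Relationships>")

  wb <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    sprintf('<workbook xmlns="%s" xmlns:r="%s"><sheets>', xmlns_main, xmlns_rel),
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  .xml_escape(names(norm)), seq_len(ns), seq_len(ns)),
          collapse = ""),
    "</sheets></workbook>")

  styles <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    sprintf('<styleSheet xmlns="%s">', xmlns_main),
    '<fonts count="1"><font/></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="2"><xf numFmtId="0"/>',
    '<xf numFmtId="14" applyNumberFormat="1"/></cellXfs>',
    "</styleSheet>")

  entries <- c(
    list("[Content_Types].xml" = charToRaw(enc2utf8(ct)),
         "_rels/.rels" = charToRaw(enc2utf8(rels)),
         "xl/workbook.xml" = charToRaw(enc2utf8(wb)),
         "xl/_rels/workbook.xml.rels" = charToRaw(enc2utf8(wb_rels)),
         "xl/styles.xml" = charToRaw(enc2utf8(styles))),
    stats::setNames(
      lapply(norm, function(s) charToRaw(enc2utf8(.sheet_xml(s$cells, s$serial)))),
      sprintf("xl/worksheets/sheet%d.xml", seq_len(ns))))

  .write_zip(entries, path)
}
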