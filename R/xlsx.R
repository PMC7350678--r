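# Minimal single-sheet XLSX writer (SpreadsheetML with inline strings).
# No xlsx-writing package is available in the deployment environment, so the
# few structured-table exports are written directly: one sheet, one header
# row, numbers as numeric cells, text as inline strings, missing as empty
# cells.  Readable by readxl and spreadsheet applications.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

col_letter <- function(j) {
  out <- character(length(j))
  for (i in seq_along(j)) {
    n <- j[i]; s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[i] <- s
  }
  out
}

xlsx_cell <- function(ref, value, numeric) {
  if (is.na(value)) return("")
  if (numeric) {
    sprintf('<c r="%s"><v>%s</v></c>', ref, format(value, digits = 15))
  } else {
    sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            ref, xml_escape(as.character(value)))
  }
}

#' Write a data frame to a minimal XLSX file
#'
#' Writes a single worksheet with one header row.  `NA` values become empty
#' cells.  Intended for the structured-table exports; not a general-purpose
#' spreadsheet writer (no styling, no multiple sheets).
#'
#' @param df A data frame.
#' @param path Output path ending in `.xlsx`.
#' @param sheet Worksheet name.
#' @return `path`, invisibly.
#' @export
write_minimal_xlsx <- function(df, path, sheet = "Sheet1") {
  stopifnot(is.data.frame(df))
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'
  ), file.path(tmp, "[Content_Types].xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'
  ), file.path(tmp, "_rels", ".rels"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    sprintf('<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets>',
            xml_escape(sheet)),
    '</workbook>'
  ), file.path(tmp, "xl", "workbook.xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'
  ), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))

  is_num <- vapply(df, is.numeric, logical(1))
  rows <- character(nrow(df) + 1)
  header <- vapply(seq_len(ncol(df)), function(j) {
    xlsx_cell(paste0(col_letter(j), 1), as.character(names(df)[j]), FALSE)
  }, character(1))
  rows[1] <- sprintf('<row r="1">%s</row>', paste(header, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_len(ncol(df)), function(j) {
      xlsx_cell(paste0(col_letter(j), i + 1), df[[j]][i], is_num[j])
    }, character(1))
    rows[i + 1] <- sprintf('<row r="%d">%s</row>', i + 1,
                           paste(cells, collapse = ""))
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', rows, '</sheetData>', '</worksheet>'
  ), file.path(tmp, "xl", "worksheets", "sheet1.xml"))

  members <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
               "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml")
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE),
           files = members, root = tmp, include_directories = FALSE,
           mode = "mirror")
  unlink(tmp, recursive = TRUE)
  invisible(path)
}
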