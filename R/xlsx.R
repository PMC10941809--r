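# Minimal OOXML spreadsheet writer.
#
# The environment ships a reader (readxl) but no XLSX writer, so templates
# are written with a small self-contained implementation: one worksheet,
# inline strings, stored (uncompressed) ZIP entries, fixed timestamps for
# byte-identical output. Readers (readxl, openpyxl, Excel) accept it.

uint_raw <- function(n, bytes) {
  out <- raw(bytes)
  for (i in seq_len(bytes)) {
    out[i] <- as.raw(n %% 256)
    n <- n %/% 256
  }
  out
}

crc32_num <- function(data) {
  hex <- digest::digest(data, algo = "crc32", serialize = FALSE)
  hex <- formatC(hex, width = 8, flag = "0")
  sum(strtoi(substring(hex, seq(1, 7, 2), seq(2, 8, 2)), 16L) *
        256^(3:0))
}

# entries: named list of raw vectors (name = archive path).
write_zip_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  names_raw <- lapply(names(entries), charToRaw)
  # DOS date 1980-01-01, time 00:00 — fixed for determinism
  dostime <- uint_raw(0, 2); dosdate <- uint_raw(33, 2)
  for (i in seq_along(entries)) {
    data <- entries[[i]]; nm <- names_raw[[i]]
    offsets[i] <- pos
    crcs[i] <- crc32_num(data)
    hdr <- c(uint_raw(0x04034b50, 4), uint_raw(20, 2), uint_raw(0, 2),
             uint_raw(0, 2), dostime, dosdate, uint_raw(crcs[i], 4),
             uint_raw(length(data), 4), uint_raw(length(data), 4),
             uint_raw(length(nm), 2), uint_raw(0, 2))
    writeBin(c(hdr, nm, data), con)
    pos <- pos + length(hdr) + length(nm) + length(data)
  }
  cd_start <- pos
  cd_len <- 0
  for (i in seq_along(entries)) {
    data <- entries[[i]]; nm <- names_raw[[i]]
    cd <- c(uint_raw(0x02014b50, 4), uint_raw(20, 2), uint_raw(20, 2),
            uint_raw(0, 2), uint_raw(0, 2), dostime, dosdate,
            uint_raw(crcs[i], 4), uint_raw(length(data), 4),
            uint_raw(length(data), 4), uint_raw(length(nm), 2),
            uint_raw(0, 2), uint_raw(0, 2), uint_raw(0, 2), uint_raw(0, 2),
            uint_raw(0, 4), uint_raw(offsets[i], 4))
    writeBin(c(cd, nm), con)
    cd_len <- cd_len + length(cd) + length(nm)
  }
  eocd <- c(uint_raw(0x06054b50, 4), uint_raw(0, 2), uint_raw(0, 2),
            uint_raw(length(entries), 2), uint_raw(length(entries), 2),
            uint_raw(cd_len, 4), uint_raw(cd_start, 4), uint_raw(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

col_letter <- function(j) {
  out <- character(length(j))
  for (k in seq_along(j)) {
    n <- j[k]; s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

# cells: character matrix incl. header row; NA cells are omitted.
write_xlsx_minimal <- function(cells, path) {
  xml_decl <- "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>\n"
  rows_xml <- vapply(seq_len(nrow(cells)), function(i) {
    cs <- vapply(seq_len(ncol(cells)), function(j) {
      v <- cells[i, j]
      if (is.na(v)) return("")
      sprintf("<c r=\"%s%d\" t=\"inlineStr\"><is><t xml:space=\"preserve\">%s</t></is></c>",
              col_letter(j), i, xml_escape(v))
    }, character(1))
    sprintf("<row r=\"%d\">%s</row>", i, paste0(cs, collapse = ""))
  }, character(1))
  sheet <- paste0(
    xml_decl,
    "<worksheet xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\">",
    "<sheetData>", paste0(rows_xml, collapse = ""), "</sheetData></worksheet>")
  workbook <- paste0(
    xml_decl,
    "<workbook xmlns=\"http://schemas.openxmlformats.org/spreadsheetml/2006/main\" ",
    "xmlns:r=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships\">",
    "<sheets><sheet name=\"Sheet1\" sheetId=\"1\" r:id=\"rId1\"/></sheets></workbook>")
  wb_rels <- paste0(
    xml_decl,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" ",
    "Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet\" ",
    "Target=\"worksheets/sheet1.xml\"/></Relationships>")
  root_rels <- paste0(
    xml_decl,
    "<Relationships xmlns=\"http://schemas.openxmlformats.org/package/2006/relationships\">",
    "<Relationship Id=\"rId1\" ",
    "Type=\"http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument\" ",
    "Target=\"xl/workbook.xml\"/></Relationships>")
  content_types <- paste0(
    xml_decl,
    "<Types xmlns=\"http://schemas.openxmlformats.org/package/2006/content-types\">",
    "<Default Extension=\"rels\" ",
    "ContentType=\"application/vnd.openxmlformats-package.relationships+xml\"/>",
    "<Default Extension=\"xml\" ContentType=\"application/xml\"/>",
    "<Override PartName=\"/xl/workbook.xml\" ",
    "ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml\"/>",
    "<Override PartName=\"/xl/worksheets/sheet1.xml\" ",
    "ContentType=\"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml\"/>",
    "</Types>")
  entries <- list(
    "[Content_Types].xml" = charToRaw(content_types),
    "_rels/.rels" = charToRaw(root_rels),
    "xl/workbook.xml" = charToRaw(workbook),
    "xl/_rels/workbook.xml.rels" = charToRaw(wb_rels),
    "xl/worksheets/sheet1.xml" = charToRaw(sheet))
  write_zip_stored(entries, path)
}
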