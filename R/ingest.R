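# Template file I/O and ontology source parsers.
#
# Templates are tabular: one row per ontology position with a positional
# code, a label, an annotation count and optional hex color / description.
# The TSV dialect is deliberately strict: UTF-8, tab separator, first-row
# header, no quoting (embedded tabs are rejected), so that round trips are
# unambiguous. XLSX uses the first worksheet, first-row header.

CODE_SYNONYMS <- c("code", "id", "tree_number", "atc_code")
LABEL_SYNONYMS <- c("label", "name", "term")
COUNT_SYNONYMS <- c("count", "counts", "value")

match_header <- function(header) {
  h <- tolower(trimws(header))
  find1 <- function(syn) {
    i <- which(h %in% syn)
    if (length(i)) i[1L] else NA_integer_
  }
  list(code = find1(CODE_SYNONYMS), label = find1(LABEL_SYNONYMS),
       count = find1(COUNT_SYNONYMS), color = find1("color"),
       description = find1("description"))
}

# Shared assembly so TSV and XLSX yield identical tables from equivalent
# content: `cells` is a character matrix of the data rows, header separate.
template_from_cells <- function(header, cells) {
  idx <- match_header(header)
  if (is.na(idx$code))
    ob_abort(sprintf("no code column found (accepted headers: %s)",
                     paste(CODE_SYNONYMS, collapse = ", ")), "format_error")
  n <- nrow(cells)
  getcol <- function(i, default) {
    if (is.na(i)) rep(default, n) else {
      v <- cells[, i]
      v[!is.na(v)] <- trimws(v[!is.na(v)])
      v
    }
  }
  code <- getcol(idx$code, NA_character_)
  if (any(is.na(code) | !nzchar(code)))
    ob_abort(sprintf("empty code in data row(s): %s",
                     paste(which(is.na(code) | !nzchar(code)), collapse = ", ")),
             "format_error")
  label <- getcol(idx$label, NA_character_)
  label <- ifelse(is.na(label) | !nzchar(label), code, label)
  cnt_raw <- getcol(idx$count, NA_character_)
  cnt <- suppressWarnings(as.numeric(cnt_raw))
  blank <- is.na(cnt_raw) | !nzchar(cnt_raw)
  cnt[blank] <- 0
  bad <- !blank & is.na(cnt)
  if (any(bad))
    ob_abort(sprintf("unparseable count in row(s) %s: %s",
                     paste(which(bad), collapse = ", "),
                     paste(unique(cnt_raw[bad]), collapse = ", ")),
             "validation_error")
  color <- getcol(idx$color, NA_character_)
  color[!is.na(color) & !nzchar(color)] <- NA_character_
  badc <- !is.na(color) & !is_hex_color(color)
  if (any(badc))
    ob_abort(sprintf("invalid hex color in row(s) %s: %s",
                     paste(which(badc), collapse = ", "),
                     paste(unique(color[badc]), collapse = ", ")),
             "validation_error")
  descr <- getcol(idx$description, NA_character_)
  descr[!is.na(descr) & !nzchar(descr)] <- NA_character_

  extra_idx <- setdiff(seq_along(header), unlist(idx[!is.na(unlist(idx))]))
  extra <- if (length(extra_idx)) {
    e <- as.data.frame(cells[, extra_idx, drop = FALSE],
                       stringsAsFactors = FALSE)
    names(e) <- header[extra_idx]
    e[] <- lapply(e, function(v) ifelse(is.na(v), "", v))
    e
  } else NULL

  structure(list(rows = term_records(code, label, cnt, color, descr),
                 extra_columns = extra),
            class = "template_table")
}

#' @export
print.template_table <- function(x, ...) {
  cat(sprintf("<template_table rows=%d extra_columns=%s>\n", nrow(x$rows),
              if (is.null(x$extra_columns)) "none"
              else paste(names(x$extra_columns), collapse = ",")))
  print(utils::head(x$rows, 10L))
  invisible(x)
}

#' Read a template file (TSV or XLSX)
#'
#' Recognized columns (case-insensitive, with synonyms): code
#' (`id`/`tree_number`/`atc_code`), label (`name`/`term`), count
#' (`counts`/`value`), `color`, `description`. Any other column is carried
#' through verbatim as an extra column. Empty count cells become 0.
#'
#' @param path File path.
#' @param format `"tsv"`, `"xlsx"` or `"auto"` (resolve by extension).
#' @return A `template_table`: list with `rows` (a [term_records()] table)
#'   and `extra_columns` (data.frame or `NULL`).
#' @export
read_template <- function(path, format = c("auto", "tsv", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path))
    ob_abort(sprintf("input file not found: %s", path), "io_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", xlsx = "xlsx",
                     ob_abort(sprintf("cannot infer format from extension '.%s'", ext),
                              "format_error"))
  }
  if (format == "tsv") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) ob_abort("empty template file", "format_error")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    header <- parts[[1L]]
    ncol <- length(header)
    cells <- matrix(NA_character_, nrow = length(parts) - 1L, ncol = ncol)
    for (i in seq_len(length(parts) - 1L)) {
      p <- parts[[i + 1L]]
      if (length(p) > ncol)
        ob_abort(sprintf("row %d has %d fields but header has %d", i,
                         length(p), ncol), "format_error")
      cells[i, seq_along(p)] <- p
    }
    cells[!is.na(cells) & !nzchar(cells)] <- NA_character_
    template_from_cells(header, cells)
  } else {
    df <- readxl::read_excel(path, sheet = 1L, col_types = "text",
                             .name_repair = "minimal")
    template_from_cells(names(df),
                        as.matrix(as.data.frame(df, stringsAsFactors = FALSE)))
  }
}

template_to_cells <- function(table) {
  r <- table$rows
  num_chr <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  base <- cbind(code = r$code, label = r$label, count = num_chr(r$count),
                color = ifelse(is.na(r$color), "", r$color),
                description = ifelse(is.na(r$description), "", r$description))
  if (!is.null(table$extra_columns))
    base <- cbind(base, as.matrix(table$extra_columns))
  base
}

#' Write a template file (TSV or XLSX)
#'
#' Inverse of [read_template()]: reading a written file reproduces the table
#' field for field (counts compared numerically).
#'
#' @param table A `template_table`.
#' @param path Output path.
#' @param format `"tsv"` or `"xlsx"`.
#' @export
write_template <- function(table, path, format = c("tsv", "xlsx")) {
  format <- match.arg(format)
  if (!inherits(table, "template_table") || nrow(table$rows) == 0L)
    ob_abort("cannot write an empty template table", "validation_error")
  cells <- template_to_cells(table)
  if (any(grepl("\t", cells, fixed = TRUE)) && format == "tsv")
    ob_abort("embedded tab in a field; the TSV dialect does not quote",
             "validation_error")
  if (format == "tsv") {
    lines <- c(paste(colnames(cells), collapse = "\t"),
               apply(cells, 1L, paste, collapse = "\t"))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  } else {
    m <- rbind(colnames(cells), cells)
    m[!nzchar(m)] <- NA_character_
    write_xlsx_minimal(m, path)
  }
  invisible(path)
}

obo_read_lines <- function(stream) {
  if (inherits(stream, "connection")) readLines(stream, warn = FALSE)
  else if (length(stream) == 1L && !grepl("\n", stream) && file.exists(stream))
    readLines(stream, warn = FALSE)
  else unlist(strsplit(stream, "\n", fixed = TRUE))
}

#' Parse an OBO ontology into positional term records
#'
#' The `is_a` graph of an OBO 1.2/1.4 file is unfolded into positional
#' codes: every root-to-term path becomes one record whose generic code is
#' the dot-joined sequence of path-local ordinal segments. Ordinals are
#' assigned by sorting sibling term ids lexicographically and zero-padding
#' to three digits, so the unfolding is deterministic. A term reachable
#' along several paths (a DAG diamond) yields one record per path, matching
#' the positional-tree rendering. Obsolete terms are skipped; counts start
#' at 0; the original term id is kept in the description field.
#'
#' @param stream A file path, connection, or character vector of OBO text.
#' @return A [term_records()] table with generic dot codes.
#' @export
parse_obo <- function(stream) {
  lines <- obo_read_lines(stream)
  lines <- sub("\\s*!.*$", "", lines)          # trailing comments
  lines <- trimws(lines)

  terms <- list()
  cur <- NULL; in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id))
      ob_abort("OBO [Term] stanza without an id", "format_error")
    if (!isTRUE(cur$obsolete)) terms[[cur$id]] <<- cur
    invisible()
  }
  for (ln in lines) {
    if (ln == "[Term]") { flush(cur); cur <- list(parents = character()); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:"))
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    else if (startsWith(ln, "is_obsolete:"))
      cur$obsolete <- identical(trimws(sub("^is_obsolete:", "", ln)), "true")
  }
  flush(cur)
  if (!length(terms)) ob_abort("no [Term] stanzas found", "format_error")

  ids <- names(terms)
  # children map, edges to unknown/obsolete parents dropped
  children <- lapply(stats::setNames(ids, ids), function(id) character())
  for (id in ids)
    for (p in intersect(terms[[id]]$parents, ids))
      children[[p]] <- c(children[[p]], id)
  children <- lapply(children, sort, method = "radix")
  roots <- sort(ids[vapply(ids, function(id)
    length(intersect(terms[[id]]$parents, ids)) == 0L, logical(1))],
    method = "radix")

  # cycle check (DFS with colors); a cyclic is_a graph has no valid unfolding
  color <- stats::setNames(rep(0L, length(ids)), ids)
  visit <- function(id, stack) {
    if (color[[id]] == 1L)
      ob_abort(sprintf("cyclic is_a relation involving '%s'", id), "cycle_error")
    if (color[[id]] == 2L) return(invisible())
    color[id] <<- 1L
    for (ch in children[[id]]) visit(ch, stack)
    color[id] <<- 2L
    invisible()
  }
  for (r in roots) visit(r)
  if (any(color == 0L))
    ob_abort(sprintf("cyclic is_a relation involving '%s'",
                     names(color)[color == 0L][1L]), "cycle_error")

  out_code <- character(); out_label <- character(); out_id <- character()
  emit <- function(id, prefix) {
    out_code <<- c(out_code, prefix)
    out_label <<- c(out_label, terms[[id]]$name %||% id)
    out_id <<- c(out_id, id)
    kids <- children[[id]]
    for (k in seq_along(kids))
      emit(kids[k], paste0(prefix, ".", formatC(k, width = 3, flag = "0")))
  }
  for (r in seq_along(roots))
    emit(roots[r], formatC(r, width = 3, flag = "0"))
  term_records(out_code, out_label, 0, NA_character_, out_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse MeSH descriptor XML into term records
#'
#' Reads an NLM `DescriptorRecordSet` XML stream and emits one record per
#' (descriptor, tree number) pair whose tree number starts with
#' `subtree_prefix` (e.g. `"C"` for the Diseases subtree). MeSH is
#' poly-hierarchical: a descriptor with several matching tree numbers
#' yields one record per position, each carrying the descriptor name as
#' label. Descriptors without tree numbers are skipped. Counts start at 0;
#' the DescriptorUI is kept in the description field.
#'
#' @param stream File path, connection, or XML text.
#' @param subtree_prefix Tree-number prefix filter (default `"C"`).
#' @return A [term_records()] table of MeSH tree numbers.
#' @export
parse_mesh_descriptor_xml <- function(stream, subtree_prefix = "C") {
  doc <- tryCatch(xml2::read_xml(stream),
                  error = function(e)
                    ob_abort(sprintf("malformed MeSH XML: %s", conditionMessage(e)),
                             "format_error"))
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  code <- character(); label <- character(); ui <- character()
  for (rec in recs) {
    name <- xml2::xml_text(
      xml2::xml_find_first(rec, "./DescriptorName/String"))
    dui <- xml2::xml_text(xml2::xml_find_first(rec, "./DescriptorUI"))
    tns <- xml2::xml_text(
      xml2::xml_find_all(rec, "./TreeNumberList/TreeNumber"))
    tns <- tns[startsWith(tns, subtree_prefix)]
    if (!length(tns)) next
    code <- c(code, tns)
    label <- c(label, rep(name, length(tns)))
    ui <- c(ui, rep(if (is.na(dui)) "" else dui, length(tns)))
  }
  if (!length(code))
    return(term_records(character(0)))
  term_records(code, label, 0, NA_character_, ifelse(nzchar(ui), ui, NA))
}

#' Parse a flat ATC code/name table into term records
#'
#' Stand-in for an ATC extraction from a drug database export: each row is
#' one (code, name) pair; all counts start at 0 and missing ancestors are
#' synthesized later by [build_forest()].
#'
#' @param rows A data.frame with columns `code` and `name` (or two unnamed
#'   columns in that order).
#' @return A [term_records()] table.
#' @export
parse_atc_flat_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (ncol(rows) < 2L)
    ob_abort("expected columns code, name", "format_error")
  if (!all(c("code", "name") %in% names(rows)))
    names(rows)[1:2] <- c("code", "name")
  code <- toupper(trimws(as.character(rows$code)))
  for (i in seq_along(code)) {
    tryCatch(parse_atc_code(code[i]), error = function(e)
      ob_abort(sprintf("row %d: %s", i, conditionMessage(e)), "malformed_code"))
  }
  dup <- unique(code[duplicated(code)])
  if (length(dup))
    ob_abort(sprintf("duplicate ATC code(s): %s", paste(dup, collapse = ", ")),
             "duplicate_code")
  term_records(code, as.character(rows$name), 0)
}
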