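# Small builders shared across test files.

mini_template <- function() {
  structure(list(rows = make_mini_atc(), extra_columns = NULL),
            class = "template_table")
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# forest from bare (code, count) pairs under the generic grammar
gforest <- function(code, count) {
  build_forest(term_records(code, count = count), "generic")
}

obo_text <- function(...) paste(c("format-version: 1.2", ...), collapse = "\n")

# what a hover string should look like once embedded in markup
xml_escape_for_test <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
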