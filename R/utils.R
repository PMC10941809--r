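# Internal helpers shared across modules.

# Classed conditions so callers (and tests) can catch specific failure modes.
ob_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ontoburst_error"),
                      call = call))
}

is_hex_color <- function(x) {
  !is.na(x) & grepl("^#[0-9A-Fa-f]{6}$", x)
}

#' @noRd
norm_hex <- function(x) toupper(x)

# Locale-independent (C collation) ordering; plot determinism depends on it.
radix_order <- function(...) order(..., method = "radix")

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Count display: integers print bare, fractional values to `digits` decimals.
format_count <- function(x, digits = 2) {
  ifelse(abs(x - round(x)) < 1e-9,
         format(round(x), scientific = FALSE, trim = TRUE),
         formatC(x, format = "f", digits = digits))
}
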