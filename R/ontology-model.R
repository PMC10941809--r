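#' Parse an ATC code
#'
#' The WHO Anatomical Therapeutic Chemical classification places every drug
#' at one of five levels; the level is encoded purely in the code length
#' (1, 3, 4, 5 or 7 characters, e.g. `"J"`, `"J05"`, `"J05A"`, `"J05AB"`,
#' `"J05AB01"`). The parent of a code is the code truncated to the
#' next-shorter valid length.
#'
#' @param code A single non-empty uppercase alphanumeric string.
#' @return A list with elements `level` (integer 1..5) and `parent`
#'   (character, or `NA` for a level-1 code).
#' @examples
#' parse_atc_code("J05AB01") # level 5, parent "J05AB"
#' @export
parse_atc_code <- function(code) {
  if (length(code) != 1L || is.na(code) || !nzchar(code))
    ob_abort("ATC code must be a single non-empty string", "malformed_code")
  if (!grepl("^[A-Z0-9]+$", code))
    ob_abort(sprintf("malformed ATC code '%s': must be uppercase alphanumeric", code),
             "malformed_code")
  lens <- c(1L, 3L, 4L, 5L, 7L)
  n <- nchar(code)
  lvl <- match(n, lens)
  if (is.na(lvl))
    ob_abort(sprintf("malformed ATC code '%s': length %d not in {1,3,4,5,7}", code, n),
             "malformed_code")
  parent <- if (lvl == 1L) NA_character_ else substr(code, 1L, lens[lvl - 1L])
  list(level = lvl, parent = parent)
}

#' Parse a MeSH tree number
#'
#' MeSH positional identifiers are dot-separated segments, e.g.
#' `"C01.925.782"`: the first segment is a category letter plus digits,
#' later segments are digits. The level is the number of segments and the
#' parent drops the last segment.
#'
#' @param tree_number A single tree-number string.
#' @return A list with `level` (integer) and `parent` (character or `NA`).
#' @examples
#' parse_mesh_tree_number("C01.925.782") # level 3, parent "C01.925"
#' @export
parse_mesh_tree_number <- function(tree_number) {
  if (length(tree_number) != 1L || is.na(tree_number) || !nzchar(tree_number))
    ob_abort("MeSH tree number must be a single non-empty string", "malformed_code")
  if (grepl("^\\.|\\.$|\\.\\.", tree_number))
    ob_abort(sprintf("malformed MeSH tree number '%s': empty segment", tree_number),
             "malformed_code")
  segs <- strsplit(tree_number, ".", fixed = TRUE)[[1L]]
  if (!grepl("^[A-Z][0-9]+$", segs[1L]))
    ob_abort(sprintf("malformed MeSH tree number '%s': first segment '%s'",
                     tree_number, segs[1L]), "malformed_code")
  if (length(segs) > 1L && !all(grepl("^[0-9]+$", segs[-1L])))
    ob_abort(sprintf("malformed MeSH tree number '%s': non-digit segment", tree_number),
             "malformed_code")
  parent <- if (length(segs) == 1L) NA_character_ else
    paste(segs[-length(segs)], collapse = ".")
  list(level = length(segs), parent = parent)
}

# GENERIC grammar: dot-separated alphanumeric segments of any content;
# used by the OBO unfolding and the synthetic fixture generator.
parse_generic_code <- function(code) {
  if (length(code) != 1L || is.na(code) || !nzchar(code))
    ob_abort("code must be a single non-empty string", "malformed_code")
  if (grepl("^\\.|\\.$|\\.\\.", code))
    ob_abort(sprintf("malformed code '%s': empty segment", code), "malformed_code")
  segs <- strsplit(code, ".", fixed = TRUE)[[1L]]
  if (!all(grepl("^[A-Za-z0-9]+$", segs)))
    ob_abort(sprintf("malformed code '%s': segments must be alphanumeric", code),
             "malformed_code")
  parent <- if (length(segs) == 1L) NA_character_ else
    paste(segs[-length(segs)], collapse = ".")
  list(level = length(segs), parent = parent)
}

#' Parse a positional ontology code under a given grammar
#'
#' @param code Code string.
#' @param kind One of `"atc"`, `"mesh"`, `"obo"`, `"generic"` (OBO codes use
#'   the generic dot grammar after unfolding).
#' @return A list with `level` and `parent`.
#' @export
parse_code <- function(code, kind) {
  kind <- match.arg(tolower(kind), c("atc", "mesh", "obo", "generic"))
  switch(kind,
         atc = parse_atc_code(code),
         mesh = parse_mesh_tree_number(code),
         parse_generic_code(code))
}

#' Construct a term-record table
#'
#' One row per (code, label, count) input term; the in-memory form of a
#' template row. Counts may be non-integer (e.g. frequencies); absent counts
#' are zero. Colors, when given, must be `#RRGGBB` hex strings.
#'
#' @param code Character vector of positional ontology codes.
#' @param label Display names (defaults to the codes).
#' @param count Non-negative numeric (default 0).
#' @param color Optional hex colors (`NA` = automatic).
#' @param description Optional free text carried into hover labels.
#' @return A `data.frame` of class `term_records`.
#' @export
term_records <- function(code, label = code, count = 0,
                         color = NA_character_, description = NA_character_) {
  n <- length(code)
  count <- rep_len(as.numeric(count), n)
  count[is.na(count)] <- 0
  if (any(count < 0))
    ob_abort("counts must be non-negative", "validation_error")
  color <- rep_len(as.character(color), n)
  bad <- !is.na(color) & !is_hex_color(color)
  if (any(bad))
    ob_abort(sprintf("invalid hex color(s): %s",
                     paste(unique(color[bad]), collapse = ", ")),
             "validation_error")
  out <- data.frame(code = as.character(code),
                    label = rep_len(as.character(label), n),
                    count = count,
                    color = ifelse(is.na(color), NA_character_, norm_hex(color)),
                    description = rep_len(as.character(description), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("term_records", "data.frame")
  out
}

#' Build an ontology forest from term records
#'
#' Every record becomes a node at the level its code dictates. Interior
#' ancestors missing from the input are synthesized with count 0 and a
#' placeholder label equal to their code (flagged `synthetic` so renderers
#' can distinguish them). Nodes are stored in a flat table sorted by code
#' under C collation, which for these prefix grammars is a depth-first
#' pre-order; `propagated_count` starts equal to `raw_count`.
#'
#' ATC codes are uppercased on ingest; MeSH tree numbers are taken verbatim.
#'
#' @param records A `term_records` table (or data.frame with its columns).
#' @param kind Ontology kind: `"atc"`, `"mesh"`, `"obo"` or `"generic"`.
#' @return An object of class `ontology_forest`: a data.frame with columns
#'   `code`, `parent`, `level`, `label`, `raw_count`, `propagated_count`,
#'   `color`, `description`, `synthetic`, plus attributes `kind` and
#'   `max_depth`.
#' @examples
#' f <- build_forest(term_records(c("J", "J05", "J05AB01"), count = c(0, 0, 3)), "atc")
#' subset(f, synthetic) # synthesized "J05A" and "J05AB"
#' @export
build_forest <- function(records, kind) {
  kind <- match.arg(tolower(kind), c("atc", "mesh", "obo", "generic"))
  if (nrow(records) == 0L)
    ob_abort("no records to build a forest from", "validation_error")
  code <- as.character(records$code)
  if (kind == "atc") code <- toupper(code)
  dup <- unique(code[duplicated(code)])
  if (length(dup))
    ob_abort(sprintf("duplicate code(s): %s", paste(dup, collapse = ", ")),
             "duplicate_code")
  parsed <- lapply(code, parse_code, kind = kind)
  level <- vapply(parsed, `[[`, integer(1), "level")
  parent <- vapply(parsed, function(p) as.character(p$parent), character(1))

  nodes <- data.frame(code = code, parent = parent, level = level,
                      label = as.character(records$label),
                      raw_count = as.numeric(records$count),
                      color = if ("color" %in% names(records))
                        as.character(records$color) else NA_character_,
                      description = if ("description" %in% names(records))
                        as.character(records$description) else NA_character_,
                      synthetic = FALSE, stringsAsFactors = FALSE)

  # Synthesize missing ancestors by repeated parent truncation.
  have <- nodes$code
  todo <- setdiff(stats::na.omit(nodes$parent), have)
  while (length(todo)) {
    p <- lapply(todo, parse_code, kind = kind)
    add <- data.frame(code = todo,
                      parent = vapply(p, function(x) as.character(x$parent),
                                      character(1)),
                      level = vapply(p, `[[`, integer(1), "level"),
                      label = todo, raw_count = 0, color = NA_character_,
                      description = NA_character_, synthetic = TRUE,
                      stringsAsFactors = FALSE)
    nodes <- rbind(nodes, add)
    have <- c(have, todo)
    todo <- setdiff(stats::na.omit(add$parent), have)
  }

  nodes <- nodes[radix_order(nodes$code), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$propagated_count <- nodes$raw_count
  nodes <- nodes[, c("code", "parent", "level", "label", "raw_count",
                     "propagated_count", "color", "description", "synthetic")]
  structure(nodes,
            kind = kind,
            max_depth = max(nodes$level),
            class = c("ontology_forest", "data.frame"))
}

#' Flatten a forest back to (code, raw_count) records
#'
#' Inverse of [build_forest()] up to the zero-count ancestors it synthesizes.
#'
#' @param forest An `ontology_forest`.
#' @param keep_synthetic Include synthesized ancestor nodes (default `TRUE`).
#' @return A `term_records` table.
#' @export
flatten_forest <- function(forest, keep_synthetic = TRUE) {
  x <- as.data.frame(forest)
  if (!keep_synthetic) x <- x[!x$synthetic, , drop = FALSE]
  term_records(x$code, x$label, x$raw_count, x$color, x$description)
}

#' @export
print.ontology_forest <- function(x, ...) {
  cat(sprintf("<ontology_forest kind=%s nodes=%d roots=%d max_depth=%d>\n",
              attr(x, "kind"), nrow(x), sum(x$level == 1L), attr(x, "max_depth")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more nodes\n", nrow(x) - 10L))
  invisible(x)
}

# Root codes in deterministic order.
forest_roots <- function(forest) {
  sort(forest$code[forest$level == 1L], method = "radix")
}

# Children codes of `code`, sorted.
forest_children <- function(forest, code) {
  sort(forest$code[!is.na(forest$parent) & forest$parent == code],
       method = "radix")
}
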