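# Independent oracles. These deliberately avoid the package's forest
# machinery: levels come from counting dot segments and descendant tests
# from code-prefix relations, so they can arbitrate what the tree-based
# implementation computes.

# descendant-or-self relation on generic dot codes
oracle_is_desc <- function(code, anc) {
  code == anc | startsWith(code, paste0(anc, "."))
}

oracle_level <- function(code) {
  lengths(gregexpr(".", code, fixed = TRUE)) *
    (regexpr(".", code, fixed = TRUE) > 0) + 1L
}

# expected propagated counts by brute-force subtree summation
oracle_propagate <- function(code, raw, max_level = 1L) {
  lvl <- oracle_level(code)
  vapply(seq_along(code), function(i) {
    if (lvl[i] >= max_level) sum(raw[oracle_is_desc(code, code[i])])
    else raw[i]
  }, numeric(1))
}

# codes surviving drop-empty: a node stays iff some descendant-or-self
# carries a positive effective count
oracle_prune_keep <- function(code, effective) {
  vapply(seq_along(code), function(i)
    any(effective[oracle_is_desc(code, code[i])] > 0), logical(1))
}

# all zero-count ancestors implied by a code set (for round-trip checks)
ancestor_closure <- function(code) {
  out <- character(0)
  for (c in code) {
    segs <- strsplit(c, ".", fixed = TRUE)[[1]]
    for (k in seq_len(length(segs) - 1))
      out <- c(out, paste(segs[1:k], collapse = "."))
  }
  setdiff(unique(out), code)
}
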