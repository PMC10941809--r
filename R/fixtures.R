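# Seeded synthetic ontologies with count annotations, so every transform
# and renderer is testable without downloading MeSH or ATC resources.

#' Specification for a synthetic ontology fixture
#'
#' Counts are drawn from a zero-inflated log-normal (rounded up to at least
#' 1 when positive), echoing the heavy-tailed annotation counts seen in
#' clinical-trial and publication data: most terms carry nothing, a few
#' carry a lot. The default zero-inflation of 0.78 mirrors a drug-class use
#' case in which roughly one in five compounds of a category had been
#' tested in at least one trial.
#'
#' @param n_roots Number of level-1 trees (>= 1).
#' @param depth Tree depth (>= 1).
#' @param branching Integer range `c(min, max)` of children per internal node.
#' @param zero_inflation Probability in \[0,1\] that a node's count is 0.
#' @param meanlog,sdlog Log-normal parameters for positive counts.
#' @param seed Integer seed; identical specs generate identical records.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_roots = 3L, depth = 3L, branching = c(2L, 4L),
                         zero_inflation = 0.78, meanlog = 1.5, sdlog = 1.2,
                         seed = 1L) {
  if (n_roots < 1L || depth < 1L)
    ob_abort("n_roots and depth must be >= 1", "validation_error")
  if (zero_inflation < 0 || zero_inflation > 1)
    ob_abort("zero_inflation must lie in [0,1]", "validation_error")
  branching <- as.integer(rep_len(branching, 2L))
  if (any(branching < 1L) || branching[2L] < branching[1L])
    ob_abort("branching must be an increasing range of positive integers",
             "validation_error")
  structure(list(n_roots = as.integer(n_roots), depth = as.integer(depth),
                 branching = branching, zero_inflation = zero_inflation,
                 meanlog = meanlog, sdlog = sdlog, seed = as.integer(seed)),
            class = "fixture_spec")
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

#' Generate synthetic forest records
#'
#' Produces generic-grammar codes (three-digit dot segments) forming a
#' complete forest of the requested shape, with counts drawn per the
#' fixture distribution. Deterministic for a given spec.
#'
#' @param spec A [fixture_spec()].
#' @return A [term_records()] table that always passes [build_forest()].
#' @examples
#' nrow(generate_forest_records(fixture_spec(1, 2, c(3, 3)))) # 1 + 3 + 9
#' @export
generate_forest_records <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_rng({
    set.seed(spec$seed)
    codes <- character(0)
    frontier <- formatC(seq_len(spec$n_roots), width = 3, flag = "0")
    codes <- frontier
    for (d in seq_len(spec$depth - 1L)) {
      nxt <- character(0)
      for (p in frontier) {
        b <- if (spec$branching[1L] == spec$branching[2L]) spec$branching[1L]
        else sample(spec$branching[1L]:spec$branching[2L], 1L)
        nxt <- c(nxt, paste0(p, ".", formatC(seq_len(b), width = 3, flag = "0")))
      }
      codes <- c(codes, nxt)
      frontier <- nxt
    }
    n <- length(codes)
    zero <- stats::runif(n) < spec$zero_inflation
    cnt <- ifelse(zero, 0,
                  pmax(1, round(stats::rlnorm(n, spec$meanlog, spec$sdlog))))
    term_records(codes, paste0("term ", codes), cnt)
  })
}

#' A hand-written miniature ATC fixture
#'
#' Seventeen nodes from the "Anti-infectives for systemic use" branch with
#' one fully populated five-level chain, an interior node carrying its own
#' raw count, and a designated zero-count decoy leaf (`J01CA08`) that
#' drop-empty pruning must remove. Total raw count is 22.
#'
#' @return A [term_records()] table (ATC grammar).
#' @export
make_mini_atc <- function() {
  term_records(
    code = c("J", "J01", "J01C", "J01CA", "J01CA04", "J01CA08",
             "J02", "J02A", "J02AA", "J02AA01",
             "J05", "J05A", "J05AB", "J05AB01", "J05AB04",
             "J05AF", "J05AF07"),
    label = c("Anti-infectives for systemic use",
              "Antibacterials for systemic use",
              "Beta-lactam antibacterials, penicillins",
              "Penicillins with extended spectrum", "amoxicillin",
              "pivampicillin",
              "Antimycotics for systemic use", "Antimycotics",
              "Antibiotics", "amphotericin B",
              "Antivirals for systemic use", "Direct acting antivirals",
              "Nucleosides and nucleotides", "aciclovir", "ribavirin",
              "Nucleotide analogues", "tenofovir disoproxil"),
    count = c(0, 0, 0, 0, 4, 0,
              0, 0, 0, 1,
              2, 0, 0, 3, 7,
              0, 5))
}
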