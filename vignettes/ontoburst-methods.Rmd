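---
title: "ontoburst: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ontoburst: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoburst)
```

## The positional-tree model

`ontoburst` works on *positional* hierarchies: each node is identified by
a code that encodes its own position, so parenthood is a pure string
relation and no external ontology service is needed.

* **ATC** — level is a function of code length (1/3/4/5/7 characters);
  the parent is the truncation to the next-shorter valid length. Codes are
  uppercased on ingest.
* **MeSH tree numbers** — level is the number of dot-separated segments;
  the parent drops the last segment. Tree numbers are taken verbatim.
  MeSH is poly-hierarchical: a descriptor with several tree numbers
  becomes one node *per position*, each carrying the full count. A
  propagated sum therefore counts such a descriptor once per position —
  the correct semantics for a positional rendering, but a caveat when
  reading root totals as "unique terms".
* **Generic / OBO** — dot-separated alphanumeric segments. An OBO `is_a`
  graph (a DAG) is unfolded into this grammar: every root-to-term path
  becomes one positional node, with ordinals assigned by sorting sibling
  ids lexicographically and zero-padding to three digits, which makes the
  unfolding deterministic. Diamonds in the DAG intentionally duplicate the
  subtree beneath them, as in any positional rendering of a DAG.

`build_forest()` synthesizes any interior ancestor missing from the input
(count 0, label = code) and flags it `synthetic`, because real templates
frequently list only leaves. Children are ordered lexicographically by
code under C collation — the source vocabularies define no display order,
and a fixed order makes plots and JSON exports reproducible byte for byte.

## Count propagation

With `propagation_config(max_level = m, include_self = s)`, every node at
level ≥ *m* receives its full subtree sum; shallower nodes keep their raw
count. Level 1 is the root, so `m = 1` propagates everything upward. The
level convention (counting from the root, not the leaves) is a package
decision; it matches how "propagate up to level *m*" reads in a GUI whose
level selector starts at the root.

`include_self = TRUE` (default) adds a node's own raw count to its
children's sums. Interior terms do carry their own annotations (a drug
*class* can itself be the subject of a trial or paper), and discarding
them would silently break conservation. With the default, conservation is
exact: each root's propagated count equals the raw total of its tree. The
`include_self = FALSE` alternative reports pure child sums; note that it
makes a positive leaf display 0, so combining it with pruning is order
sensitive (see below).

Counts are floating point throughout — frequencies and scores are valid
inputs — and are displayed with two decimals unless integral.

## Pruning and pipeline order

`drop_empty()` iteratively removes leaves whose *effective* (propagated)
count is zero until a fixpoint, so an entirely unannotated subtree
disappears including its interior nodes. It never removes a node with a
positive effective count, and it is idempotent.

The canonical pipeline is **propagate → drop_empty → assign_colors**:
propagation feeds both the pruning decision and the color normalization.
With the default self-inclusive propagation the reversed order
(prune, then propagate) happens to yield the same forest, because a zero
leaf contributes nothing to any sum; with `include_self = FALSE` the two
orders genuinely differ (a positive leaf displays 0 and is pruned only in
canonical order), which the test suite demonstrates on a crafted fixture.

## Color scaling

A `color_scale()` is an ordered list of (position, `#RRGGBB`) stops with
positions strictly increasing from 0 to 1. Positions are *normalized
fractions* of the maximum effective count in the forest, not absolute
counts: the source GUI does not document which of the two its thresholds
are, and normalized stops keep one scale meaningful across data sets of
any magnitude. Normalization is global across the forest by default so
that wedge colors are comparable between branches; `per_branch = TRUE`
exposes the alternative. Interpolation is linear per RGB channel with
channels rounded half-away-from-zero — a fixed rounding rule so the same
input produces identical hex strings on every platform. Manual colors
given in the template always override automatic coloring, and an all-zero
forest uniformly receives the position-0 color.

## Rendering

`build_plot_spec()` produces renderer-agnostic parallel arrays (id,
parent, label, value, color, hover text) per level-1 branch — one sunburst
per branch mirrors the single-branch drill-down view of the original
tool; the tiled summary view arranges all branches row-major with a
configurable number of plots per row (`ceiling(n / per_row)` rows, last
row partial). Wedge angular span is proportional to effective count among
siblings. Zero-count siblings retained when pruning is off share equally
whatever span the positive siblings leave unused, so empty wedges stay
visible; when children sum above their parent's value (possible when
propagation is off), spans are rescaled by the child sum instead.

HTML export draws the wedges as inline SVG with native tooltips and a
small inline script — no charting runtime is fetched, so the file
contains no `http(s)` reference at all and renders offline. The JSON
export (`spec_version` 1) is the lossless, byte-stable serialization used
by the tests; HTML is presentation only.

## The synthetic generator

`generate_forest_records()` emulates the statistical shape of real
annotation data: complete trees of configurable depth and branching with
counts from a zero-inflated rounded log-normal. Defaults state a world
anchored in the package's motivating use cases: `zero_inflation = 0.78`
(in the COVID-19/ATC example roughly 22% of compounds of a drug class had
at least one trial, so 78% of terms carry nothing) and
`meanlog = 1.5, sdlog = 1.2` (median ≈ 4–5 annotations among annotated
terms, with a heavy right tail reaching the hundreds — trial-count-like).
What the generator does **not** emulate: real label text, the uneven
branching of real vocabularies (ATC fans out 14 → thousands), MeSH
poly-hierarchy, or correlated counts between sibling terms. A green test
therefore establishes algorithmic correctness on tree-shaped inputs of
realistic sparsity and skew, not fidelity to any specific vocabulary;
grammar handling for the real vocabularies is covered separately by
ATC/MeSH fixtures.

## Numerical and degenerate-input choices

* Sums are plain double-precision additions in deterministic (deepest
  level first, code-sorted) order; oracle comparisons in the tests are
  exact, which double addition of these magnitudes supports.
* Ties and ordering: all sibling order is lexicographic by code, radix
  (C-locale) sorted, never locale dependent.
* Empty forest: `build_forest()` refuses empty record sets;
  `build_plot_spec()` and the exporters refuse empty inputs with an
  `empty_output` error rather than writing a blank artifact.
* An all-zero forest renders with equal-split wedges and uniform
  position-0 color.
* XLSX output is written by a minimal built-in OOXML writer (stored-entry
  ZIP, inline strings, fixed timestamps) because the environment provides
  a reader but no writer; output is deliberately byte-stable and is
  verified against an independent reader in the tests.

## Known limitations

* Name-to-code resolution is out of scope: inputs must already carry ATC
  codes or MeSH tree numbers. (The original tool's minimum input of bare
  term names implies a resolution table it does not document.)
* MeSH supplementary concept records are not modeled; only descriptor
  tree numbers are.
* Static raster export is delegated to the browser (print/save from the
  opened HTML).
* The OBO unfolding duplicates DAG subtrees by design; for heavily
  multi-parent ontologies the positional forest can be much larger than
  the term count.
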