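# ontoburst

Interactive sunburst visualization of ranked drug and disease lists on
hierarchical ontologies.

## The problem

Drug-repositioning and literature-mining studies routinely produce long
ranked lists — "number of COVID-19 clinical trials per compound", "number
of publications per disease term". Such lists only become interpretable
when placed back into the hierarchy the terms come from: the WHO
**ATC** drug classification (14 anatomical main groups, five levels, codes
of length 1/3/4/5/7 such as `J05AB01`) or the NLM **MeSH** disease subtree
(23 top-level disease categories, poly-hierarchical dot-separated tree
numbers such as `C01.925.782`). `ontoburst` turns a flat table of
`(code, label, count)` rows into per-branch or tiled-summary **sunburst
plots** — radial treemaps where each ring is one hierarchy level and wedge
angle encodes a term's annotation count — exported as self-contained
interactive HTML, with no network access required to build or view them.

The core operations are:

* **Forest building** — every code is parsed under its ontology grammar,
  missing interior ancestors are synthesized with count 0, children are
  kept in deterministic (lexicographic) order.
* **Count propagation** — bottom-up subtree summation
  `propagated(n) = raw(n) + Σ propagated(children(n))`, applied to all
  nodes at or below a chosen level (level 1 = root, i.e. propagate all the
  way up). Conservation holds by construction: each root's propagated
  count equals the raw total of its tree.
* **Drop-empty pruning** — iterated removal of zero-count leaves to a
  fixpoint, so entirely unannotated subtrees vanish.
* **Color scaling** — counts normalized by the forest-wide maximum and
  linearly interpolated per RGB channel across user-defined stops;
  manually specified `#RRGGBB` colors always win.

Also included: TSV/XLSX template readers and writers, an OBO `is_a`-graph
unfolder, a MeSH descriptor XML parser, a flat ATC table reader, a seeded
synthetic-ontology generator, and a CLI covering every option end to end.

## Worked example

```r
library(ontoburst)

recs <- make_mini_atc()                      # 17-node anti-infectives fixture
f <- build_forest(recs, "atc")
f <- propagate_counts(f, propagation_config(max_level = 1))
f <- drop_empty(f)
f <- assign_colors(f, color_scale(c(0, 0.5, 1),
                                  c("#FFFFFF", "#FFA500", "#FF0000")))
print(f)
```

```
<ontology_forest kind=atc nodes=16 roots=1 max_depth=5>
      code parent level                                   label raw_count
1        J   <NA>     1        Anti-infectives for systemic use         0
2      J01      J     2         Antibacterials for systemic use         0
3     J01C    J01     3 Beta-lactam antibacterials, penicillins         0
4    J01CA   J01C     4      Penicillins with extended spectrum         0
5  J01CA04  J01CA     5                             amoxicillin         4
...
   propagated_count   color
1                22 #FF0000
2                 4 #FFDEA2
...
11               17 #FF4B00
```

The fixture's 22 raw annotations all reach the root `J` (conservation);
the zero-count decoy leaf `J01CA08` was pruned (17 → 16 nodes); the
antivirals class `J05` shows 17 = its own 2 interior annotations plus 15
from its compounds, and is colored near the red end of the scale. Then:

```r
specs <- build_plot_spec(f, plot_config(title = "COVID-19 trials, mini ATC"))
export_html(specs, "mini.html")   # 6.8 kB, no external references
export_json(specs, "mini.json")   # lossless, byte-stable spec
```

Equivalent CLI run:

```sh
ontoburst --input mini.tsv --kind atc --propagate --drop-empty \
  --color-scale "0:#FFFFFF,0.5:#FFA500,1:#FF0000" \
  --summary --plots-per-row 5 --out-html mini.html
```

(the launcher lives at `system.file("exec", "ontoburst", package = "ontoburst")`;
`run_cli()` is the same entry point from R).

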