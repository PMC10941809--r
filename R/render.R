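# Sunburst plot specifications and export.
#
# The renderer is split in two layers: build_plot_spec() turns a forest
# into renderer-agnostic parallel arrays (one spec per level-1 branch),
# which serialize losslessly to JSON; export_html() draws them as SVG
# sunbursts in a single self-contained file with no external resources.

#' Plot appearance settings
#'
#' @param summary Tile all branch sunbursts into one grid view (`TRUE`) or
#'   one plot per branch.
#' @param plots_per_row Sunbursts per grid row in summary view.
#' @param show_labels `"none"`, `"all"`, or a positive integer L = show
#'   labels only for levels 1..L.
#' @param border_enabled,border_color,border_width Wedge border settings.
#' @param drop_empty Snapshot of whether empty nodes were pruned.
#' @param title Plot title.
#' @return A `plot_config` list.
#' @export
plot_config <- function(summary = TRUE, plots_per_row = 5L,
                        show_labels = "all", border_enabled = TRUE,
                        border_color = "#FFFFFF", border_width = 1,
                        drop_empty = TRUE, title = "") {
  plots_per_row <- as.integer(plots_per_row)
  if (is.na(plots_per_row) || plots_per_row < 1L)
    ob_abort("plots_per_row must be >= 1", "config_error")
  if (is.numeric(show_labels)) {
    show_labels <- as.integer(show_labels)
    if (is.na(show_labels) || show_labels < 1L)
      ob_abort("show_labels level must be >= 1", "config_error")
  } else {
    show_labels <- match.arg(show_labels, c("all", "none"))
  }
  if (!is_hex_color(border_color))
    ob_abort(sprintf("invalid border color '%s'", border_color), "config_error")
  border_width <- as.numeric(border_width)
  if (is.na(border_width) || border_width < 0)
    ob_abort("border width must be >= 0", "config_error")
  structure(list(summary = isTRUE(summary), plots_per_row = plots_per_row,
                 show_labels = show_labels,
                 border = list(enabled = isTRUE(border_enabled),
                               color = norm_hex(border_color),
                               width = border_width),
                 drop_empty = isTRUE(drop_empty), title = as.character(title)),
            class = "plot_config")
}

label_visible <- function(policy, level) {
  if (identical(policy, "all")) rep(TRUE, length(level))
  else if (identical(policy, "none")) rep(FALSE, length(level))
  else level <= policy
}

#' Build sunburst plot specifications from a forest
#'
#' Emits one `plot_spec` per level-1 branch, ordered by root code. Within a
#' spec, nodes are in depth-first order with children sorted by code.
#' Suppressed labels become empty strings but wedges keep their hover
#' text (`label | code | count` plus the description when present).
#'
#' @param forest A transformed `ontology_forest`.
#' @param config A [plot_config()].
#' @return A `plot_spec_list` of `plot_spec` objects, each holding parallel
#'   vectors `node_id`, `parent_id`, `label`, `value`, `color`,
#'   `hover_text`, plus `branch_root_label` and the config snapshot.
#' @export
build_plot_spec <- function(forest, config = plot_config()) {
  stopifnot(inherits(forest, "ontology_forest"))
  if (nrow(forest) == 0L)
    ob_abort("forest is empty; nothing to plot", "empty_output")
  roots <- forest_roots(forest)
  specs <- lapply(roots, function(r) {
    # depth-first expansion, children by code
    ord <- character(0)
    stack <- r
    while (length(stack)) {
      cur <- stack[1L]; stack <- stack[-1L]
      ord <- c(ord, cur)
      stack <- c(forest_children(forest, cur), stack)
    }
    i <- match(ord, forest$code)
    level <- forest$level[i]
    vis <- label_visible(config$show_labels, level)
    hover <- paste0(forest$label[i], " | ", forest$code[i], " | ",
                    format_count(forest$propagated_count[i]),
                    ifelse(is.na(forest$description[i]), "",
                           paste0(" | ", forest$description[i])))
    structure(list(
      node_id = forest$code[i],
      parent_id = ifelse(is.na(forest$parent[i]), "", forest$parent[i]),
      label = ifelse(vis, forest$label[i], ""),
      value = as.numeric(forest$propagated_count[i]),
      color = ifelse(is.na(forest$color[i]), "#CCCCCC", forest$color[i]),
      hover_text = hover,
      branch_root_label = forest$label[match(r, forest$code)],
      config = config), class = "plot_spec")
  })
  structure(specs, class = "plot_spec_list")
}

#' @export
print.plot_spec <- function(x, ...) {
  cat(sprintf("<plot_spec branch='%s' nodes=%d>\n", x$branch_root_label,
              length(x$node_id)))
  invisible(x)
}

#' Arrange branch sunbursts in a summary grid
#'
#' Row-major tiling: `ceiling(n / plots_per_row)` rows, the last possibly
#' partial; each cell is annotated with its branch root label.
#'
#' @param specs A `plot_spec_list` (from [build_plot_spec()]).
#' @param plots_per_row Plots per row (>= 1).
#' @return A `grid_layout`: the specs plus `rows`, a list of index vectors.
#' @examples
#' # 14 ATC branches at 5 per row tile as rows of 5, 5, 4
#' @export
layout_summary <- function(specs, plots_per_row = 5L) {
  plots_per_row <- as.integer(plots_per_row)
  if (is.na(plots_per_row) || plots_per_row < 1L)
    ob_abort("plots_per_row must be >= 1", "config_error")
  if (!length(specs))
    ob_abort("no plot specs to lay out", "empty_output")
  n <- length(specs)
  n_rows <- ceiling(n / plots_per_row)
  rows <- split(seq_len(n), ceiling(seq_len(n) / plots_per_row))
  structure(list(specs = specs, plots_per_row = plots_per_row,
                 n_rows = as.integer(n_rows), rows = unname(rows),
                 cell_labels = vapply(specs, `[[`, character(1),
                                      "branch_root_label")),
            class = "grid_layout")
}

as_layout <- function(x) {
  if (inherits(x, "grid_layout")) return(x)
  if (inherits(x, "plot_spec"))
    x <- structure(list(x), class = "plot_spec_list")
  if (inherits(x, "plot_spec_list"))
    return(layout_summary(x, x[[1L]]$config$plots_per_row))
  ob_abort("expected a plot_spec, plot_spec_list or grid_layout", "config_error")
}

serialize_spec <- function(s) {
  list(branch_root_label = s$branch_root_label,
       config = list(summary = s$config$summary,
                     plots_per_row = s$config$plots_per_row,
                     show_labels = as.character(s$config$show_labels),
                     border = s$config$border,
                     drop_empty = s$config$drop_empty,
                     title = s$config$title),
       nodes = list(node_id = s$node_id, parent_id = s$parent_id,
                    label = s$label, value = s$value, color = s$color,
                    hover_text = s$hover_text))
}

deserialize_spec <- function(j) {
  sl <- j$config$show_labels
  if (grepl("^[0-9]+$", sl)) sl <- as.integer(sl)
  cfg <- plot_config(summary = j$config$summary,
                     plots_per_row = j$config$plots_per_row,
                     show_labels = sl,
                     border_enabled = j$config$border$enabled,
                     border_color = j$config$border$color,
                     border_width = j$config$border$width,
                     drop_empty = j$config$drop_empty,
                     title = j$config$title)
  structure(list(node_id = as.character(j$nodes$node_id),
                 parent_id = as.character(j$nodes$parent_id),
                 label = as.character(j$nodes$label),
                 value = as.numeric(j$nodes$value),
                 color = as.character(j$nodes$color),
                 hover_text = as.character(j$nodes$hover_text),
                 branch_root_label = j$branch_root_label,
                 config = cfg), class = "plot_spec")
}

#' Export plot specifications as JSON
#'
#' Lossless, versioned (`spec_version: 1`) serialization of the plot
#' arrays and configuration; identical input yields byte-identical output.
#'
#' @param x A `plot_spec`, `plot_spec_list` or `grid_layout`.
#' @param path Output path.
#' @seealso [read_plot_json()]
#' @export
export_json <- function(x, path) {
  layout <- as_layout(x)
  obj <- list(spec_version = 1L,
              plots_per_row = layout$plots_per_row,
              specs = lapply(layout$specs, serialize_spec))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON plot specification back
#'
#' @param path Path written by [export_json()].
#' @return A `grid_layout` equal to the exported one.
#' @export
read_plot_json <- function(path) {
  j <- jsonlite::read_json(path)
  if (!identical(j$spec_version, 1L) && !identical(j$spec_version, 1))
    ob_abort("unsupported spec_version", "format_error")
  specs <- structure(lapply(j$specs, deserialize_spec), class = "plot_spec_list")
  layout_summary(specs, as.integer(j$plots_per_row))
}

# ---- SVG sunburst geometry ----------------------------------------------

polar_xy <- function(cx, cy, r, a) {
  c(cx + r * cos(a), cy - r * sin(a))  # SVG y grows downward
}

wedge_path <- function(cx, cy, r0, r1, a0, a1) {
  full <- abs((a1 - a0) - 2 * pi) < 1e-9
  if (full) {
    # annulus drawn as two half rings to avoid degenerate arcs
    p <- function(r) sprintf(
      "M %.3f %.3f A %.3f %.3f 0 1 0 %.3f %.3f A %.3f %.3f 0 1 0 %.3f %.3f",
      cx + r, cy, r, r, cx - r, cy, r, r, cx + r, cy)
    if (r0 <= 1e-9) return(p(r1))
    return(paste(p(r1), p(r0)))
  }
  large <- as.integer((a1 - a0) > pi)
  o0 <- polar_xy(cx, cy, r1, a0); o1 <- polar_xy(cx, cy, r1, a1)
  if (r0 <= 1e-9) {
    return(sprintf("M %.3f %.3f L %.3f %.3f A %.3f %.3f 0 %d 0 %.3f %.3f Z",
                   cx, cy, o0[1], o0[2], r1, r1, large, o1[1], o1[2]))
  }
  i0 <- polar_xy(cx, cy, r0, a0); i1 <- polar_xy(cx, cy, r0, a1)
  sprintf("M %.3f %.3f A %.3f %.3f 0 %d 0 %.3f %.3f L %.3f %.3f A %.3f %.3f 0 %d 1 %.3f %.3f Z",
          o0[1], o0[2], r1, r1, large, o1[1], o1[2],
          i1[1], i1[2], r0, r0, large, i0[1], i0[2])
}

# Angular intervals: children partition the parent's span proportionally to
# their effective values; zero-value siblings equally share whatever span
# the positive values leave unused, so retained empty wedges stay visible.
spec_angles <- function(spec) {
  n <- length(spec$node_id)
  a0 <- numeric(n); a1 <- numeric(n)
  root <- which(spec$parent_id == "")[1L]
  a0[root] <- 0; a1[root] <- 2 * pi
  kids_of <- split(seq_len(n), spec$parent_id)
  assign_children <- function(p) {
    ks <- kids_of[[spec$node_id[p]]]
    if (is.null(ks)) return(invisible())
    span <- a1[p] - a0[p]
    vals <- spec$value[ks]
    denom <- max(spec$value[p], sum(vals))
    w <- if (denom > 0) span * vals / denom else numeric(length(ks))
    residual <- span - sum(w)
    zero <- vals == 0
    if (any(zero)) w[zero] <- residual / sum(zero)
    else if (denom == 0) w <- rep(span / length(ks), length(ks))
    start <- a0[p] + c(0, cumsum(w))[seq_along(ks)]
    a0[ks] <<- start; a1[ks] <<- start + w
    for (k in ks) assign_children(k)
    invisible()
  }
  assign_children(root)
  list(a0 = a0, a1 = a1)
}

spec_to_svg <- function(spec, size = 420) {
  n <- length(spec$node_id)
  lev <- integer(n)
  idx <- match(spec$parent_id, spec$node_id)
  for (i in seq_len(n)) lev[i] <- if (spec$parent_id[i] == "") 1L else lev[idx[i]] + 1L
  L <- max(lev)
  cx <- size / 2; cy <- size / 2
  t <- (size / 2 - 6) / L
  ang <- spec_angles(spec)
  b <- spec$config$border
  stroke <- if (b$enabled && b$width > 0)
    sprintf(" stroke=\"%s\" stroke-width=\"%.3g\"", b$color, b$width)
  else " stroke=\"none\""
  paths <- vapply(seq_len(n), function(i) {
    r0 <- (lev[i] - 1L) * t; r1 <- lev[i] * t
    d <- wedge_path(cx, cy, r0, r1, ang$a0[i], ang$a1[i])
    lbl <- ""
    if (nzchar(spec$label[i]) && (ang$a1[i] - ang$a0[i]) > 0.02) {
      mid <- (ang$a0[i] + ang$a1[i]) / 2
      rm <- if (lev[i] == 1L) 0 else (r0 + r1) / 2
      xy <- polar_xy(cx, cy, rm, mid)
      lbl <- sprintf(paste0("<text x=\"%.1f\" y=\"%.1f\" text-anchor=\"middle\" ",
                            "dominant-baseline=\"middle\" font-size=\"8\">%s</text>"),
                     xy[1], xy[2], xml_escape(spec$label[i]))
    }
    sprintf("<path class=\"w\" d=\"%s\" fill=\"%s\"%s fill-rule=\"evenodd\"><title>%s</title></path>%s",
            d, spec$color[i], stroke, xml_escape(spec$hover_text[i]), lbl)
  }, character(1))
  # no xmlns: inline SVG in HTML5 needs none, and the output must contain
  # no http(s) references at all (self-containment is scanned for)
  sprintf("<svg viewBox=\"0 0 %d %d\" width=\"%d\" height=\"%d\">%s</svg>",
          size, size, size, size, paste0(paths, collapse = ""))
}

#' Export sunbursts as a self-contained interactive HTML file
#'
#' Writes a single HTML document with one SVG sunburst per branch, tiled
#' per the layout's `plots_per_row`. All styling and scripting is inlined:
#' the file references no external resources and renders offline. Wedges
#' show their hover text as native tooltips and highlight on mouse-over.
#'
#' @param x A `plot_spec`, `plot_spec_list` or `grid_layout`.
#' @param path Output `.html` path.
#' @param title Optional page title (defaults to the config title).
#' @export
export_html <- function(x, path, title = NULL) {
  layout <- as_layout(x)
  if (!length(layout$specs))
    ob_abort("empty layout; nothing to export", "empty_output")
  title <- title %||% layout$specs[[1L]]$config$title
  if (!nzchar(title)) title <- "Ontology sunburst"
  cells <- vapply(seq_along(layout$specs), function(i) {
    s <- layout$specs[[i]]
    sprintf("<figure><figcaption>%s</figcaption>%s</figure>",
            xml_escape(s$branch_root_label), spec_to_svg(s))
  }, character(1))
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>", xml_escape(title), "</title>\n",
    "<style>body{font-family:sans-serif;margin:16px}",
    ".grid{display:grid;grid-template-columns:repeat(",
    layout$plots_per_row, ",auto);gap:12px}",
    "figure{margin:0;text-align:center}figcaption{font-size:13px;font-weight:bold}",
    ".w:hover{opacity:0.75;cursor:pointer}</style>\n</head>\n<body>\n",
    "<h2>", xml_escape(title), "</h2>\n<div class=\"grid\">\n",
    paste0(cells, collapse = "\n"),
    "\n</div>\n<script>",
    "document.querySelectorAll('.w').forEach(function(p){",
    "p.addEventListener('mouseenter',function(){p.setAttribute('opacity','0.75');});",
    "p.addEventListener('mouseleave',function(){p.removeAttribute('opacity');});",
    "});</script>\n</body>\n</html>\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(html, con, useBytes = TRUE)
  invisible(path)
}
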