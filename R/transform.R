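# Pure transforms on an ontology forest: bottom-up count propagation with a
# level cutoff, iterative pruning of empty subtrees, and threshold-based
# color resolution. Canonical pipeline order is
# propagate -> drop_empty -> assign_colors, since propagated values feed
# both the pruning decision and the color normalization.

#' Define a color scale
#'
#' Ordered stops of (normalized position, hex color) defining the
#' thresholds for automatic color coding. Positions are fractions of the
#' maximum effective count in the forest, not absolute counts: position 0
#' is "no annotations", position 1 is "the most annotated term".
#'
#' @param positions Numeric vector in \[0,1\], strictly increasing, starting
#'   at 0 and ending at 1; at least two values.
#' @param colors Hex colors (`#RRGGBB`), one per position.
#' @return An object of class `color_scale`.
#' @examples
#' color_scale(c(0, 0.5, 1), c("#FFFFFF", "#FFA500", "#FF0000"))
#' @export
color_scale <- function(positions = c(0, 1),
                        colors = c("#FFFFFF", "#FF0000")) {
  positions <- as.numeric(positions)
  colors <- as.character(colors)
  if (length(positions) < 2L || length(positions) != length(colors))
    ob_abort("a color scale needs >= 2 (position, color) stops", "validation_error")
  if (positions[1L] != 0 || positions[length(positions)] != 1 ||
      any(diff(positions) <= 0))
    ob_abort("stop positions must strictly increase from 0 to 1", "validation_error")
  if (!all(is_hex_color(colors)))
    ob_abort(sprintf("invalid hex color(s): %s",
                     paste(colors[!is_hex_color(colors)], collapse = ", ")),
             "validation_error")
  structure(list(positions = positions, colors = norm_hex(colors)),
            class = "color_scale")
}

#' @export
print.color_scale <- function(x, ...) {
  cat("<color_scale>", paste(sprintf("%.3g:%s", x$positions, x$colors),
                             collapse = " "), "\n")
  invisible(x)
}

#' Interpolate a color on a scale
#'
#' Locates the bracketing stops for `v` and interpolates linearly per RGB
#' channel; channels are rounded half-away-from-zero so output is identical
#' across platforms.
#'
#' @param scale A [color_scale()].
#' @param v Number(s) in \[0,1\].
#' @return Uppercase `#RRGGBB` string(s).
#' @examples
#' interpolate_color(color_scale(), 0.5) # "#FF8080"
#' @export
interpolate_color <- function(scale, v) {
  stopifnot(inherits(scale, "color_scale"))
  if (any(is.na(v)) || any(v < 0) || any(v > 1))
    ob_abort("interpolation position must lie in [0,1]", "domain_error")
  rgb <- t(vapply(scale$colors, function(h)
    strtoi(substring(h, c(2, 4, 6), c(3, 5, 7)), 16L), integer(3)))
  vapply(v, function(x) {
    i <- findInterval(x, scale$positions, rightmost.closed = TRUE)
    p0 <- scale$positions[i]; p1 <- scale$positions[i + 1L]
    t <- (x - p0) / (p1 - p0)
    ch <- rgb[i, ] + t * (rgb[i + 1L, ] - rgb[i, ])
    ch <- floor(ch + 0.5)  # half-away-from-zero; channels are >= 0
    sprintf("#%02X%02X%02X", ch[1L], ch[2L], ch[3L])
  }, character(1))
}

#' Propagation settings
#'
#' @param enabled Run propagation at all (`FALSE` leaves counts untouched).
#' @param max_level Levels at or deeper than this receive propagated
#'   subtree sums; shallower levels keep their raw counts. Level 1 is the
#'   tree root, so `max_level = 1` propagates all the way up.
#' @param include_self Add a node's own raw count to its children's sums
#'   (default `TRUE`), so annotations placed on interior terms are not lost.
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(enabled = TRUE, max_level = 1L,
                               include_self = TRUE) {
  max_level <- as.integer(max_level)
  if (is.na(max_level) || max_level < 1L)
    ob_abort("max_level must be an integer >= 1", "validation_error")
  structure(list(enabled = isTRUE(enabled), max_level = max_level,
                 include_self = isTRUE(include_self)),
            class = "propagation_config")
}

#' Propagate counts up the ontology
#'
#' Bottom-up summation: every node at level >= `config$max_level` gets
#' `propagated_count = raw_count + sum(children's propagated_count)`
#' (its full subtree sum); shallower nodes keep `propagated_count =
#' raw_count`. With `include_self = FALSE` a node's own raw count is
#' excluded from what it passes upward and from its own displayed sum.
#' Idempotent; a disabled config is the identity.
#'
#' @param forest An `ontology_forest`.
#' @param config A [propagation_config()].
#' @return The forest with `propagated_count` updated.
#' @export
propagate_counts <- function(forest, config = propagation_config()) {
  stopifnot(inherits(forest, "ontology_forest"))
  if (!config$enabled) {
    forest$propagated_count <- forest$raw_count
    return(forest)
  }
  # full subtree sums S = raw + sum(children's S), deepest level first
  subtree <- forest$raw_count
  idx_by_parent <- match(forest$parent, forest$code)
  for (lvl in sort(unique(forest$level), decreasing = TRUE)) {
    at <- which(forest$level == lvl & !is.na(idx_by_parent))
    if (length(at)) {
      sums <- tapply(subtree[at], idx_by_parent[at], sum)
      tgt <- as.integer(names(sums))
      subtree[tgt] <- subtree[tgt] + as.numeric(sums)
    }
  }
  if (!config$include_self) subtree <- subtree - forest$raw_count
  forest$propagated_count <- ifelse(forest$level >= config$max_level,
                                    subtree, forest$raw_count)
  forest
}

#' Drop empty subtrees
#'
#' Iteratively removes leaves whose effective (propagated) count is zero
#' until a fixpoint: interior nodes whose entire subtree carries no
#' annotations vanish with it. Never removes a node with a positive
#' effective count; idempotent.
#'
#' @param forest An `ontology_forest`.
#' @return The pruned forest.
#' @export
drop_empty <- function(forest) {
  stopifnot(inherits(forest, "ontology_forest"))
  repeat {
    has_child <- forest$code %in% forest$parent
    rm <- !has_child & forest$propagated_count == 0
    if (!any(rm)) break
    forest <- forest[!rm, , drop = FALSE]
  }
  attr(forest, "max_depth") <- if (nrow(forest)) max(forest$level) else 0L
  forest
}

#' Resolve node colors
#'
#' Normalizes each node's effective count by the forest-wide maximum and
#' interpolates on the scale. Manual colors from the input template always
#' win over automatic coloring. If every count is zero, all nodes get the
#' scale's position-0 color. Normalization is global across the forest so
#' colors are comparable between branches; set `per_branch = TRUE` to
#' normalize within each level-1 branch instead.
#'
#' @param forest An `ontology_forest` (optionally propagated/pruned).
#' @param scale A [color_scale()].
#' @param per_branch Normalize per level-1 branch rather than globally.
#' @return The forest with its `color` column fully resolved.
#' @export
assign_colors <- function(forest, scale = color_scale(), per_branch = FALSE) {
  stopifnot(inherits(forest, "ontology_forest"))
  if (!nrow(forest)) return(forest)
  eff <- forest$propagated_count
  denom <- if (per_branch) {
    root <- branch_root(forest)
    m <- tapply(eff, root, max)
    as.numeric(m[root])
  } else rep(max(eff), nrow(forest))
  v <- ifelse(denom > 0, eff / denom, 0)
  auto <- interpolate_color(scale, v)
  forest$color <- ifelse(is.na(forest$color), auto, norm_hex(forest$color))
  forest
}

# level-1 ancestor code of every node; parents resolve before children when
# processed in increasing level order
branch_root <- function(forest) {
  out <- forest$code
  idx <- match(forest$parent, forest$code)
  for (lvl in sort(unique(forest$level))) {
    if (lvl == 1L) next
    i <- which(forest$level == lvl)
    out[i] <- out[idx[i]]
  }
  out
}
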