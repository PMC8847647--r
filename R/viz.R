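# Figure builders and deterministic SVG renderers for the two signature
# outputs: the network pie-chart map (small pies = per-compartment U counts,
# large pies = per-edge B counts, annotated with J and p) and per-variable
# wiring ("London Underground") diagrams. Figure specs carry plain numbers
# taken directly from the classification — renderers never recompute counts —
# and render to deterministic, diffable SVG text with a JSON sidecar.

.default_colours <- c("#1f77b4", "#ff7f0e")   # group 1 blue, group 2 orange

fmt2 <- function(x) sprintf("%.2f", x)

#' Build the network pie-map figure specification
#'
#' Node layout is deterministic for a fixed network: when one compartment is
#' adjacent to every other (a hub, like serum) it sits at the centre with
#' the remaining compartments on a circle in declared order; otherwise all
#' compartments sit on the circle. Each node carries the two groups' U-list
#' sizes, each edge the two groups' B-list sizes, and `J`/`p` annotations
#' are copied (formatted to 2 decimals) from the matching rows of the
#' overlap table.
#'
#' @param classification a two-group [classify_switch()] result.
#' @param overlaps an [overlap_table()] for the same run (may be filtered to
#'   a lipid class); `NULL` omits annotations.
#' @param lipid_class optional lipid class filter applied to the U/B counts
#'   (use the same filter as in `overlaps`).
#' @param colours two fill colours, group 1 then group 2.
#' @return list of class `switch_figure_spec` with `nodes`, `edges`,
#'   `groups` and `colours`.
#' @export
build_switch_figure <- function(classification, overlaps = NULL,
                                lipid_class = NULL,
                                colours = .default_colours) {
  stopifnot(inherits(classification, "switch_classification"))
  network <- classification$network
  groups <- names(classification$groups)
  if (length(groups) != 2L) stop("two-group classification required",
                                 call. = FALSE)
  comps <- network$compartments
  deg <- table(factor(c(network$edges$from, network$edges$to),
                      levels = comps))
  hub <- comps[deg == length(comps) - 1L][1L]
  ring <- if (!is.na(hub)) setdiff(comps, hub) else comps
  theta <- 2 * pi * (seq_along(ring) - 1L) / length(ring) - pi / 2
  pos <- data.frame(compartment = ring,
                    x = round(cos(theta), 6), y = round(sin(theta), 6),
                    stringsAsFactors = FALSE)
  if (!is.na(hub)) {
    pos <- rbind(data.frame(compartment = hub, x = 0, y = 0,
                            stringsAsFactors = FALSE), pos)
  }
  count_scope <- function(g, category, location) {
    length(scope_members(classification, g, category, location, lipid_class))
  }
  annotate <- function(category, location) {
    if (is.null(overlaps)) return(NA_character_)
    sel <- overlaps$category == category &
      (is.na(location) & is.na(overlaps$location) |
         !is.na(overlaps$location) & overlaps$location %in% location)
    if (!any(sel)) return(NA_character_)
    sprintf("J %s, p %s", fmt2(overlaps$J[sel][1L]),
            fmt2(overlaps$p[sel][1L]))
  }
  nodes <- pos
  nodes$count_g1 <- vapply(nodes$compartment, count_scope, integer(1),
                           g = groups[1L], category = "U")
  nodes$count_g2 <- vapply(nodes$compartment, count_scope, integer(1),
                           g = groups[2L], category = "U")
  nodes$annotation <- vapply(nodes$compartment, function(cmp) {
    annotate("U", cmp)
  }, character(1))
  ek <- edge_key(network$edges$from, network$edges$to)
  edges <- data.frame(from = network$edges$from, to = network$edges$to,
                      key = ek, stringsAsFactors = FALSE)
  edges$count_g1 <- vapply(ek, count_scope, integer(1), g = groups[1L],
                           category = "B")
  edges$count_g2 <- vapply(ek, count_scope, integer(1), g = groups[2L],
                           category = "B")
  edges$annotation <- vapply(ek, function(k) annotate("B", k), character(1))
  structure(list(nodes = nodes, edges = edges, groups = groups,
                 colours = colours, lipid_class = lipid_class),
            class = "switch_figure_spec")
}

# One two-slice pie as SVG elements; a zero-count side collapses so the
# other group fills the disc, and a fully empty pie is omitted in favour of
# a "0:0" annotation by the caller.
.svg_pie <- function(cx, cy, r, counts, colours) {
  total <- sum(counts)
  if (total == 0L) return(character(0))
  if (any(counts == 0L)) {
    fill <- colours[which(counts > 0L)]
    return(sprintf(
      '<circle cx="%.1f" cy="%.1f" r="%.1f" fill="%s" stroke="#333" stroke-width="0.5"/>',
      cx, cy, r, fill))
  }
  frac <- counts[1L] / total
  a0 <- -pi / 2
  a1 <- a0 + 2 * pi * frac
  arc <- function(from, to, fill) {
    large <- if ((to - from) %% (2 * pi) > pi) 1L else 0L
    sprintf(
      '<path d="M %.2f %.2f L %.2f %.2f A %.1f %.1f 0 %d 1 %.2f %.2f Z" fill="%s" stroke="#333" stroke-width="0.5"/>',
      cx, cy, cx + r * cos(from), cy + r * sin(from), r, r, large,
      cx + r * cos(to), cy + r * sin(to), fill)
  }
  c(arc(a0, a1, colours[1L]), arc(a1, a0 + 2 * pi, colours[2L]))
}

.svg_doc <- function(body, width, height) {
  paste(c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    '<style>text { font-family: sans-serif; }</style>',
    body, "</svg>"), collapse = "\n")
}

#' Render a network pie-map figure to SVG
#'
#' Small pies show the per-compartment U-type counts of the two groups,
#' larger pies on the edges show the B-type counts; each pie is annotated
#' with its counts (`g1:g2`) and, when available, `J` and `p` formatted to
#' two decimals. A JSON sidecar with every plotted number is written next
#' to the SVG.
#'
#' @param spec a [build_switch_figure()] spec.
#' @param path output SVG path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
render_switch_figure <- function(spec, path) {
  stopifnot(inherits(spec, "switch_figure_spec"))
  size <- 640L
  scale <- 230
  px <- function(v) size / 2 + scale * v
  py <- function(v) size / 2 + scale * v
  body <- character(0)
  for (i in seq_len(nrow(spec$edges))) {
    a <- spec$nodes[spec$nodes$compartment == spec$edges$from[i], ]
    b <- spec$nodes[spec$nodes$compartment == spec$edges$to[i], ]
    body <- c(body, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#999" stroke-width="1.5"/>',
      px(a$x), py(a$y), px(b$x), py(b$y)))
  }
  for (i in seq_len(nrow(spec$edges))) {
    a <- spec$nodes[spec$nodes$compartment == spec$edges$from[i], ]
    b <- spec$nodes[spec$nodes$compartment == spec$edges$to[i], ]
    mx <- px((a$x + b$x) / 2); my <- py((a$y + b$y) / 2)
    counts <- c(spec$edges$count_g1[i], spec$edges$count_g2[i])
    body <- c(body, .svg_pie(mx, my, 28, counts, spec$colours),
              sprintf('<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle">%d:%d</text>',
                      mx, my + 42, counts[1L], counts[2L]))
    if (!is.na(spec$edges$annotation[i])) {
      body <- c(body, sprintf(
        '<text x="%.1f" y="%.1f" font-size="10" text-anchor="middle">%s</text>',
        mx, my + 54, spec$edges$annotation[i]))
    }
  }
  for (i in seq_len(nrow(spec$nodes))) {
    nd <- spec$nodes[i, ]
    counts <- c(nd$count_g1, nd$count_g2)
    body <- c(body, .svg_pie(px(nd$x), py(nd$y), 18, counts, spec$colours),
              sprintf('<text x="%.1f" y="%.1f" font-size="12" font-weight="bold" text-anchor="middle">%s</text>',
                      px(nd$x), py(nd$y) - 24, nd$compartment),
              sprintf('<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle">%d:%d</text>',
                      px(nd$x), py(nd$y) + 32, counts[1L], counts[2L]))
    if (!is.na(nd$annotation)) {
      body <- c(body, sprintf(
        '<text x="%.1f" y="%.1f" font-size="10" text-anchor="middle">%s</text>',
        px(nd$x), py(nd$y) + 44, nd$annotation))
    }
  }
  body <- c(body, sprintf(
    '<text x="10" y="20" font-size="12" fill="%s">%s</text>',
    spec$colours[1L], spec$groups[1L]), sprintf(
    '<text x="10" y="36" font-size="12" fill="%s">%s</text>',
    spec$colours[2L], spec$groups[2L]))
  writeLines(.svg_doc(body, size, size), path)
  sidecar <- sub("\\.svg$", ".json", path)
  jsonlite::write_json(list(groups = spec$groups, nodes = spec$nodes,
                            edges = spec$edges),
                       sidecar, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Build a wiring-diagram specification
#'
#' One horizontal track per lipid variable and group, with a stop glyph at
#' every compartment where that group's presence call holds. Variables are
#' ordered canonically (lipid class, carbons, double bonds, name);
#' compartments keep their declared network order.
#'
#' @param classification a two-group [classify_switch()] result.
#' @param variables subset of variable names to draw (non-empty).
#' @param colours two line colours, group 1 then group 2.
#' @return list of class `wiring_diagram_spec` with `stops` (long data
#'   frame: variable, group, compartment, present), `variables`,
#'   `compartments`, `groups`, `colours`.
#' @export
build_wiring_diagram <- function(classification, variables,
                                 colours = .default_colours) {
  stopifnot(inherits(classification, "switch_classification"))
  if (length(variables) == 0L) {
    stop("empty variable subset: nothing to draw", call. = FALSE)
  }
  known <- classification$variables$raw_name
  bad <- setdiff(variables, known)
  if (length(bad) > 0L) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sp <- classification$variables
  sp <- sp[match(variables, sp$raw_name), , drop = FALSE]
  variables <- variables[lipid_order(sp)]
  comps <- classification$network$compartments
  groups <- names(classification$groups)
  stops <- do.call(rbind, lapply(groups, function(g) {
    rec <- classification$groups[[g]]$record
    rec <- rec[match(variables, rec$variable), ]
    do.call(rbind, lapply(seq_along(variables), function(i) {
      here <- strsplit(rec$compartments[i], ";", fixed = TRUE)[[1L]]
      data.frame(variable = variables[i], group = g, compartment = comps,
                 present = comps %in% here, stringsAsFactors = FALSE)
    }))
  }))
  rownames(stops) <- NULL
  structure(list(stops = stops, variables = variables,
                 compartments = comps, groups = groups, colours = colours),
            class = "wiring_diagram_spec")
}

#' Render a wiring diagram to SVG
#'
#' @param spec a [build_wiring_diagram()] spec.
#' @param path output SVG path; a JSON sidecar of the plotted presence calls
#'   is written alongside.
#' @return `path`, invisibly.
#' @export
render_wiring_diagram <- function(spec, path) {
  stopifnot(inherits(spec, "wiring_diagram_spec"))
  row_h <- 26L; col_w <- 90L
  left <- 130L; top <- 50L
  width <- left + col_w * length(spec$compartments) + 30L
  height <- top + row_h * length(spec$variables) + 20L
  xc <- left + col_w * (seq_along(spec$compartments) - 0.5)
  body <- sprintf(
    '<text x="%.1f" y="%d" font-size="11" text-anchor="middle" font-weight="bold">%s</text>',
    xc, top - 20L, spec$compartments)
  for (i in seq_along(spec$variables)) {
    v <- spec$variables[i]
    yb <- top + row_h * (i - 0.5)
    body <- c(body, sprintf(
      '<text x="%d" y="%.1f" font-size="10" text-anchor="end">%s</text>',
      left - 10L, yb + 3, v))
    for (k in seq_along(spec$groups)) {
      g <- spec$groups[k]
      y <- yb + (k - 1.5) * 7
      sel <- spec$stops$variable == v & spec$stops$group == g
      present <- spec$stops$present[sel][
        match(spec$compartments, spec$stops$compartment[sel])]
      if (any(present)) {
        span <- range(which(present))
        body <- c(body, sprintf(
          '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s" stroke-width="3" stroke-linecap="round"/>',
          xc[span[1L]], y, xc[span[2L]], y, spec$colours[k]))
        body <- c(body, sprintf(
          '<circle cx="%.1f" cy="%.1f" r="3.5" fill="#fff" stroke="%s" stroke-width="2"/>',
          xc[present], y, spec$colours[k]))
      }
    }
  }
  body <- c(body, sprintf(
    '<text x="10" y="%d" font-size="11" fill="%s">%s</text>',
    c(18L, 34L), spec$colours, spec$groups))
  writeLines(.svg_doc(body, width, height), path)
  jsonlite::write_json(list(groups = spec$groups,
                            compartments = spec$compartments,
                            stops = spec$stops),
                       sub("\\.svg$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
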