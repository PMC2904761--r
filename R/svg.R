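# Minimal self-contained SVG rendering: compartments (rectangle, oval,
# annulus), straight edges, node glyphs.  Grid coordinates map to pixels
# with (row, col) -> (y, x).

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

comp_svg <- function(comp, s, pad) {
  px <- function(col) pad + col * s
  py <- function(row) pad + row * s
  style <- sprintf("fill:none;stroke:%s;stroke-width:1.5",
                   switch(comp$id, plasma_membrane = "#3366cc",
                          nucleus = "#ccaa00", mitochondria = "#cc3333",
                          golgi = "#8b5a2b", "#999999"))
  draw <- function(shape, size, dash = FALSE) {
    st <- if (dash) paste0(style, ";stroke-dasharray:4 2") else style
    if (shape == "rectangle")
      sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" style="%s"/>',
              px(comp$center[2] - size[2] / 2), py(comp$center[1] - size[1] / 2),
              size[2] * s, size[1] * s, st)
    else
      sprintf('<ellipse cx="%.1f" cy="%.1f" rx="%.1f" ry="%.1f" style="%s"/>',
              px(comp$center[2]), py(comp$center[1]),
              size[2] / 2 * s, size[1] / 2 * s, st)
  }
  if (comp$shape == "annulus")
    paste0(draw(comp$base, comp$size),
           draw(comp$base, comp$inner_size, dash = TRUE))
  else draw(comp$shape, comp$size)
}

#' Render a layout as SVG
#'
#' Draws compartment outlines, straight edge lines and circular node glyphs
#' with labels. Works for both grid and continuous layouts.
#'
#' @param layout a [grid_layout()] or `spring_layout`.
#' @param graph a [pathway_graph()].
#' @param compartments optional list of [compartment()]s.
#' @param path output SVG file.
#' @param scale pixels per grid unit.
#' @param labels draw node labels?
#' @return `path`, invisibly.
#' @export
render_svg <- function(layout, graph, compartments = NULL, path,
                       scale = 16, labels = TRUE) {
  grid <- attr(layout, "grid")
  dims <- if (!is.null(grid)) c(grid$h - 1, grid$w - 1)
          else as.numeric(attr(layout, "canvas"))
  pad <- scale
  width <- dims[2] * scale + 2 * pad
  height <- dims[1] * scale + 2 * pad
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">'),
                   width, height, width, height),
           '<rect width="100%" height="100%" fill="white"/>')
  for (comp in compartments %||% list())
    out <- c(out, comp_svg(comp, scale, pad))
  if (n_nodes(graph) > 0) {
    pos <- layout_positions(graph, layout)
    x <- pad + pos[, 2] * scale
    y <- pad + pos[, 1] * scale
    ei <- edge_index(graph)
    for (k in seq_len(nrow(ei)))
      out <- c(out, sprintf(
        '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#444444" stroke-width="1"/>',
        x[ei[k, 1]], y[ei[k, 1]], x[ei[k, 2]], y[ei[k, 2]]))
    for (i in seq_len(nrow(pos))) {
      out <- c(out, sprintf(
        '<circle cx="%.1f" cy="%.1f" r="%.1f" fill="#88bb88" stroke="#226622"/>',
        x[i], y[i], scale * 0.3))
      if (labels)
        out <- c(out, sprintf(
          '<text x="%.1f" y="%.1f" font-size="%.1f" fill="#222222">%s</text>',
          x[i] + scale * 0.35, y[i] - scale * 0.2, scale * 0.45,
          svg_esc(graph$nodes$label[i])))
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
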