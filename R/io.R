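# Readers and writers: GraphML (via igraph), a plain JSON graph dialect,
# compartment JSON, and layout JSON.

#' Read a pathway graph from GraphML
#'
#' Nodes must carry a `localization` attribute; `name` (or `id`) supplies
#' the node id and `label` is optional. Any edge direction attribute is
#' ignored for layout purposes (edges are undirected).
#'
#' @param path GraphML file.
#' @return A [pathway_graph()].
#' @export
read_pathway_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  id <- if (!is.null(va$name)) va$name else va$id
  if (is.null(id)) stop(path, ": nodes carry no 'name'/'id' attribute")
  if (is.null(va$localization))
    stop(path, ": nodes carry no 'localization' attribute")
  nodes <- data.frame(id = id,
                      label = if (!is.null(va$label)) va$label else id,
                      localization = va$localization)
  el <- igraph::as_edgelist(g, names = FALSE)
  pathway_graph(nodes, cbind(id[el[, 1]], id[el[, 2]]))
}

#' Write a pathway graph as GraphML
#'
#' @param graph a [pathway_graph()].
#' @param path output file.
#' @export
write_pathway_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(graph$edges), directed = FALSE,
    vertices = graph$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a pathway graph from the JSON dialect
#'
#' Format: `{"nodes": [{"id", "label", "localization"}, ...],
#' "edges": [["a", "b"], ...]}`.
#'
#' @param path JSON file.
#' @return A [pathway_graph()].
#' @export
read_pathway_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  edges <- x$edges
  if (is.list(edges) && !is.matrix(edges)) edges <- do.call(rbind, edges)
  pathway_graph(x$nodes, edges)
}

#' Write a pathway graph as JSON
#'
#' @param graph a [pathway_graph()].
#' @param path output file.
#' @export
write_pathway_json <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes,
         edges = unname(apply(graph$edges, 1, identity, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a compartment specification from JSON
#'
#' A JSON array of objects with fields `id`, `shape`, `center` ([row, col]),
#' `size` ([height, width]), optional `inner_size`, `base`, `movable`,
#' `tags`, `exclude`, `within`.
#'
#' @param path JSON file.
#' @return List of [compartment()]s.
#' @export
read_compartments <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(x, function(c_) {
    compartment(id = c_$id, shape = c_$shape, center = unlist(c_$center),
                size = unlist(c_$size),
                inner_size = if (!is.null(c_$inner_size))
                  unlist(c_$inner_size),
                base = if (!is.null(c_$base)) c_$base else "rectangle",
                movable = isTRUE(c_$movable),
                tags = if (!is.null(c_$tags)) unlist(c_$tags) else c_$id,
                exclude = if (!is.null(c_$exclude)) unlist(c_$exclude)
                          else character(),
                within = c_$within)
  })
}

#' Write a compartment specification as JSON
#'
#' @param compartments list of [compartment()]s.
#' @param path output file.
#' @export
write_compartments <- function(compartments, path) {
  jsonlite::write_json(lapply(compartments, function(c_) {
    out <- unclass(c_)
    out$original_size <- NULL
    out[!vapply(out, is.null, TRUE)]
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a layout (grid or continuous) as JSON
#'
#' Stores grid/canvas metadata and per-node positions.
#'
#' @param layout a [grid_layout()] or `spring_layout`.
#' @param path output file.
#' @export
write_layout_json <- function(layout, path) {
  grid <- attr(layout, "grid")
  meta <- if (!is.null(grid)) list(type = "grid", h = grid$h, w = grid$w)
          else list(type = "continuous",
                    canvas = as.numeric(attr(layout, "canvas")))
  pts <- unclass(layout)
  jsonlite::write_json(
    c(meta, list(positions = data.frame(id = rownames(pts),
                                        row = pts[, 1], col = pts[, 2]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layout written by [write_layout_json()]
#'
#' @param path JSON file.
#' @return A [grid_layout()] or `spring_layout`.
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  pts <- cbind(row = x$positions$row, col = x$positions$col)
  rownames(pts) <- x$positions$id
  if (identical(x$type, "grid"))
    grid_layout(pts, layout_grid(x$h, x$w))
  else structure(pts, class = "spring_layout", canvas = x$canvas)
}
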