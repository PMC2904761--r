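#' Construct a pathway graph
#'
#' A pathway graph is a set of uniquely identified nodes, each carrying a
#' free-text sub-cellular localization tag, joined by undirected edges.
#' Self-loops and duplicate edges are rejected; every edge endpoint must be a
#' known node id. Nodes are stored sorted by id so that downstream
#' tie-breaking is reproducible.
#'
#' @param nodes data.frame with columns `id`, `label` (optional; defaults to
#'   `id`) and `localization`.
#' @param edges two-column matrix or data.frame of node ids (unordered
#'   pairs), or a list of length-2 character vectors.
#' @return An object of class `pathway_graph` with elements `nodes`
#'   (data.frame) and `edges` (two-column character matrix).
#' @export
pathway_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("id", "localization") %in% names(nodes)))
    stop("`nodes` needs columns 'id' and 'localization'")
  nodes$id <- as.character(nodes$id)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  nodes <- nodes[order(nodes$id), c("id", "label", "localization")]
  rownames(nodes) <- NULL

  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, edges)
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(), ncol = 2)
  } else {
    if (ncol(edges) != 2) stop("`edges` must have two columns")
    storage.mode(edges) <- "character"
    bad <- setdiff(c(edges), nodes$id)
    if (length(bad))
      stop("edge endpoint(s) not in node set: ", paste(bad, collapse = ", "))
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    # canonical orientation: edges are undirected
    edges <- cbind(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
    key <- paste(edges[, 1], edges[, 2])
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    edges <- edges[order(key), , drop = FALSE]
  }
  colnames(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges), class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  tab <- table(x$nodes$localization)
  cat("  localization:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$nodes)
n_edges <- function(graph) nrow(graph$edges)

# edges as 1-based indices into graph$nodes
edge_index <- function(graph) {
  if (n_edges(graph) == 0) return(matrix(integer(), ncol = 2))
  cbind(match(graph$edges[, 1], graph$nodes$id),
        match(graph$edges[, 2], graph$nodes$id))
}

# adjacency list of 1-based node indices
neighbor_index <- function(graph) {
  n <- n_nodes(graph)
  nb <- vector("list", n)
  ei <- edge_index(graph)
  for (k in seq_len(nrow(ei))) {
    nb[[ei[k, 1]]] <- c(nb[[ei[k, 1]]], ei[k, 2])
    nb[[ei[k, 2]]] <- c(nb[[ei[k, 2]]], ei[k, 1])
  }
  nb
}

#' Define a layout grid
#'
#' Grid points are integer (row, col) pairs, 0-based, with
#' `0 <= row < h` and `0 <= col < w`. Throughout the package a grid point is
#' also addressed by its linear index `row * w + col + 1`.
#'
#' @param h,w positive integer row and column counts.
#' @return Object of class `layout_grid`.
#' @export
layout_grid <- function(h, w) {
  h <- as.integer(h); w <- as.integer(w)
  stopifnot(h >= 1, w >= 1)
  structure(list(h = h, w = w), class = "layout_grid")
}

#' @export
print.layout_grid <- function(x, ...) {
  cat(sprintf("<layout_grid> %d rows x %d columns\n", x$h, x$w))
  invisible(x)
}

# linear index <-> (row, col); points is an n x 2 matrix of 0-based coords
point_index <- function(points, grid) {
  points <- rbind(points)
  as.integer(points[, 1] * grid$w + points[, 2] + 1)
}

index_point <- function(idx, grid) {
  idx <- as.integer(idx) - 1L
  cbind(row = idx %/% grid$w, col = idx %% grid$w)
}

# coordinates of all grid points in index order
grid_coords <- function(grid) {
  idx <- seq_len(grid$h * grid$w)
  index_point(idx, grid)
}

#' Build a grid layout
#'
#' A layout is an injective assignment of every node to a grid point,
#' represented as an n x 2 integer matrix of 0-based (row, col) coordinates
#' with node ids as row names.
#'
#' @param points n x 2 matrix of (row, col) coordinates, row names = node ids.
#' @param grid a [layout_grid()].
#' @return Object of class `grid_layout`.
#' @export
grid_layout <- function(points, grid) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("row", "col")
  if (nrow(points) > 0 && is.null(rownames(points)))
    stop("layout points need node-id row names")
  if (any(points[, 1] < 0 | points[, 1] >= grid$h |
          points[, 2] < 0 | points[, 2] >= grid$w))
    stop("layout contains points outside the grid")
  structure(points, class = "grid_layout", grid = grid)
}

#' @export
print.grid_layout <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<grid_layout> %d nodes on %dx%d grid\n", nrow(x), g$h, g$w))
  invisible(x)
}

# positions ordered to match graph$nodes; errors on missing nodes
layout_positions <- function(graph, layout) {
  idx <- match(graph$nodes$id, rownames(layout))
  if (anyNA(idx))
    stop("layout is missing node(s): ",
         paste(graph$nodes$id[is.na(idx)], collapse = ", "))
  pos <- unclass(layout)[idx, , drop = FALSE]
  rownames(pos) <- graph$nodes$id
  pos
}

#' Grid-sizing helper
#'
#' Rows and columns are chosen proportional to the square root of the node
#' count, following the empirical rule that `(h + w) / sqrt(|V|)` should land
#' in roughly the 6.5--11 range observed for curated pathway drawings.
#'
#' @param n_nodes node count.
#' @param span target value of `(h + w) / sqrt(n_nodes)` (default 7).
#' @param aspect ratio h / w (default 1).
#' @return A [layout_grid()].
#' @export
grid_dims <- function(n_nodes, span = 7, aspect = 1) {
  s <- span * sqrt(n_nodes)
  h <- max(4L, as.integer(round(s * aspect / (1 + aspect))))
  w <- max(4L, as.integer(round(s)) - h)
  layout_grid(h, w)
}

#' Grid span ratio
#'
#' `(h + w) / sqrt(n)`, the quantity the sizing rule keeps roughly constant.
#'
#' @param grid a [layout_grid()] (or list with `h`, `w`).
#' @param n_nodes node count.
#' @return Numeric scalar.
#' @export
grid_span_ratio <- function(grid, n_nodes) (grid$h + grid$w) / sqrt(n_nodes)
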