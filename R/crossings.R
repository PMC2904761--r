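#' Do two straight segments cross?
#'
#' Returns 1 iff the open interiors of the two segments intersect: a proper
#' crossing, or a collinear overlap of positive length (segments drawn on
#' top of each other). Segments that merely touch at an endpoint — including
#' T-junctions, which are the business of the node-edge counter — return 0.
#' All tests use exact arithmetic on integer coordinates.
#'
#' @param e,f segments: 2 x 2 matrices (one endpoint per row, `(row, col)`),
#'   or length-4 vectors `c(r1, c1, r2, c2)`.
#' @return 0 or 1.
#' @export
segments_cross <- function(e, f) {
  e <- matrix(as.numeric(e), 2, 2, byrow = is.null(dim(e)))
  f <- matrix(as.numeric(f), 2, 2, byrow = is.null(dim(f)))
  as.integer(cpp_seg_cross_batch(rbind(e[1, ]), rbind(e[2, ]),
                                 rbind(f[1, ]), rbind(f[2, ])))
}

#' Does a node lie on the interior of an edge segment?
#'
#' 1 iff `p` lies on the closed segment excluding its endpoints.
#'
#' @param p grid point `c(row, col)`.
#' @param e segment: 2 x 2 matrix or `c(r1, c1, r2, c2)`.
#' @return 0 or 1.
#' @export
node_on_edge <- function(p, e) {
  e <- matrix(as.numeric(e), 2, 2, byrow = is.null(dim(e)))
  as.integer(cpp_on_segment_batch(rbind(as.numeric(p)),
                                  rbind(e[1, ]), rbind(e[2, ])))
}

#' Count all edge-edge and node-edge crossings of a layout
#'
#' Edge-edge crossings are counted over unordered edge pairs that do not
#' share a graph endpoint; node-edge crossings over (node, edge) pairs where
#' the node is not an endpoint of the edge and its point lies strictly
#' inside the segment.
#'
#' @param graph a [pathway_graph()].
#' @param layout a [grid_layout()] (or any node -> coordinate matrix; the
#'   counts are also meaningful for continuous spring layouts).
#' @return Named integer vector `c(ee = ..., ne = ...)`.
#' @export
count_all_crossings <- function(graph, layout) {
  pos <- layout_positions(graph, layout)
  ei <- edge_index(graph)
  if (nrow(ei) == 0) return(c(ee = 0L, ne = 0L))
  cpp_count_crossings(pos, ei - 1L)
}

#' Crossing-count deltas for all candidate moves of one node
#'
#' For every grid point `q`, the exact change in the (edge-edge, node-edge)
#' crossing counts if node `v` were relocated to `q`, everything else held
#' fixed. The entry at `v`'s current point is (0, 0). Points occupied by
#' other nodes are flagged unusable (the optimizer never moves there), but
#' their geometric deltas are still reported.
#'
#' @param v node id.
#' @param graph a [pathway_graph()].
#' @param layout a [grid_layout()].
#' @param grid a [layout_grid()].
#' @return List with integer vectors `dee`, `dne` (length `h * w`, grid-point
#'   index order) and logical `usable`.
#' @export
bulk_candidate_counts <- function(v, graph, layout, grid) {
  pos <- layout_positions(graph, layout)
  vi <- match(v, graph$nodes$id)
  if (is.na(vi)) stop("unknown node '", v, "'")
  ei <- edge_index(graph)
  res <- cpp_bulk_deltas(vi - 1L, pos, rbind(ei) - 1L, grid$h, grid$w)
  usable <- rep(TRUE, grid$h * grid$w)
  usable[point_index(pos[-vi, , drop = FALSE], grid)] <- FALSE
  list(dee = res$dee, dne = res$dne, usable = usable)
}
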