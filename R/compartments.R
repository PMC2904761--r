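#' Define a compartment
#'
#' Compartments are geometric regions of the grid representing sub-cellular
#' locations. Three shapes are supported: axis-aligned `rectangle`, `oval`
#' (ellipse inequality, boundary inclusive), and `annulus` — the ring of grid
#' points inside an outer boundary but outside (and not on the boundary of)
#' an inner one, modelling membranes. Annuli take their outline from `base`
#' (`"rectangle"` frames for the plasma membrane, `"oval"` rings for nuclear
#' membranes); the default ring width is one grid unit.
#'
#' @param id compartment id.
#' @param shape `"rectangle"`, `"oval"` or `"annulus"`.
#' @param center real-valued (row, col) center.
#' @param size full (height, width) extent in grid units; both > 0.
#' @param inner_size annulus only: full extent of the inner boundary; must be
#'   strictly smaller than `size` in both dimensions. Defaults to
#'   `size - 2` (ring width 1).
#' @param base annulus only: outline shape, `"rectangle"` (default) or
#'   `"oval"`.
#' @param movable may the dynamic-compartment mode resize/reposition it?
#' @param tags localization tags whose nodes live in this compartment
#'   (default: the id).
#' @param exclude ids of compartments whose regions are carved out of this
#'   one (e.g. the cytoplasm excludes the nucleus).
#' @param within id of the enclosing compartment, if any; repositioning keeps
#'   the bounding rectangle inside the parent's, and the no-overlap rule is
#'   enforced among compartments sharing a parent.
#' @return Object of class `compartment`.
#' @export
compartment <- function(id, shape = c("rectangle", "oval", "annulus"),
                        center, size, inner_size = NULL,
                        base = c("rectangle", "oval"),
                        movable = FALSE, tags = id,
                        exclude = character(), within = NULL) {
  shape <- match.arg(shape)
  base <- match.arg(base)
  center <- as.numeric(center); size <- as.numeric(size)
  stopifnot(length(center) == 2, length(size) == 2, all(size > 0))
  if (shape == "annulus") {
    if (is.null(inner_size)) inner_size <- pmax(size - 2, size * 0.01)
    inner_size <- as.numeric(inner_size)
    if (!all(inner_size < size))
      stop("annulus inner size must be strictly inside the outer size")
  } else inner_size <- NULL
  structure(list(id = id, shape = shape, center = center, size = size,
                 original_size = size, inner_size = inner_size, base = base,
                 movable = isTRUE(movable), tags = as.character(tags),
                 exclude = as.character(exclude), within = within),
            class = "compartment")
}

#' @export
print.compartment <- function(x, ...) {
  cat(sprintf("<compartment> %s [%s] center=(%.1f,%.1f) size=(%.1f,%.1f)%s\n",
              x$id, x$shape, x$center[1], x$center[2], x$size[1], x$size[2],
              if (x$movable) " movable" else ""))
  invisible(x)
}

# membership of every grid point in the *own* geometry of one compartment
# (before any `exclude` carving), as a logical vector in index order
shape_mask <- function(comp, grid) {
  co <- grid_coords(grid)
  inside <- function(shape, size) {
    dr <- co[, 1] - comp$center[1]
    dc <- co[, 2] - comp$center[2]
    if (shape == "rectangle") {
      abs(dr) <= size[1] / 2 + 1e-9 & abs(dc) <= size[2] / 2 + 1e-9
    } else {
      (dr / (size[1] / 2))^2 + (dc / (size[2] / 2))^2 <= 1 + 1e-9
    }
  }
  if (comp$shape == "annulus") {
    inside(comp$base, comp$size) & !inside(comp$base, comp$inner_size)
  } else {
    inside(comp$shape, comp$size)
  }
}

# geometry after carving out excluded compartments
region_mask <- function(comp, compartments, grid) {
  m <- shape_mask(comp, grid)
  for (other in compartments)
    if (other$id %in% comp$exclude) m <- m & !shape_mask(other, grid)
  m
}

#' Grid points admissible for a localization tag
#'
#' The union of the (exclusion-carved) regions of all compartments bearing
#' the tag.
#'
#' @param compartments list of [compartment()]s.
#' @param tag localization tag.
#' @param grid a [layout_grid()].
#' @return Integer vector of grid-point indices (`row * w + col + 1`).
#' @export
region_points <- function(compartments, tag, grid) {
  carrying <- Filter(function(c) tag %in% c$tags, compartments)
  if (!length(carrying)) stop("no compartment carries tag '", tag, "'")
  m <- rep(FALSE, grid$h * grid$w)
  for (comp in carrying) m <- m | region_mask(comp, compartments, grid)
  which(m)
}

#' Build the per-tag constraint map
#'
#' For each localization tag present in the graph (or in `tags`), the set of
#' admissible grid points, plus the per-compartment node sets used by the
#' dynamic-compartment mode.
#'
#' @param compartments list of [compartment()]s; `NULL` disables constraints
#'   (every tag admits the whole grid).
#' @param grid a [layout_grid()].
#' @param graph optional [pathway_graph()] supplying tags and node sets.
#' @param tags tags to resolve when `graph` is absent.
#' @return Object of class `constraint_map`: list with `admissible` (named
#'   list tag -> index vector) and `nodes_by_compartment` (named list
#'   compartment id -> node ids).
#' @export
build_constraints <- function(compartments, grid, graph = NULL, tags = NULL) {
  if (is.null(tags)) tags <- unique(graph$nodes$localization)
  if (is.null(compartments)) {
    adm <- lapply(tags, function(t) seq_len(grid$h * grid$w))
  } else {
    adm <- lapply(tags, function(t) region_points(compartments, t, grid))
  }
  names(adm) <- tags
  empty <- tags[vapply(adm, length, 1L) == 0]
  if (length(empty))
    stop("no admissible grid points for tag(s): ",
         paste(empty, collapse = ", "))
  nbc <- list()
  if (!is.null(compartments) && !is.null(graph)) {
    for (comp in compartments)
      nbc[[comp$id]] <-
        graph$nodes$id[graph$nodes$localization %in% comp$tags]
  }
  structure(list(admissible = adm, nodes_by_compartment = nbc,
                 grid = grid, compartments = compartments),
            class = "constraint_map")
}

#' @export
print.constraint_map <- function(x, ...) {
  cat("<constraint_map>\n")
  for (t in names(x$admissible))
    cat(sprintf("  %-18s %d admissible points\n", t, length(x$admissible[[t]])))
  invisible(x)
}

#' Validate a layout against injectivity and localization constraints
#'
#' Violations are returned as data, not raised: one row per problem, either a
#' `collision` (two nodes on one grid point) or a `constraint` breach (a node
#' outside the admissible region of its tag).
#'
#' @param graph a [pathway_graph()].
#' @param layout a [grid_layout()] covering all nodes.
#' @param constraints a [build_constraints()] result.
#' @return data.frame with columns `type`, `node`, `detail`; zero rows iff
#'   the layout is valid.
#' @export
validate_layout <- function(graph, layout, constraints) {
  grid <- constraints$grid
  pos <- layout_positions(graph, layout)
  idx <- point_index(pos, grid)
  out <- list()
  dup <- duplicated(idx) | duplicated(idx, fromLast = TRUE)
  for (i in which(dup))
    out[[length(out) + 1]] <- data.frame(
      type = "collision", node = graph$nodes$id[i],
      detail = sprintf("grid point (%d,%d) shared", pos[i, 1], pos[i, 2]))
  for (i in seq_len(n_nodes(graph))) {
    tag <- graph$nodes$localization[i]
    adm <- constraints$admissible[[tag]]
    if (is.null(adm))
      out[[length(out) + 1]] <- data.frame(
        type = "constraint", node = graph$nodes$id[i],
        detail = sprintf("unknown tag '%s'", tag))
    else if (!(idx[i] %in% adm))
      out[[length(out) + 1]] <- data.frame(
        type = "constraint", node = graph$nodes$id[i],
        detail = sprintf("point (%d,%d) outside region '%s'",
                         pos[i, 1], pos[i, 2], tag))
  }
  if (!length(out))
    return(data.frame(type = character(), node = character(),
                      detail = character()))
  do.call(rbind, out)
}
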