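# Dynamic resizing and repositioning of compartments (the "GDC" mode).

#' Spread statistics of a compartment's nodes
#'
#' Center of gravity and the vertical/horizontal spread of the nodes
#' localized to a compartment. Spread is reported as the full-extent proxy
#' `2 * max` deviation from the centroid along each axis (the default), or
#' `2 * mean` deviation (`method = "mean"`).
#'
#' @param positions k x 2 matrix of (row, col) node coordinates (k >= 1).
#' @param method `"max"` (default) or `"mean"`.
#' @return List with `b` (centroid, length-2), `s_v` and `s_h`.
#' @export
spread_statistics <- function(positions, method = c("max", "mean")) {
  method <- match.arg(method)
  positions <- rbind(positions)
  b <- colMeans(positions)
  dv <- abs(positions[, 1] - b[1])
  dh <- abs(positions[, 2] - b[2])
  f <- if (method == "max") max else mean
  list(b = unname(b), s_v = 2 * f(dv), s_h = 2 * f(dh))
}

#' Resize decision for one compartment
#'
#' Shrink (by factor 0.95) when the node spread fills less than 40% of the
#' compartment in *both* directions; enlarge (by 1/0.95) when it exceeds 90%
#' in *either*; otherwise keep. Sizes are clamped to
#' `[0.6, 1.5] * original_size`; a compartment already at a bound keeps its
#' size rather than stepping past it.
#'
#' @param comp a [compartment()].
#' @param s_v,s_h spreads from [spread_statistics()].
#' @return `"shrink"`, `"enlarge"` or `"keep"`.
#' @export
resize_decision <- function(comp, s_v, s_h) {
  ratio <- comp$size[1] / comp$original_size[1]
  if (s_v < 0.4 * comp$size[1] && s_h < 0.4 * comp$size[2]) {
    if (ratio > 0.6 + 1e-9) return("shrink")
    return("keep")
  }
  if (s_v > 0.9 * comp$size[1] || s_h > 0.9 * comp$size[2]) {
    if (ratio < 1.5 - 1e-9) return("enlarge")
    return("keep")
  }
  "keep"
}

apply_resize <- function(comp, decision) {
  if (decision == "shrink") {
    comp$size <- pmax(comp$size * 0.95, 0.6 * comp$original_size)
    if (!is.null(comp$inner_size))
      comp$inner_size <- pmin(pmax(comp$inner_size * 0.95,
                                   comp$size * 0.01), comp$size - 1e-6)
  } else if (decision == "enlarge") {
    comp$size <- pmin(comp$size / 0.95, 1.5 * comp$original_size)
    if (!is.null(comp$inner_size))
      comp$inner_size <- pmin(comp$inner_size / 0.95, comp$size - 1e-6)
  }
  comp
}

bounding_rect <- function(comp) {
  c(comp$center[1] - comp$size[1] / 2, comp$center[2] - comp$size[2] / 2,
    comp$center[1] + comp$size[1] / 2, comp$center[2] + comp$size[2] / 2)
}

point_in_rect <- function(r, c, rect) {
  r > rect[1] & r < rect[3] & c > rect[2] & c < rect[4]
}

# corner-in-rectangle test, as classically (and imperfectly) formulated:
# rectangles overlap if a corner of one lies strictly inside the other.
# Misses the cross-shaped overlap where no corner is contained; the strict
# mode uses full interval intersection instead.
rects_overlap <- function(a, b, mode = c("corner", "strict")) {
  mode <- match.arg(mode)
  if (mode == "strict")
    return(a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
  corners <- function(r) rbind(c(r[1], r[2]), c(r[1], r[4]),
                               c(r[3], r[2]), c(r[3], r[4]))
  ca <- corners(a); cb <- corners(b)
  any(point_in_rect(ca[, 1], ca[, 2], b)) ||
    any(point_in_rect(cb[, 1], cb[, 2], a))
}

rect_within <- function(inner, outer) {
  inner[1] >= outer[1] - 1e-9 && inner[2] >= outer[2] - 1e-9 &&
    inner[3] <= outer[3] + 1e-9 && inner[4] <= outer[4] + 1e-9
}

# geometry admissible? checks every node's localization, sibling overlap,
# and containment in the `within` parent
geometry_valid <- function(compartments, graph, idx, grid,
                           overlap_mode = "corner") {
  tags <- unique(graph$nodes$localization)
  for (tag in tags) {
    pts <- tryCatch(region_points(compartments, tag, grid),
                    error = function(e) integer())
    node_idx <- idx[graph$nodes$localization == tag]
    if (!all(node_idx %in% pts)) return(FALSE)
  }
  byid <- setNames(compartments, vapply(compartments, `[[`, "", "id"))
  for (i in seq_along(compartments)) {
    ci <- compartments[[i]]
    if (!is.null(ci$within) && !is.null(byid[[ci$within]])) {
      if (!rect_within(bounding_rect(ci), bounding_rect(byid[[ci$within]])))
        return(FALSE)
    }
    for (j in seq_along(compartments)) {
      if (j <= i) next
      cj <- compartments[[j]]
      same_parent <- identical(ci$within, cj$within) &&
        !is.null(ci$within)
      if (!same_parent) next
      if (!ci$movable && !cj$movable) next  # fixed scene geometry
      if (rects_overlap(bounding_rect(ci), bounding_rect(cj),
                        mode = overlap_mode))
        return(FALSE)
    }
  }
  TRUE
}

#' Reposition a compartment toward its nodes' center of gravity
#'
#' Searches the grid points within Manhattan distance `max_manhattan` of the
#' (discretized) center of gravity `b_c`, in order of increasing Manhattan
#' distance (ties: lowest row, then column), and returns the first center
#' for which every node still satisfies its localization, no sibling
#' bounding rectangles overlap, and the compartment stays inside its
#' `within` parent. Returns `NULL` if no candidate is valid.
#'
#' @param comp the (possibly already resized) [compartment()] to place.
#' @param b_c nodes' center of gravity (real-valued (row, col)).
#' @param compartments full compartment list (with `comp` in its current
#'   geometry; it is swapped out during the search).
#' @param graph a [pathway_graph()].
#' @param layout current [grid_layout()].
#' @param grid a [layout_grid()].
#' @param max_manhattan search radius (default 10).
#' @param overlap_mode `"corner"` (the classical four-corner test) or
#'   `"strict"` (full rectangle intersection).
#' @return New center `c(row, col)` or `NULL`.
#' @export
reposition_compartment <- function(comp, b_c, compartments, graph, layout,
                                   grid, max_manhattan = 10,
                                   overlap_mode = "corner") {
  b_disc <- floor(b_c + 0.5)
  co <- grid_coords(grid)
  md <- abs(co[, 1] - b_disc[1]) + abs(co[, 2] - b_disc[2])
  cand <- which(md <= max_manhattan)
  cand <- cand[order(md[cand], co[cand, 1], co[cand, 2])]
  idx <- point_index(layout_positions(graph, layout), grid)
  ids <- vapply(compartments, `[[`, "", "id")
  slot <- match(comp$id, ids)
  for (k in cand) {
    trial <- comp
    trial$center <- as.numeric(co[k, ])
    comps <- compartments
    comps[[slot]] <- trial
    if (geometry_valid(comps, graph, idx, grid, overlap_mode))
      return(trial$center)
  }
  NULL
}

# one update round over all movable compartments; returns list(compartments,
# changed)
update_compartments <- function(compartments, graph, layout, grid,
                                nodes_by_compartment, max_manhattan = 10,
                                overlap_mode = "corner",
                                spread_method = "max") {
  changed <- FALSE
  pos <- layout_positions(graph, layout)
  for (i in seq_along(compartments)) {
    comp <- compartments[[i]]
    if (!comp$movable) next
    vc <- nodes_by_compartment[[comp$id]]
    if (is.null(vc) || !length(vc)) next
    st <- spread_statistics(pos[vc, , drop = FALSE], method = spread_method)
    decision <- resize_decision(comp, st$s_v, st$s_h)
    resized <- apply_resize(comp, decision)

    center <- reposition_compartment(resized, st$b, compartments, graph,
                                     layout, grid, max_manhattan,
                                     overlap_mode)
    accepted <- NULL
    if (!is.null(center)) {
      accepted <- resized; accepted$center <- center
    } else if (decision != "keep") {
      # revert the size change, retry the repositioning alone
      center <- reposition_compartment(comp, st$b, compartments, graph,
                                       layout, grid, max_manhattan,
                                       overlap_mode)
      if (!is.null(center)) { accepted <- comp; accepted$center <- center }
    }
    if (!is.null(accepted) &&
        (!identical(accepted$center, comp$center) ||
         !identical(accepted$size, comp$size))) {
      compartments[[i]] <- accepted
      changed <- TRUE
    }
  }
  list(compartments = compartments, changed = changed)
}

#' Grid layout with dynamic compartment update
#'
#' Interleaves greedy grid-search passes (up to `|V|` accepted moves each)
#' with compartment update rounds: each movable compartment is resized
#' according to the spread of its nodes and repositioned toward their center
#' of gravity, subject to every node keeping its localization and sibling
#' compartments not overlapping. A decaying surface penalty keeps nodes off
#' compartment surfaces early so the compartments stay free to move; since
#' the penalty decays to zero, convergence of the search is preserved. The
#' run stops when a pass accepts no move and no compartment changes.
#'
#' With no movable compartment this reduces exactly to [optimize_layout()].
#'
#' @param graph a [pathway_graph()].
#' @param grid a [layout_grid()].
#' @param compartments list of [compartment()]s (outer membrane and
#'   extracellular region are conventionally immovable).
#' @param params a [cost_params()].
#' @param layout optional initial admissible [grid_layout()].
#' @param seed RNG seed for the random initial layout.
#' @param max_rounds cap on update rounds (default 100).
#' @param max_manhattan repositioning search radius (default 10).
#' @param overlap_mode `"corner"` or `"strict"` (see
#'   [reposition_compartment()]).
#' @param spread_method `"max"` or `"mean"` (see [spread_statistics()]).
#' @return Object of class `pathgrid_fit` with extra elements
#'   `compartments` (final geometry) and `compartment_trace` (one row per
#'   compartment per round).
#' @export
gdc_layout <- function(graph, grid, compartments, params = cost_params(),
                       layout = NULL, seed = NULL, max_rounds = 100,
                       max_manhattan = 10, overlap_mode = "corner",
                       spread_method = "max") {
  constraints <- build_constraints(compartments, grid, graph)
  if (is.null(layout))
    layout <- random_layout(graph, grid, constraints, seed = seed)
  viol <- validate_layout(graph, layout, constraints)
  if (nrow(viol))
    stop("initial layout is inadmissible:\n",
         paste(sprintf("  [%s] %s: %s", viol$type, viol$node, viol$detail),
               collapse = "\n"))
  any_movable <- any(vapply(compartments, `[[`, TRUE, "movable"))
  state <- init_caches(graph, layout, params, constraints,
                       gdc = any_movable, compartments = compartments)
  n <- n_nodes(graph)
  trace <- list()
  ctrace <- list()
  for (round in seq_len(max_rounds)) {
    moved <- 0L
    while (moved < n) {
      mv <- best_move(state)
      if (is.null(mv)) break
      apply_move_and_update(state, mv)
      trace[[length(trace) + 1]] <- trace_row(state, mv)
      moved <- moved + 1L
    }
    changed <- FALSE
    if (any_movable) {
      upd <- update_compartments(state$compartments, graph,
                                 current_layout(state), grid,
                                 constraints$nodes_by_compartment,
                                 max_manhattan, overlap_mode, spread_method)
      changed <- upd$changed
      if (changed) {
        state$compartments <- upd$compartments
        constraints <- build_constraints(upd$compartments, grid, graph)
        state$constraints <- constraints
        hw <- grid$h * grid$w
        for (i in seq_len(n)) {
          tag <- graph$nodes$localization[i]
          state$adm[, i] <- FALSE
          state$adm[constraints$admissible[[tag]], i] <- TRUE
        }
        state$band <- surface_band(upd$compartments, grid)
        state$n_near <- sum(state$band[state$idx])
      }
      for (comp in state$compartments)
        if (comp$movable)
          ctrace[[length(ctrace) + 1]] <- data.frame(
            round = round, id = comp$id,
            center_row = comp$center[1], center_col = comp$center[2],
            height = comp$size[1], width = comp$size[2])
      state$l <- state$l + 1L
    }
    if (moved == 0L && !changed) break
  }
  final <- current_layout(state)
  structure(list(layout = final,
                 cost = total_cost(graph, final, params,
                                   compartments = state$compartments,
                                   l = state$l, gdc = state$gdc),
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(),
                 steps = state$moves,
                 converged = TRUE,
                 state = state,
                 compartments = state$compartments,
                 compartment_trace = if (length(ctrace))
                   do.call(rbind, ctrace) else data.frame()),
            class = "pathgrid_fit")
}
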