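# Greedy grid search with delta-cost caches.
#
# The search state is an environment holding, for every (node, grid point)
# pair, the exact change in each cost component if that node moved there:
#   field   — repulsion field: sum_u F_r(d(q, P(u))) over all placed nodes,
#             with the zero-distance self term dropped (finite everywhere);
#   repnode — per node v, sum_{u != v} F_r(d(P(v), P(u)));
#   frq     — F_r(d(q, P(v))) per (point, node), so the repulsion delta is
#             field[q] - frq[q, v] - repnode[v] in O(1);
#   da      — attraction deltas (only v and its neighbours change per move);
#   dee/dne — crossing-count deltas, maintained in C++ via the case analysis
#             of which terms a single move can touch.
# Every accepted move updates the caches incrementally; a full recompute
# every `refresh_every` moves bounds floating-point drift.

CONV_TOL <- 1e-9

fr_contrib <- function(state, p) {
  d2 <- (state$coords[, 1] - p[1])^2 + (state$coords[, 2] - p[2])^2
  v <- state$params$f_r(sqrt(d2))
  v[d2 == 0] <- 0
  v
}

refresh_caches <- function(state) {
  n <- length(state$ids)
  hw <- state$grid$h * state$grid$w
  pos <- state$pos
  f_r <- state$params$f_r; f_a <- state$params$f_a

  state$field <- rep(0, hw)
  for (i in seq_len(n)) state$field <- state$field + fr_contrib(state, pos[i, ])

  if (n >= 2) {
    dm <- as.matrix(stats::dist(pos))
    fm <- f_r(dm); diag(fm) <- 0
    state$repnode <- rowSums(fm)
  } else state$repnode <- rep(0, n)

  state$frq <- matrix(0, hw, n)
  state$da <- matrix(0, hw, n)
  for (i in seq_len(n)) {
    d <- sqrt((state$coords[, 1] - pos[i, 1])^2 +
              (state$coords[, 2] - pos[i, 2])^2)
    state$frq[, i] <- f_r(d)
    nbi <- state$nb[[i]]
    if (length(nbi)) {
      acc <- rep(0, hw); cur <- 0
      for (u in nbi) {
        du <- sqrt((state$coords[, 1] - pos[u, 1])^2 +
                   (state$coords[, 2] - pos[u, 2])^2)
        acc <- acc + f_a(du)
        cur <- cur + f_a(sqrt(sum((pos[i, ] - pos[u, ])^2)))
      }
      state$da[, i] <- acc - cur
    }
  }

  state$dee <- matrix(0L, hw, n)
  state$dne <- matrix(0L, hw, n)
  for (i in seq_len(n)) {
    bd <- cpp_bulk_deltas(i - 1L, pos, state$ei0, state$grid$h, state$grid$w)
    state$dee[, i] <- bd$dee
    state$dne[, i] <- bd$dne
  }

  bk <- total_cost(state$graph, current_layout(state), state$params,
                   compartments = state$compartments, l = state$l,
                   gdc = state$gdc)
  state$comp_attr <- bk$attraction
  state$comp_rep <- bk$repulsion
  state$comp_ee <- bk$ee
  state$comp_ne <- bk$ne
  state$n_near <- sum(state$band[state$idx])
  invisible(state)
}

current_layout <- function(state) {
  pts <- state$pos
  rownames(pts) <- state$ids
  grid_layout(pts, state$grid)
}

current_total <- function(state) {
  p <- state$params
  s <- if (state$gdc) state$alpha * exp(-p$beta * state$l) else 0
  p$w_a * state$comp_attr + p$w_r * state$comp_rep +
    p$w_e * state$comp_ee + p$w_n * state$comp_ne + s * state$n_near
}

#' Initialize the delta-cost caches for the greedy grid search
#'
#' Builds the full search state: the repulsion field over all grid points,
#' per-node repulsion/attraction delta caches, and the crossing-count delta
#' tables for every (node, grid point) pair. Nodes with no admissible vacant
#' point raise a warning and simply contribute no candidate moves until
#' space frees up.
#'
#' @param graph a [pathway_graph()].
#' @param layout a valid initial [grid_layout()].
#' @param params a [cost_params()].
#' @param constraints a [build_constraints()] result.
#' @param gdc activate the surface penalty / dynamic-compartment bookkeeping.
#' @param compartments compartment list (required when `gdc = TRUE`).
#' @return A search-state environment of class `pathgrid_state`.
#' @export
init_caches <- function(graph, layout, params, constraints,
                        gdc = FALSE, compartments = NULL) {
  grid <- constraints$grid
  state <- new.env(parent = emptyenv())
  class(state) <- "pathgrid_state"
  state$graph <- graph
  state$grid <- grid
  state$params <- params
  state$constraints <- constraints
  state$gdc <- gdc
  state$compartments <- if (gdc) compartments else constraints$compartments
  state$l <- 0L
  state$alpha <- resolve_alpha(params, grid)
  state$ids <- graph$nodes$id
  state$ei <- edge_index(graph)
  state$ei0 <- state$ei - 1L
  storage.mode(state$ei0) <- "integer"
  state$nb <- neighbor_index(graph)
  state$coords <- grid_coords(grid)

  pos <- layout_positions(graph, layout)
  state$pos <- pos
  state$idx <- point_index(pos, grid)
  if (anyDuplicated(state$idx)) stop("initial layout has node collisions")
  hw <- grid$h * grid$w
  state$occupied <- rep(FALSE, hw)
  state$occupied[state$idx] <- TRUE

  n <- length(state$ids)
  state$adm <- matrix(FALSE, hw, n)
  for (i in seq_len(n)) {
    tag <- graph$nodes$localization[i]
    pts <- state$constraints$admissible[[tag]]
    if (is.null(pts)) stop("no constraint region for tag '", tag, "'")
    state$adm[pts, i] <- TRUE
  }
  frozen <- which(colSums(state$adm & !state$occupied) == 0)
  if (length(frozen))
    warning("no admissible vacant point for node(s): ",
            paste(state$ids[frozen], collapse = ", "),
            " — frozen until space frees up")

  state$band <- if (gdc) surface_band(state$compartments, grid)
                else rep(FALSE, hw)
  state$moves <- 0L
  state$refresh_every <- 200L
  refresh_caches(state)
  state
}

#' @export
print.pathgrid_state <- function(x, ...) {
  cat(sprintf("<pathgrid_state> %d nodes, %dx%d grid, %d moves applied\n",
              length(x$ids), x$grid$h, x$grid$w, x$moves))
  invisible(x)
}

# total-cost delta matrix (hw x n); inadmissible entries are +Inf
delta_matrix <- function(state) {
  p <- state$params
  dr <- state$field - state$frq -
    matrix(state$repnode, nrow(state$frq), ncol(state$frq), byrow = TRUE)
  d <- p$w_a * state$da + p$w_r * dr +
    p$w_e * state$dee + p$w_n * state$dne
  if (state$gdc && any(state$band)) {
    s <- state$alpha * exp(-p$beta * state$l)
    d <- d + s * (matrix(state$band, nrow(d), ncol(d)) -
                  matrix(state$band[state$idx], nrow(d), ncol(d), byrow = TRUE))
  }
  d[!(state$adm & !state$occupied)] <- Inf
  d
}

#' Best admissible move
#'
#' The (node, vacant admissible grid point) pair with the most negative
#' total-cost delta; ties break on the lowest (node id, row, col). Returns
#' `NULL` when no move decreases the cost by more than the convergence
#' tolerance (1e-9) — the search has converged.
#'
#' @param state a [init_caches()] search state.
#' @return `NULL`, or a list with `node` (id), `node_i`, `point` (index),
#'   `delta`.
#' @export
best_move <- function(state) {
  d <- delta_matrix(state)
  k <- which.min(d)
  if (!length(k) || !is.finite(d[k]) || d[k] >= -CONV_TOL) return(NULL)
  q <- (k - 1L) %% nrow(d) + 1L
  vi <- (k - 1L) %/% nrow(d) + 1L
  list(node = state$ids[vi], node_i = vi, point = q, delta = d[k])
}

#' Apply a move and update all caches incrementally
#'
#' Relocates one node and refreshes the caches: the repulsion field gains
#' the new position's contribution and loses the old one; attraction deltas
#' are recomputed only for the moved node and its neighbours (no other
#' node's attraction delta can change); crossing-delta columns are adjusted
#' in C++ by exactly the terms that involve the moved node or its edges.
#' After the update the caches equal a fresh [init_caches()] re-build (this
#' is asserted wholesale in the test suite). A full recompute runs every 200
#' accepted moves to bound floating-point drift.
#'
#' @param state a search state.
#' @param move a [best_move()] result.
#' @return The state, invisibly (modified in place).
#' @export
apply_move_and_update <- function(state, move) {
  vi <- move$node_i
  q <- move$point
  if (state$occupied[q]) stop("internal error: target grid point occupied")
  old <- state$pos[vi, ]
  oldidx <- state$idx[vi]
  newpt <- as.numeric(index_point(q, state$grid))

  # component bookkeeping from the cached deltas
  p <- state$params
  state$comp_attr <- state$comp_attr + state$da[q, vi]
  state$comp_rep <- state$comp_rep +
    (state$field[q] - state$frq[q, vi] - state$repnode[vi])
  state$comp_ee <- state$comp_ee + state$dee[q, vi]
  state$comp_ne <- state$comp_ne + state$dne[q, vi]
  state$n_near <- state$n_near + state$band[q] - state$band[oldidx]

  # position & occupancy
  state$pos[vi, ] <- newpt
  state$idx[vi] <- q
  state$occupied[oldidx] <- FALSE
  state$occupied[q] <- TRUE

  # repulsion field and per-node repulsion
  state$field <- state$field + fr_contrib(state, newpt) - fr_contrib(state, old)
  n <- length(state$ids)
  if (n >= 2) {
    others <- setdiff(seq_len(n), vi)
    d_new <- sqrt(rowSums((state$pos[others, , drop = FALSE] -
                           matrix(newpt, length(others), 2, byrow = TRUE))^2))
    d_old <- sqrt(rowSums((state$pos[others, , drop = FALSE] -
                           matrix(old, length(others), 2, byrow = TRUE))^2))
    state$repnode[others] <- state$repnode[others] +
      p$f_r(d_new) - p$f_r(d_old)
    state$repnode[vi] <- sum(p$f_r(d_new))
  }
  d <- sqrt((state$coords[, 1] - newpt[1])^2 + (state$coords[, 2] - newpt[2])^2)
  state$frq[, vi] <- p$f_r(d)

  # attraction deltas: only v and N(v) are affected
  hw <- nrow(state$frq)
  for (i in c(vi, state$nb[[vi]])) {
    nbi <- state$nb[[i]]
    if (!length(nbi)) next
    acc <- rep(0, hw); cur <- 0
    for (u in nbi) {
      du <- sqrt((state$coords[, 1] - state$pos[u, 1])^2 +
                 (state$coords[, 2] - state$pos[u, 2])^2)
      acc <- acc + p$f_a(du)
      cur <- cur + p$f_a(sqrt(sum((state$pos[i, ] - state$pos[u, ])^2)))
    }
    state$da[, i] <- acc - cur
  }

  # crossing deltas: C++ case analysis
  upd <- cpp_update_crossing_cache(state$dee, state$dne, vi - 1L,
                                   old[1], old[2], state$pos, state$ei0,
                                   state$grid$h, state$grid$w)
  state$dee <- upd$dee
  state$dne <- upd$dne

  state$moves <- state$moves + 1L
  if (state$moves %% state$refresh_every == 0L) refresh_caches(state)
  invisible(state)
}

trace_row <- function(state, move) {
  s <- if (state$gdc) state$alpha * exp(-state$params$beta * state$l) else 0
  data.frame(step = state$moves, node = move$node,
             to_row = state$pos[move$node_i, 1],
             to_col = state$pos[move$node_i, 2],
             delta = move$delta,
             attraction = state$comp_attr, repulsion = state$comp_rep,
             ee = state$comp_ee, ne = state$comp_ne,
             surface = s * state$n_near,
             total = current_total(state))
}

#' Greedy grid-layout optimization
#'
#' Starting from an admissible layout (random if none is given), repeatedly
#' applies the single (node, vacant admissible grid point) move that most
#' decreases the total cost, until no move improves it by more than the
#' tolerance or `max_steps` moves were accepted. The cost trace is strictly
#' decreasing, so termination is guaranteed.
#'
#' @param graph a [pathway_graph()].
#' @param grid a [layout_grid()].
#' @param constraints a [build_constraints()] result (`NULL` = build an
#'   unconstrained map — the "no location information" mode).
#' @param params a [cost_params()].
#' @param layout optional initial [grid_layout()]; must be admissible.
#' @param max_steps accepted-move cap; default `10 * |V|`.
#' @param seed RNG seed for the random initial layout (only used when
#'   `layout` is `NULL`; the search itself is deterministic).
#' @return Object of class `pathgrid_fit`: list with `layout`, `cost`
#'   (final [total_cost()] breakdown), `trace` (one row per accepted move),
#'   `steps`, `converged`, and the final search `state`.
#' @export
optimize_layout <- function(graph, grid, constraints = NULL,
                            params = cost_params(), layout = NULL,
                            max_steps = 10 * n_nodes(graph), seed = NULL) {
  if (is.null(constraints))
    constraints <- build_constraints(NULL, grid, graph)
  if (is.null(layout))
    layout <- random_layout(graph, grid, constraints, seed = seed)
  viol <- validate_layout(graph, layout, constraints)
  if (nrow(viol))
    stop("initial layout is inadmissible:\n",
         paste(sprintf("  [%s] %s: %s", viol$type, viol$node, viol$detail),
               collapse = "\n"))
  state <- init_caches(graph, layout, params, constraints)
  trace <- list()
  converged <- FALSE
  while (state$moves < max_steps) {
    mv <- best_move(state)
    if (is.null(mv)) { converged <- TRUE; break }
    apply_move_and_update(state, mv)
    trace[[length(trace) + 1]] <- trace_row(state, mv)
  }
  if (state$moves >= max_steps && is.null(best_move(state)))
    converged <- TRUE
  final <- current_layout(state)
  structure(list(layout = final,
                 cost = total_cost(graph, final, params),
                 trace = if (length(trace)) do.call(rbind, trace)
                         else trace_row(state, list(node = NA, node_i = 1,
                                                    delta = 0))[0, ],
                 steps = state$moves, converged = converged, state = state),
            class = "pathgrid_fit")
}

#' @export
print.pathgrid_fit <- function(x, ...) {
  cat(sprintf("<pathgrid_fit> %d accepted moves (%s)\n", x$steps,
              if (x$converged) "converged" else "step limit"))
  print(x$cost)
  invisible(x)
}
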