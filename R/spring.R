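# Continuous-space spring-embedder baseline.  Attraction d^2 along edges,
# repulsion 1/d^2 between all pairs; per-iteration displacement along the
# net force, capped by a linearly cooling step size; no localization
# constraints (the baseline ignores location information by design).

#' One spring-embedder step
#'
#' Displaces every node along its net force — attraction `f_a(d)` toward
#' each neighbour, repulsion `f_r(d)` away from every other node — with the
#' displacement magnitude capped at `step_size`. Coincident nodes are
#' jittered apart first. Positions are clamped to the canvas.
#'
#' @param layout n x 2 matrix of real (row, col) coordinates, row names =
#'   node ids.
#' @param graph a [pathway_graph()].
#' @param step_size displacement cap (grid units).
#' @param canvas c(height, width).
#' @param f_a,f_r force functions of distance.
#' @return Updated coordinate matrix.
#' @export
spring_step <- function(layout, graph, step_size, canvas,
                        f_a = function(d) d^2, f_r = function(d) 1 / d^2) {
  pos <- layout_positions(graph, layout)
  n <- nrow(pos)
  if (n < 2) return(layout)
  # jitter exact coincidences
  repeat {
    d <- as.matrix(stats::dist(pos))
    dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
    if (!nrow(dup)) break
    for (k in seq_len(nrow(dup)))
      pos[dup[k, 2], ] <- pos[dup[k, 2], ] + stats::runif(2, -0.01, 0.01)
  }
  force <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    diff <- sweep(pos, 2, pos[i, ])           # vectors i -> others
    dd <- sqrt(rowSums(diff^2)); dd[i] <- Inf
    unit <- diff / dd
    rep_mag <- f_r(dd); rep_mag[i] <- 0
    force[i, ] <- -colSums(unit * rep_mag)    # push away from others
  }
  ei <- edge_index(graph)
  for (k in seq_len(nrow(ei))) {
    a <- ei[k, 1]; b <- ei[k, 2]
    diff <- pos[b, ] - pos[a, ]
    dd <- sqrt(sum(diff^2))
    pull <- f_a(dd) * diff / dd
    force[a, ] <- force[a, ] + pull
    force[b, ] <- force[b, ] - pull
  }
  mag <- sqrt(rowSums(force^2))
  scale <- ifelse(mag > 0, pmin(mag, step_size) / mag, 0)
  pos <- pos + force * scale
  pos[, 1] <- pmin(pmax(pos[, 1], 0), canvas[1])
  pos[, 2] <- pmin(pmax(pos[, 2], 0), canvas[2])
  pos
}

#' Run the spring-embedder baseline
#'
#' Random initial placement on the canvas, then `iters` steps with a
#' linearly decaying step size. Deterministic for a fixed seed. Crossing
#' metrics for the result are measured directly on the continuous segments
#' (no snapping to the grid).
#'
#' @param graph a [pathway_graph()].
#' @param canvas c(height, width); a [layout_grid()] is also accepted.
#' @param iters iteration count (default 500).
#' @param seed RNG seed.
#' @param layout optional initial coordinates (skips the random init).
#' @param f_a,f_r force functions.
#' @return n x 2 coordinate matrix of class `spring_layout` with the canvas
#'   as attribute.
#' @export
spring_run <- function(graph, canvas, iters = 500, seed = NULL,
                       layout = NULL,
                       f_a = function(d) d^2, f_r = function(d) 1 / d^2) {
  stopifnot(iters >= 1)
  if (inherits(canvas, "layout_grid")) canvas <- c(canvas$h - 1, canvas$w - 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(graph)
  if (is.null(layout)) {
    pos <- cbind(stats::runif(n, 0, canvas[1]), stats::runif(n, 0, canvas[2]))
    rownames(pos) <- graph$nodes$id
  } else pos <- layout_positions(graph, layout)
  t0 <- min(canvas) / 10
  for (it in seq_len(iters)) {
    step <- t0 * (1 - (it - 1) / iters) + 1e-3
    pos <- spring_step(pos, graph, step, canvas, f_a = f_a, f_r = f_r)
  }
  colnames(pos) <- c("row", "col")
  structure(pos, class = "spring_layout", canvas = canvas)
}

#' Snap a continuous layout to the nearest grid points
#'
#' Rounds each coordinate to the nearest lattice point and clamps to the
#' grid. Used when comparing the spring baseline's crossing counts with grid
#' layouts on equal terms; note snapping can create node collisions and
#' collinear overlaps, which the crossing counters handle exactly.
#'
#' @param layout a `spring_layout` (or any node -> real coordinate matrix).
#' @param grid a [layout_grid()].
#' @return A [grid_layout()] (possibly with coincident nodes).
#' @export
snap_layout <- function(layout, grid) {
  pts <- unclass(layout)
  pts <- round(pts)
  pts[, 1] <- pmin(pmax(pts[, 1], 0), grid$h - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), grid$w - 1)
  grid_layout(pts, grid)
}

#' @export
print.spring_layout <- function(x, ...) {
  cv <- attr(x, "canvas")
  cat(sprintf("<spring_layout> %d nodes on %.0fx%.0f canvas\n",
              nrow(x), cv[1], cv[2]))
  invisible(x)
}
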