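#' Cost parameters
#'
#' Weights and force functions for the layout cost. The cost of a layout is
#' `w_a * sum_edges F_a(d) + w_r * sum_pairs F_r(d) + w_e * ee + w_n * ne
#' + surface penalty`, with Euclidean distances in grid units, each edge and
#' each unordered node pair counted once, and `ee`/`ne` the exact crossing
#' counts. The default forces are the classical spring-embedder pair
#' `F_a(d) = d^2`, `F_r(d) = 1/d^2`.
#'
#' When only `w_e` is given, `w_n` defaults to `2 * w_e`: node-edge
#' crossings hide which edges attach to a node and are treated as twice as
#' harmful as edge-edge crossings.
#'
#' The surface penalty is active only in the dynamic-compartment mode: each
#' node within one grid unit of a movable compartment's surface costs
#' `alpha * exp(-beta * l)`, where `l` counts compartment-update rounds.
#' `alpha = NULL` resolves to `20 * (w + h)` of the grid in use.
#'
#' @param w_a,w_r,w_e,w_n non-negative weights.
#' @param alpha surface-penalty scale (`NULL` = `20 * (w + h)`).
#' @param beta surface-penalty decay rate per update round (> 0).
#' @param f_a,f_r attraction/repulsion force functions of distance.
#' @return Object of class `cost_params`.
#' @export
cost_params <- function(w_a = 1, w_r = 1, w_e = 10, w_n = 2 * w_e,
                        alpha = NULL, beta = 0.002,
                        f_a = function(d) d^2, f_r = function(d) 1 / d^2) {
  stopifnot(w_a >= 0, w_r >= 0, w_e >= 0, w_n >= 0, beta > 0)
  structure(list(w_a = w_a, w_r = w_r, w_e = w_e, w_n = w_n,
                 alpha = alpha, beta = beta, f_a = f_a, f_r = f_r),
            class = "cost_params")
}

#' Named weight presets
#'
#' Weight sets used for the three study pathways: `"fas"` (apoptosis
#' signalling; w_a=1, w_r=1, w_e=10, w_n=20), `"elegans"` (neuronal
#' cell-fate model; 1, 1, 50, 100) and `"endothelial"` (TNF response model;
#' 12, 1, 50, 100).
#'
#' @param name preset name.
#' @param ... overrides passed on to [cost_params()].
#' @return A [cost_params()] object.
#' @export
preset_weights <- function(name = c("fas", "elegans", "endothelial"), ...) {
  name <- match.arg(name)
  w <- switch(name,
              fas = list(w_a = 1, w_r = 1, w_e = 10, w_n = 20),
              elegans = list(w_a = 1, w_r = 1, w_e = 50, w_n = 100),
              endothelial = list(w_a = 12, w_r = 1, w_e = 50, w_n = 100))
  do.call(cost_params, c(w, list(...)))
}

resolve_alpha <- function(params, grid) {
  if (!is.null(params$alpha)) params$alpha else 20 * (grid$w + grid$h)
}

#' Attraction-force sum
#'
#' `sum F_a(d(P(v), P(u)))` over adjacent pairs, each edge counted once.
#'
#' @param graph a [pathway_graph()].
#' @param layout node -> coordinate assignment.
#' @param f_a force function of distance.
#' @return Numeric scalar.
#' @export
attraction_sum <- function(graph, layout, f_a = function(d) d^2) {
  ei <- edge_index(graph)
  if (nrow(ei) == 0) return(0)
  pos <- layout_positions(graph, layout)
  d <- sqrt(rowSums((pos[ei[, 1], , drop = FALSE] -
                     pos[ei[, 2], , drop = FALSE])^2))
  sum(f_a(d))
}

#' Repulsion-force sum
#'
#' `sum F_r(d(P(v), P(u)))` over all unordered node pairs, each once.
#'
#' @inheritParams attraction_sum
#' @param f_r force function of distance.
#' @return Numeric scalar.
#' @export
repulsion_sum <- function(graph, layout, f_r = function(d) 1 / d^2) {
  pos <- layout_positions(graph, layout)
  n <- nrow(pos)
  if (n < 2) return(0)
  d <- stats::dist(pos)
  sum(f_r(as.numeric(d)))
}

# logical mask over grid points within one grid unit of the surface of any
# movable compartment: points with a 4-neighbour of opposite membership
surface_band <- function(compartments, grid) {
  band <- rep(FALSE, grid$h * grid$w)
  if (is.null(compartments)) return(band)
  for (comp in compartments) {
    if (!comp$movable) next
    m <- matrix(shape_mask(comp, grid), nrow = grid$h, ncol = grid$w,
                byrow = TRUE)
    up <- rbind(m[-1, , drop = FALSE], m[grid$h, , drop = FALSE])
    dn <- rbind(m[1, , drop = FALSE], m[-grid$h, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], m[, grid$w, drop = FALSE])
    rt <- cbind(m[, 1, drop = FALSE], m[, -grid$w, drop = FALSE])
    edge <- (m != up) | (m != dn) | (m != lf) | (m != rt)
    band <- band | as.vector(t(edge))
  }
  band
}

#' Compartment-surface penalty
#'
#' `alpha * exp(-beta * l)` for every node located within one grid unit of
#' the surface of a movable compartment; zero when the dynamic-compartment
#' mode is off (`gdc = FALSE`) or no compartment is movable. The penalty
#' discourages parking nodes against surfaces early on (which would pin the
#' compartment) and decays to zero as the update-round counter `l` grows, so
#' it cannot prevent convergence.
#'
#' @param graph a [pathway_graph()].
#' @param layout a [grid_layout()].
#' @param compartments list of [compartment()]s.
#' @param grid a [layout_grid()].
#' @param l update-round counter (>= 0).
#' @param alpha,beta penalty parameters (see [cost_params()]).
#' @param gdc is the dynamic-compartment mode active?
#' @return Numeric scalar.
#' @export
surface_penalty <- function(graph, layout, compartments, grid, l = 0,
                            alpha = NULL, beta = 0.002, gdc = TRUE) {
  if (!gdc || is.null(compartments)) return(0)
  band <- surface_band(compartments, grid)
  if (!any(band)) return(0)
  if (is.null(alpha)) alpha <- 20 * (grid$w + grid$h)
  pos <- layout_positions(graph, layout)
  n_near <- sum(band[point_index(pos, grid)])
  alpha * exp(-beta * l) * n_near
}

#' Full cost of a layout
#'
#' Evaluates every component and the weighted total. With `gdc = FALSE`
#' (the default) the surface penalty is identically zero.
#'
#' @param graph a [pathway_graph()].
#' @param layout a [grid_layout()].
#' @param params a [cost_params()].
#' @param compartments compartments (needed only for the surface penalty).
#' @param l update-round counter for the surface penalty.
#' @param gdc is the dynamic-compartment mode active?
#' @return Object of class `cost_breakdown`: list with `attraction`,
#'   `repulsion`, `ee`, `ne`, `surface` and `total`.
#' @export
total_cost <- function(graph, layout, params = cost_params(),
                       compartments = NULL, l = 0, gdc = FALSE) {
  grid <- attr(layout, "grid")
  att <- attraction_sum(graph, layout, params$f_a)
  rep_ <- repulsion_sum(graph, layout, params$f_r)
  cr <- count_all_crossings(graph, layout)
  sp <- surface_penalty(graph, layout, compartments, grid, l = l,
                        alpha = params$alpha, beta = params$beta, gdc = gdc)
  structure(list(attraction = att, repulsion = rep_,
                 ee = unname(cr["ee"]), ne = unname(cr["ne"]), surface = sp,
                 total = unname(params$w_a * att + params$w_r * rep_ +
                   params$w_e * cr["ee"] + params$w_n * cr["ne"] + sp)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<cost_breakdown> total=%.4f  (attraction=%.4f ",
                     "repulsion=%.4f ee=%d ne=%d surface=%.4f)\n"),
              x$total, x$attraction, x$repulsion, x$ee, x$ne, x$surface))
  invisible(x)
}

#' @export
format.cost_breakdown <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
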