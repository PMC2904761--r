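# Independent R oracles: vectorized orientation-test geometry and
# brute-force cost evaluation, used to cross-check the package's C++
# backend.  All arithmetic is on integer grid coordinates, where doubles
# are exact.

# internal helpers used by fixtures/oracles
layout_positions <- pathgrid:::layout_positions
edge_index <- pathgrid:::edge_index
index_point <- pathgrid:::index_point
point_index <- pathgrid:::point_index

or3 <- function(ax, ay, bx, by, cx, cy)
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))

# vectorized open-interior segment intersection
oracle_cross_vec <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- or3(cx, cy, dx, dy, ax, ay)
  d2 <- or3(cx, cy, dx, dy, bx, by)
  d3 <- or3(ax, ay, bx, by, cx, cy)
  d4 <- or3(ax, ay, bx, by, dx, dy)
  proper <- d1 * d2 < 0 & d3 * d4 < 0
  coll <- d1 == 0 & d2 == 0 & d3 == 0 & d4 == 0
  horiz <- abs(bx - ax) >= abs(by - ay)
  alo <- ifelse(horiz, pmin(ax, bx), pmin(ay, by))
  ahi <- ifelse(horiz, pmax(ax, bx), pmax(ay, by))
  blo <- ifelse(horiz, pmin(cx, dx), pmin(cy, dy))
  bhi <- ifelse(horiz, pmax(cx, dx), pmax(cy, dy))
  degen <- (ax == bx & ay == by) | (cx == dx & cy == dy)
  overlap <- coll & pmax(alo, blo) < pmin(ahi, bhi)
  as.integer((proper | overlap) & !degen)
}

# vectorized strict-interior point-on-segment
oracle_on_vec <- function(px, py, ax, ay, bx, by) {
  coll <- or3(ax, ay, bx, by, px, py) == 0
  dot1 <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
  dot2 <- (px - bx) * (ax - bx) + (py - by) * (ay - by)
  degen <- ax == bx & ay == by
  as.integer(coll & dot1 > 0 & dot2 > 0 & !degen)
}

# pairwise-enumeration crossing counts; pos is n x 2, ei is m x 2 (1-based)
oracle_count <- function(pos, ei) {
  m <- nrow(ei)
  ee <- 0L
  if (m >= 2) {
    pr <- t(utils::combn(m, 2))
    i <- pr[, 1]; j <- pr[, 2]
    shared <- ei[i, 1] == ei[j, 1] | ei[i, 1] == ei[j, 2] |
      ei[i, 2] == ei[j, 1] | ei[i, 2] == ei[j, 2]
    cr <- oracle_cross_vec(pos[ei[i, 1], 1], pos[ei[i, 1], 2],
                           pos[ei[i, 2], 1], pos[ei[i, 2], 2],
                           pos[ei[j, 1], 1], pos[ei[j, 1], 2],
                           pos[ei[j, 2], 1], pos[ei[j, 2], 2])
    ee <- sum(cr[!shared])
  }
  ne <- 0L
  if (m >= 1) {
    n <- nrow(pos)
    u <- rep(seq_len(n), times = m)
    e <- rep(seq_len(m), each = n)
    endpoint <- u == ei[e, 1] | u == ei[e, 2]
    on <- oracle_on_vec(pos[u, 1], pos[u, 2],
                        pos[ei[e, 1], 1], pos[ei[e, 1], 2],
                        pos[ei[e, 2], 1], pos[ei[e, 2], 2])
    ne <- sum(on[!endpoint])
  }
  c(ee = ee, ne = ne)
}

# full recount of the candidate table for node vi (1-based): for each grid
# point q, oracle counts with vi moved to q, minus counts at the current spot
oracle_bulk <- function(vi, pos, ei, grid) {
  base <- oracle_count(pos, ei)
  hw <- grid$h * grid$w
  dee <- integer(hw); dne <- integer(hw)
  for (q in seq_len(hw)) {
    p2 <- pos
    p2[vi, ] <- index_point(q, grid)
    cnt <- oracle_count(p2, ei)
    dee[q] <- cnt["ee"] - base["ee"]
    dne[q] <- cnt["ne"] - base["ne"]
  }
  list(dee = dee, dne = dne)
}

# brute-force total cost (no surface term), independent of the C++ path
oracle_total <- function(pos, ei, params) {
  att <- 0
  if (nrow(ei))
    att <- sum(params$f_a(sqrt(rowSums(
      (pos[ei[, 1], , drop = FALSE] - pos[ei[, 2], , drop = FALSE])^2))))
  rep_ <- if (nrow(pos) >= 2)
    sum(params$f_r(as.numeric(dist(pos)))) else 0
  cnt <- oracle_count(pos, ei)
  params$w_a * att + params$w_r * rep_ +
    params$w_e * cnt["ee"] + params$w_n * cnt["ne"]
}

# small random test instance: graph, grid, layout, index matrices
random_instance <- function(n, m, h, w, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pool <- t(utils::combn(n, 2))
  pool <- pool[sample.int(nrow(pool), min(m, nrow(pool))), , drop = FALSE]
  g <- pathway_graph(
    data.frame(id = ids, localization = "cytoplasm"),
    cbind(ids[pool[, 1]], ids[pool[, 2]]))
  grid <- layout_grid(h, w)
  cons <- build_constraints(NULL, grid, g)
  lay <- random_layout(g, grid, cons, seed = seed + 5000)
  list(graph = g, grid = grid, cons = cons, layout = lay,
       pos = layout_positions(g, lay), ei = edge_index(g))
}

# tiny deterministic graph builders
toy_graph <- function(edges, tags = NULL) {
  ids <- sort(unique(c(edges)))
  if (is.null(tags)) tags <- setNames(rep("cytoplasm", length(ids)), ids)
  pathway_graph(data.frame(id = ids, localization = tags[ids]), edges)
}

place <- function(graph, grid, ...) {
  pts <- rbind(...)
  rownames(pts) <- graph$nodes$id
  grid_layout(pts, grid)
}
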