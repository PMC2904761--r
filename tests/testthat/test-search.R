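test_that("initial delta caches equal brute force on a tiny instance", {
  grid <- layout_grid(3, 3)
  g <- pathway_graph(data.frame(id = c("a", "b"), localization = "cytoplasm"),
                     matrix(character(), ncol = 2))
  cons <- build_constraints(NULL, grid, g)
  lay <- place(g, grid, c(0, 0), c(2, 2))
  p <- cost_params(w_a = 1, w_r = 1, w_e = 10, w_n = 20)
  st <- init_caches(g, lay, p, cons)

  pos <- layout_positions(g, lay)
  ei <- edge_index(g)
  base <- oracle_total(pos, ei, p)
  for (vi in 1:2) {
    for (q in seq_len(9)) {
      qpt <- index_point(q, grid)
      occupied <- any(point_index(pos, grid) == q)
      if (occupied) next
      p2 <- pos; p2[vi, ] <- qpt
      brute <- oracle_total(p2, ei, p) - base
      d <- pathgrid:::delta_matrix(st)
      expect_equal(d[q, vi], unname(brute), tolerance = 1e-12,
                   info = sprintf("node %d point %d", vi, q))
    }
  }
})

test_that("all-zero weights give all-zero deltas", {
  inst <- random_instance(6, 7, 5, 5, seed = 1)
  p <- cost_params(w_a = 0, w_r = 0, w_e = 0, w_n = 0)
  st <- init_caches(inst$graph, inst$layout, p, inst$cons)
  d <- pathgrid:::delta_matrix(st)
  expect_true(all(d[is.finite(d)] == 0))
  expect_null(best_move(st))
})

test_that("best_move returns the most negative admissible delta", {
  inst <- random_instance(7, 8, 6, 6, seed = 2)
  st <- init_caches(inst$graph, inst$layout, cost_params(), inst$cons)
  d <- pathgrid:::delta_matrix(st)
  mv <- best_move(st)
  expect_false(is.null(mv))
  expect_equal(mv$delta, min(d))
  expect_equal(d[mv$point, mv$node_i], mv$delta)
})

test_that("caches equal a fresh re-init after every accepted move", {
  for (s in 1:8) {
    inst <- random_instance(n = sample(6:12, 1), m = sample(6:14, 1),
                            h = 7, w = 7, seed = 400 + s)
    p <- cost_params()
    st <- init_caches(inst$graph, inst$layout, p, inst$cons)
    for (k in 1:6) {
      mv <- best_move(st)
      if (is.null(mv)) break
      apply_move_and_update(st, mv)
      fresh <- init_caches(inst$graph, pathgrid:::current_layout(st), p,
                           inst$cons)
      expect_identical(st$dee, fresh$dee)
      expect_identical(st$dne, fresh$dne)
      expect_equal(st$da, fresh$da, tolerance = 1e-9)
      expect_equal(st$field, fresh$field, tolerance = 1e-9)
      expect_equal(st$repnode, fresh$repnode, tolerance = 1e-9)
    }
  }
})

test_that("moving a lone far-away node strictly lowers repulsion", {
  g <- pathway_graph(data.frame(id = c("a", "b", "c"),
                                localization = "cytoplasm"),
                     matrix(character(), ncol = 2))
  grid <- layout_grid(8, 8)
  lay <- place(g, grid, c(0, 0), c(0, 1), c(1, 0))   # clustered corner
  r0 <- repulsion_sum(g, lay)
  far <- place(g, grid, c(0, 0), c(0, 1), c(7, 7))
  expect_lt(repulsion_sum(g, far), r0)
})

test_that("an already-optimal layout is returned unchanged with empty trace", {
  g <- toy_graph(rbind(c("a", "b")))
  grid <- layout_grid(3, 3)
  # adjacent placement: attraction 1, repulsion 1; no move can beat it
  lay <- place(g, grid, c(1, 1), c(1, 2))
  fit <- optimize_layout(g, grid, NULL, cost_params(), layout = lay)
  expect_equal(fit$steps, 0)
  expect_equal(nrow(fit$trace), 0)
  expect_true(fit$converged)
  expect_equal(unclass(fit$layout), unclass(lay), ignore_attr = TRUE)
})

test_that("greedy search finds the exhaustive optimum for a 3-path", {
  g <- toy_graph(rbind(c("a", "b"), c("b", "c")))
  grid <- layout_grid(4, 4)
  # a and c adjacent, b far away
  lay <- place(g, grid, c(0, 0), c(3, 3), c(0, 1))
  p <- cost_params(w_a = 1, w_r = 1, w_e = 10, w_n = 20)
  fit <- optimize_layout(g, grid, NULL, p, layout = lay)
  expect_lt(fit$cost$total, total_cost(g, lay, p)$total)

  # exhaustive search over all injective placements of 3 nodes on 16 points
  ei <- edge_index(g)
  best <- Inf
  pts <- pathgrid:::grid_coords(grid)
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    if (i == j || j == k || i == k) next
    best <- min(best, oracle_total(rbind(pts[i, ], pts[j, ], pts[k, ]), ei, p))
  }
  expect_equal(fit$cost$total, unname(best), tolerance = 1e-9)
})

test_that("optimizer rejects inadmissible starting layouts", {
  g <- toy_graph(rbind(c("a", "b")), tags = c(a = "nucleus", b = "nucleus"))
  grid <- layout_grid(6, 6)
  comps <- list(compartment("nucleus", "rectangle", center = c(1, 1),
                            size = c(2, 2)))
  cons <- build_constraints(comps, grid, g)
  bad <- place(g, grid, c(5, 5), c(0, 0))
  expect_error(optimize_layout(g, grid, cons, layout = bad), "inadmissible")
})

test_that("constrained optimization keeps layouts admissible and monotone", {
  g <- generate_pathway(40, 46, seed = 5)
  grid <- grid_dims(40)
  comps <- default_compartments(grid)
  cons <- build_constraints(comps, grid, g)
  fit <- optimize_layout(g, grid, cons, cost_params(), seed = 9)
  expect_true(fit$converged)
  expect_equal(nrow(validate_layout(g, fit$layout, cons)), 0)
  expect_true(all(diff(c(total_cost(g, fit$layout, cost_params())$total)) <= 0))
  expect_true(all(diff(fit$trace$total) < 0))
  # the final breakdown matches an independent recomputation
  expect_equal(fit$cost$total,
               unname(oracle_total(layout_positions(g, fit$layout),
                                   edge_index(g), cost_params())))
})
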