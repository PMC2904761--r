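test_that("segment crossing follows the open-interior convention", {
  expect_equal(segments_cross(c(0, 0, 2, 2), c(0, 2, 2, 0)), 1L) # proper X
  expect_equal(segments_cross(c(0, 0, 2, 2), c(2, 2, 4, 0)), 0L) # touch at end
  expect_equal(segments_cross(c(0, 0, 4, 4), c(2, 2, 6, 6)), 1L) # collinear overlap
  expect_equal(segments_cross(c(0, 0, 2, 2), c(2, 2, 4, 4)), 0L) # collinear touch
  expect_equal(segments_cross(c(0, 0, 4, 0), c(2, 0, 2, 2)), 0L) # T-junction
  # symmetry
  expect_equal(segments_cross(c(0, 2, 2, 0), c(0, 0, 2, 2)), 1L)
})

test_that("node-on-edge is strict-interior", {
  expect_equal(node_on_edge(c(1, 1), c(0, 0, 2, 2)), 1L)
  expect_equal(node_on_edge(c(0, 0), c(0, 0, 2, 2)), 0L) # endpoint excluded
  expect_equal(node_on_edge(c(1, 2), c(0, 0, 2, 2)), 0L) # off the line
})

test_that("count_all_crossings matches worked examples", {
  # K4 drawn convex: only the two diagonals cross
  g <- toy_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"),
                       c("a", "c"), c("b", "d")))
  grid <- layout_grid(3, 3)
  lay <- place(g, grid, c(0, 0), c(0, 2), c(2, 2), c(2, 0))
  expect_equal(count_all_crossings(g, lay), c(ee = 1L, ne = 0L))

  # collinear path: the middle node is an endpoint of both segments
  p <- toy_graph(rbind(c("a", "b"), c("b", "c")))
  lp <- place(p, grid, c(0, 0), c(1, 1), c(2, 2))
  expect_equal(count_all_crossings(p, lp), c(ee = 0L, ne = 0L))
})

test_that("crossing counts agree with the pairwise-enumeration oracle", {
  for (s in 1:60) {
    inst <- random_instance(n = sample(6:15, 1), m = sample(6:18, 1),
                            h = sample(5:10, 1), w = sample(5:10, 1),
                            seed = s)
    expect_equal(count_all_crossings(inst$graph, inst$layout),
                 oracle_count(inst$pos, inst$ei), info = paste("seed", s))
  }
})

test_that("counts are invariant under translation of the whole layout", {
  inst <- random_instance(8, 10, 6, 6, seed = 99)
  base <- count_all_crossings(inst$graph, inst$layout)
  grid2 <- layout_grid(9, 9)
  shifted <- grid_layout(unclass(inst$layout) + 3, grid2)
  expect_equal(count_all_crossings(inst$graph, shifted), base)
})

test_that("bulk candidate counts: trivial cases", {
  grid <- layout_grid(4, 4)
  # edgeless graph: moving any node changes nothing
  g0 <- pathway_graph(data.frame(id = c("a", "b"), localization = "cytoplasm"),
                      matrix(character(), ncol = 2))
  l0 <- place(g0, grid, c(0, 0), c(3, 3))
  b0 <- bulk_candidate_counts("a", g0, l0, grid)
  expect_true(all(b0$dee == 0) && all(b0$dne == 0))
  expect_false(b0$usable[pathgrid:::point_index(c(3, 3), grid)])

  # moving a node onto the midpoint of an existing edge: ne delta +1 there
  g1 <- toy_graph(rbind(c("a", "b")))
  g1 <- pathway_graph(rbind(g1$nodes,
                            data.frame(id = "z", label = "z",
                                       localization = "cytoplasm")),
                      g1$edges)
  l1 <- place(g1, grid, c(0, 0), c(2, 2), c(0, 3))
  b1 <- bulk_candidate_counts("z", g1, l1, grid)
  mid <- pathgrid:::point_index(c(1, 1), grid)
  expect_equal(b1$dne[mid], 1L)
  # delta at the node's own point is zero
  expect_equal(b1$dne[pathgrid:::point_index(c(0, 3), grid)], 0L)
  expect_equal(b1$dee[pathgrid:::point_index(c(0, 3), grid)], 0L)
})

test_that("bulk candidate counts equal a full recount at every grid point", {
  for (s in 1:20) {
    inst <- random_instance(n = sample(5:12, 1), m = sample(5:14, 1),
                            h = 8, w = 8, seed = 200 + s)
    vi <- sample(nrow(inst$pos), 1)
    got <- bulk_candidate_counts(inst$graph$nodes$id[vi], inst$graph,
                                 inst$layout, inst$grid)
    want <- oracle_bulk(vi, inst$pos, inst$ei, inst$grid)
    expect_equal(as.integer(got$dee), want$dee, info = paste("seed", s))
    expect_equal(as.integer(got$dne), want$dne, info = paste("seed", s))
  }
})
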