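test_that("pathway_graph enforces its invariants", {
  nodes <- data.frame(id = c("a", "b", "c"), localization = "cytoplasm")
  g <- pathway_graph(nodes, rbind(c("a", "b"), c("b", "c")))
  expect_s3_class(g, "pathway_graph")
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)

  expect_error(pathway_graph(rbind(nodes, nodes[1, ]), rbind(c("a", "b"))),
               "duplicate node ids")
  expect_error(pathway_graph(nodes, rbind(c("a", "z"))), "not in node set")
  expect_error(pathway_graph(nodes, rbind(c("a", "a"))), "self-loops")
  expect_error(pathway_graph(nodes, rbind(c("a", "b"), c("b", "a"))),
               "duplicate edges")
})

test_that("grid points and linear indices are mutually inverse", {
  grid <- layout_grid(5, 7)
  idx <- seq_len(35)
  pts <- pathgrid:::index_point(idx, grid)
  expect_equal(pathgrid:::point_index(pts, grid), idx)
  expect_true(all(pts[, 1] >= 0 & pts[, 1] < 5))
  expect_true(all(pts[, 2] >= 0 & pts[, 2] < 7))
})

test_that("region_points matches the stated shapes", {
  grid <- layout_grid(3, 3)
  comp <- compartment("cytoplasm", "rectangle", center = c(1, 1),
                      size = c(2, 2))
  expect_setequal(region_points(list(comp), "cytoplasm", grid), 1:9)

  # annulus: full 5x5 outer minus centered 3x3 inner leaves the 16 border pts
  grid5 <- layout_grid(5, 5)
  ring <- compartment("membrane", "annulus", center = c(2, 2),
                      size = c(4, 4), inner_size = c(2, 2))
  pts <- region_points(list(ring), "membrane", grid5)
  expect_length(pts, 16)
  co <- pathgrid:::index_point(pts, grid5)
  expect_true(all(co[, 1] %in% c(0, 4) | co[, 2] %in% c(0, 4)))

  expect_error(region_points(list(comp), "nucleus", grid), "no compartment")
})

test_that("region membership agrees with a point-by-point oracle", {
  in_shape <- function(r, c, shape, ctr, size)
    if (shape == "rectangle")
      abs(r - ctr[1]) <= size[1] / 2 + 1e-9 & abs(c - ctr[2]) <= size[2] / 2 + 1e-9
    else
      (r - ctr[1])^2 / (size[1] / 2)^2 + (c - ctr[2])^2 / (size[2] / 2)^2 <= 1 + 1e-9
  set.seed(42)
  for (trial in 1:100) {
    grid <- layout_grid(sample(4:9, 1), sample(4:9, 1))
    shape <- sample(c("rectangle", "oval", "annulus"), 1)
    ctr <- c(runif(1, 0, grid$h - 1), runif(1, 0, grid$w - 1))
    size <- c(runif(1, 1, grid$h), runif(1, 1, grid$w))
    base <- sample(c("rectangle", "oval"), 1)
    comp <- compartment("x", shape, center = ctr, size = size,
                        inner_size = if (shape == "annulus") size * 0.5,
                        base = base)
    pts <- tryCatch(region_points(list(comp), "x", grid),
                    error = function(e) integer())
    co <- pathgrid:::grid_coords(grid)
    expected <- if (shape == "annulus")
      in_shape(co[, 1], co[, 2], base, ctr, size) &
        !in_shape(co[, 1], co[, 2], base, ctr, size * 0.5)
    else in_shape(co[, 1], co[, 2], shape, ctr, size)
    expect_equal(pts, which(expected), info = paste("trial", trial))
  }
})

test_that("region_points is deterministic and disjoint tags stay disjoint", {
  grid <- layout_grid(10, 10)
  a <- compartment("a", "rectangle", center = c(2, 2), size = c(3, 3))
  b <- compartment("b", "oval", center = c(7, 7), size = c(4, 4))
  pa <- region_points(list(a, b), "a", grid)
  expect_identical(pa, region_points(list(a, b), "a", grid))
  expect_length(intersect(pa, region_points(list(a, b), "b", grid)), 0)
})

test_that("validate_layout reports collisions and constraint breaches", {
  grid <- layout_grid(6, 6)
  comps <- list(
    compartment("nucleus", "rectangle", center = c(1, 1), size = c(2, 2)),
    compartment("plasma_membrane", "annulus", center = c(2.5, 2.5),
                size = c(5, 5)))
  g <- toy_graph(rbind(c("a", "b")),
                 tags = c(a = "nucleus", b = "plasma_membrane"))
  cons <- build_constraints(comps, grid, g)

  # (1,1) is inside the nucleus region but excluded from the membrane ring,
  # so the collision also breaches b's constraint
  collide <- place(g, grid, c(1, 1), c(1, 1))
  v <- validate_layout(g, collide, cons)
  expect_equal(sort(unique(v$type)), c("collision", "constraint"))
  expect_equal(sum(v$type == "collision"), 2)

  # membrane node placed inside the nucleus region
  bad <- place(g, grid, c(0, 0), c(1, 1))
  v2 <- validate_layout(g, bad, cons)
  expect_equal(v2$type, "constraint")
  expect_equal(v2$node, "b")

  ok <- place(g, grid, c(0, 0), c(0, 5))
  expect_equal(nrow(validate_layout(g, ok, cons)), 0)
})
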