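test_that("spread statistics match direct computation", {
  s1 <- spread_statistics(rbind(c(3, 4)))
  expect_equal(s1$b, c(3, 4))
  expect_equal(c(s1$s_v, s1$s_h), c(0, 0))

  s2 <- spread_statistics(rbind(c(0, 0), c(4, 0)))
  expect_equal(s2$b, c(2, 0))
  expect_equal(s2$s_v, 4)
  expect_equal(s2$s_h, 0)

  set.seed(10)
  for (k in 1:20) {
    pts <- cbind(sample(0:20, 8, TRUE), sample(0:20, 8, TRUE))
    s <- spread_statistics(pts)
    b <- colMeans(pts)
    expect_equal(s$b, unname(b))
    expect_equal(s$s_v, 2 * max(abs(pts[, 1] - b[1])))
    expect_equal(s$s_h, 2 * max(abs(pts[, 2] - b[2])))
    sm <- spread_statistics(pts, method = "mean")
    expect_equal(sm$s_v, 2 * mean(abs(pts[, 1] - b[1])))
  }
})

test_that("resize decisions follow the 0.4 / 0.9 thresholds and size caps", {
  comp <- compartment("nucleus", "oval", center = c(5, 10), size = c(10, 20),
                      movable = TRUE)
  expect_equal(resize_decision(comp, s_v = 3, s_h = 7), "shrink")  # 3<4, 7<8
  expect_equal(resize_decision(comp, s_v = 9.5, s_h = 0), "enlarge") # 9.5>9
  expect_equal(resize_decision(comp, s_v = 5, s_h = 10), "keep")

  at_min <- comp
  at_min$size <- 0.6 * at_min$original_size
  expect_equal(resize_decision(at_min, s_v = 1, s_h = 1), "keep")
  at_max <- comp
  at_max$size <- 1.5 * at_max$original_size
  expect_equal(resize_decision(at_max, s_v = 14.9, s_h = 1), "keep")
})

make_scene <- function(grid) {
  list(compartment("cytoplasm", "rectangle",
                   center = c((grid$h - 1) / 2, (grid$w - 1) / 2),
                   size = c(grid$h - 1, grid$w - 1),
                   exclude = c("nucleus", "mitochondria")),
       compartment("nucleus", "oval", center = c(3, 3), size = c(3, 3),
                   movable = TRUE, within = "cytoplasm"),
       compartment("mitochondria", "oval", center = c(8, 8), size = c(3, 3),
                   movable = TRUE, within = "cytoplasm"))
}

test_that("repositioning matches an exhaustive candidate search", {
  grid <- layout_grid(12, 12)
  comps <- make_scene(grid)
  g <- toy_graph(rbind(c("a", "b")), tags = c(a = "nucleus", b = "nucleus"))
  lay <- place(g, grid, c(3, 3), c(3, 4))

  for (s in 1:12) {
    set.seed(500 + s)
    b_c <- c(runif(1, 1, 10), runif(1, 1, 10))
    got <- reposition_compartment(comps[[2]], b_c, comps, g, lay, grid)
    # exhaustive oracle: scan every grid point, keep valid ones, take the
    # minimum Manhattan distance with (row, col) tie-break
    bd <- floor(b_c + 0.5)
    co <- pathgrid:::grid_coords(grid)
    md <- abs(co[, 1] - bd[1]) + abs(co[, 2] - bd[2])
    valid <- rep(FALSE, nrow(co))
    idx <- point_index(layout_positions(g, lay), grid)
    for (q in which(md <= 10)) {
      trial <- comps
      trial[[2]]$center <- as.numeric(co[q, ])
      regions_ok <- tryCatch({
        pts <- region_points(trial, "nucleus", grid)
        all(idx %in% pts)
      }, error = function(e) FALSE)
      # nucleus must stay inside the cytoplasm and off the mitochondria
      br <- function(cc) c(cc$center - cc$size / 2, cc$center + cc$size / 2)
      a <- br(trial[[2]]); b <- br(trial[[3]]); outer_ <- br(trial[[1]])
      overlap <- a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
      contained <- all(a[1:2] >= outer_[1:2] - 1e-9) &&
        all(a[3:4] <= outer_[3:4] + 1e-9)
      valid[q] <- regions_ok && !overlap && contained
    }
    if (!any(valid)) {
      expect_null(got, info = paste("seed", s))
    } else {
      cand <- which(valid)
      cand <- cand[order(md[cand], co[cand, 1], co[cand, 2])]
      expect_equal(got, as.numeric(co[cand[1], ]), info = paste("seed", s))
    }
  }
})

test_that("reposition keeps the current center when it is already best", {
  grid <- layout_grid(12, 12)
  comps <- make_scene(grid)
  g <- toy_graph(rbind(c("a", "b")), tags = c(a = "nucleus", b = "nucleus"))
  lay <- place(g, grid, c(3, 3), c(3, 4))
  # center of gravity exactly on a grid point that is valid: distance 0 wins
  got <- reposition_compartment(comps[[2]], c(3, 3), comps, g, lay, grid)
  expect_equal(got, c(3, 3))
})

test_that("dynamic-compartment runs keep every invariant", {
  g <- generate_pathway(40, 46, seed = 21)
  grid <- grid_dims(40)
  comps <- default_compartments(grid)
  for (s in 1:3) {
    fit <- gdc_layout(g, grid, comps, cost_params(), seed = 600 + s)
    # final sizes within [0.6, 1.5] x original
    for (comp in fit$compartments) {
      r <- comp$size / comp$original_size
      expect_true(all(r >= 0.6 - 1e-9 & r <= 1.5 + 1e-9))
    }
    # the final layout is admissible under the FINAL geometry
    cons <- build_constraints(fit$compartments, grid, g)
    expect_equal(nrow(validate_layout(g, fit$layout, cons)), 0)
    # movable bounding rectangles never overlapped in any round
    tr <- fit$compartment_trace
    for (rd in unique(tr$round)) {
      rows <- tr[tr$round == rd, ]
      if (nrow(rows) == 2) {
        a <- c(rows$center_row[1] - rows$height[1] / 2,
               rows$center_col[1] - rows$width[1] / 2,
               rows$center_row[1] + rows$height[1] / 2,
               rows$center_col[1] + rows$width[1] / 2)
        b <- c(rows$center_row[2] - rows$height[2] / 2,
               rows$center_col[2] - rows$width[2] / 2,
               rows$center_row[2] + rows$height[2] / 2,
               rows$center_col[2] + rows$width[2] / 2)
        expect_false(a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
      }
    }
  }
})

test_that("with all compartments frozen, GDC reproduces the plain optimizer", {
  g <- generate_pathway(30, 35, seed = 31)
  grid <- grid_dims(30)
  comps <- lapply(default_compartments(grid), function(c_) {
    c_$movable <- FALSE
    c_
  })
  cons <- build_constraints(comps, grid, g)
  lay <- random_layout(g, grid, cons, seed = 32)
  f1 <- gdc_layout(g, grid, comps, cost_params(), layout = lay)
  f2 <- optimize_layout(g, grid, cons, cost_params(), layout = lay,
                        max_steps = 10000)
  expect_identical(unclass(f1$layout), unclass(f2$layout))
  expect_equal(f1$cost$total, f2$cost$total)
})
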