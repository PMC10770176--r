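test_that("grid specification enforces divisibility and counts nodes", {
  g <- grid_spec()
  expect_equal(c(g$N_i, g$N_j), c(101L, 51L))
  expect_error(grid_spec(h = -1), "positive")
  expect_error(grid_spec(0, 201, 0, 100, h = 2), "integer multiples")
})

test_that("a square cell loads with the right area and interior mask", {
  f <- withr::local_tempfile(fileext = ".txt")
  # 10 um square, corners on the 2 um grid offset so nodes fall inside
  writeLines(c("cell_id x y", "7 21 21", "7 31 21", "7 31 31", "7 21 31"), f)
  dom <- suppressMessages(load_tissue(f, grid_spec(), epsilon = 2))
  expect_length(dom$cells, 1)
  expect_equal(dom$cells[[1]]$area, 100, tolerance = 1e-9)
  # interior nodes: x, y in {22, 24, ..., 30} um -> 5 x 5 = 25 nodes
  expect_equal(sum(dom$interior), 25L)
  xs <- which(apply(dom$interior, 1, any))
  expect_equal(range((xs - 1) * 2), c(22, 30))
})

test_that("malformed geometry files are rejected with the offending cell", {
  g <- grid_spec()
  open_f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 21 21", "3 31 21", "3 31 31"), open_f) # gap 10 um > h
  expect_error(suppressMessages(load_tissue(open_f, g)), "open contour.*3")

  dup_f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 21 21", "1 31 21", "1 31 31", "1 21 31",
               "2 41 41", "2 51 41", "2 51 51", "2 41 51",
               "1 61 61", "1 71 61", "1 71 71", "1 61 71"), dup_f)
  expect_error(suppressMessages(load_tissue(dup_f, g)), "duplicate cell_id: 1")

  out_f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("9 190 50", "9 210 50", "9 210 60", "9 190 60"), out_f)
  expect_error(suppressMessages(load_tissue(out_f, g)), "out-of-domain.*9")
})

test_that("geometry files round-trip through write_tissue/load_tissue", {
  fx <- small_tissue()
  f <- withr::local_tempfile(fileext = ".txt")
  write_tissue(fx$dom, f)
  dom2 <- suppressMessages(load_tissue(f, fx$dom$grid, fx$dom$epsilon))
  expect_equal(length(dom2$cells), length(fx$dom$cells))
  expect_equal(cell_areas(dom2), cell_areas(fx$dom), tolerance = 1e-6)
  expect_equal(dom2$interior, fx$dom$interior)
})

test_that("synthetic generator is deterministic and respects its contracts", {
  g <- grid_spec(0, 100, 0, 50, h = 2)
  d0 <- generate_synthetic_tissue(g, n_cells = 0, seed = 1)
  expect_length(d0$cells, 0)
  expect_false(any(d0$interior))

  a <- suppressMessages(generate_synthetic_tissue(g, 25, 4, seed = 42))
  b <- suppressMessages(generate_synthetic_tissue(g, 25, 4, seed = 42))
  expect_identical(lapply(a$cells, `[[`, "xy"), lapply(b$cells, `[[`, "xy"))

  expect_error(generate_synthetic_tissue(g, 5, mean_radius = 1, seed = 1),
               "twice the grid spacing")
  expect_error(suppressMessages(
    generate_synthetic_tissue(g, 5000, 4, seed = 1)), "packing failure")

  # cell-free strip of >= 2 epsilon along the vessel edge
  min_x <- min(vapply(a$cells, function(c) min(c$xy[, 1]), numeric(1)))
  expect_gte(min_x, g$x_min + 2 * a$epsilon)
})

test_that("packed contours do not overlap and masks match polygon areas", {
  dom <- suppressMessages(generate_synthetic_tissue(
    grid_spec(), n_cells = 300, mean_radius = 4, seed = 7))
  expect_length(dom$cells, 300)
  # non-overlap: no boundary point of one cell inside another (bbox-filtered)
  bb <- t(vapply(dom$cells, function(c)
    c(range(c$xy[, 1]), range(c$xy[, 2])), numeric(4)))
  overlaps <- 0L
  for (l in seq_along(dom$cells)) {
    near <- which(bb[, 1] <= bb[l, 2] & bb[, 2] >= bb[l, 1] &
                  bb[, 3] <= bb[l, 4] & bb[, 4] >= bb[l, 3])
    for (m in setdiff(near, l)) {
      if (any(pracma::inpolygon(dom$cells[[m]]$xy[, 1], dom$cells[[m]]$xy[, 2],
                                dom$cells[[l]]$xy[, 1], dom$cells[[l]]$xy[, 2])))
        overlaps <- overlaps + 1L
    }
  }
  expect_equal(overlaps, 0L)
  # node-count area vs shoelace area
  node_area <- sum(dom$interior) * dom$grid$h^2
  poly_area <- sum(cell_areas(dom))
  expect_lt(abs(node_area - poly_area) / poly_area, 0.05)
  # every node is interior xor interstitial by construction; receptor reach
  expect_true(all(dom$interior + !dom$interior == 1))
})

test_that("receptor map matches a brute-force distance scan and is strict", {
  fx <- small_tissue()
  dom <- fx$dom
  g <- dom$grid
  xs <- g$x_min + (seq_len(g$N_i) - 1) * g$h
  ys <- g$y_min + (seq_len(g$N_j) - 1) * g$h
  open <- !dom$interior
  rm_pkg <- build_receptor_map(dom)
  for (l in sample(seq_along(dom$cells), 5)) {
    xy <- dom$cells[[l]]$xy
    for (p in seq_len(nrow(xy))) {
      d2 <- outer((xs - xy[p, 1])^2, (ys - xy[p, 2])^2, "+")
      brute <- which(d2 < dom$epsilon^2 & open)
      expect_identical(sort(rm_pkg[[l]][[p]]), sort(as.integer(brute)))
      # strictness: all mapped nodes closer than epsilon
      if (length(brute))
        expect_true(all(d2[brute] < dom$epsilon^2))
    }
  }
})

test_that("a receptor exactly on a grid node keeps only that node at r < eps", {
  # single square cell whose boundary midpoints land on grid nodes
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 20 20", "1 28 20", "1 28 28", "1 20 28"), f)
  dom <- suppressMessages(load_tissue(f, grid_spec(), epsilon = 2))
  on_node <- which(vapply(seq_along(dom$cells[[1]]$xy[, 1]), function(p) {
    xy <- dom$cells[[1]]$xy[p, ]
    all(abs(xy / 2 - round(xy / 2)) < 1e-9)
  }, logical(1)))
  expect_gt(length(on_node), 0)
  for (p in on_node) {
    xy <- dom$cells[[1]]$xy[p, ]
    hits <- dom$receptor_map[[1]][[p]]
    xs <- (hits - 1) %% dom$grid$N_i * 2
    ys <- (hits - 1) %/% dom$grid$N_i * 2
    d <- sqrt((xs - xy[1])^2 + (ys - xy[2])^2)
    expect_true(all(d < 2)) # distance-2 neighbors excluded by strict "<"
  }
})
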