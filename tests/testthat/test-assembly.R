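toy_edges <- function(weights22) {
  # 2x2 grid cycle: H(0,0) H(1,0) V(0,0) V(0,1)
  tibble::tibble(
    direction = c("H", "H", "V", "V"),
    row = c(0L, 1L, 0L, 0L), col = c(0L, 0L, 0L, 1L),
    row2 = c(0L, 1L, 1L, 1L), col2 = c(1L, 1L, 0L, 1L),
    dx = c(90L, 90L, 0L, 0L), dy = c(0L, 0L, 90L, 90L),
    ncc = weights22, repaired = FALSE, weight = weights22
  )
}

test_that("plausible edges outrank implausible ones after boosting", {
  g <- list(tile_w = 100, tile_h = 100, rows = 2, cols = 2)
  m <- stage_model(10, 10, r = 2)
  tbl <- toy_edges(c(0.3, 0.9, 0.8, 0.7))[, -9] # drop weight
  tbl$dx <- c(90L, 40L, 0L, 1L) # second H edge implausible (nominal 90)
  out <- build_tile_graph(tbl, m, g)
  expect_gt(out$weight[1], out$weight[2]) # 1.3 > 0.9
  expect_equal(out$weight[1], 1.3)
  expect_equal(out$weight[2], 0.9)
  tbl$ncc[3] <- NA
  out2 <- build_tile_graph(tbl, m, g)
  expect_lt(out2$weight[3], -1e8)
})

test_that("maximum spanning tree drops the lightest cycle edge", {
  grid <- list(rows = 2, cols = 2)
  tree <- maximum_spanning_tree(toy_edges(c(0.9, 0.6, 0.8, 0.7)), grid)
  expect_equal(nrow(tree), 3)
  expect_false(any(tree$weight == 0.6))
  # equal weights: deterministic tie-break, weight total preserved
  t2 <- maximum_spanning_tree(toy_edges(rep(0.5, 4)), grid)
  expect_equal(sum(t2$weight), 1.5)
  t3 <- maximum_spanning_tree(toy_edges(rep(0.5, 4)), grid)
  expect_identical(t2, t3)
})

test_that("MST total weight matches brute force and igraph on random 3x3 grids", {
  grid <- list(rows = 3, cols = 3)
  vid <- function(row, col) row * 3 + col + 1
  pairs <- neighbor_pairs(grid)
  for (s in 1:50) {
    set.seed(s)
    edges <- pairs |>
      dplyr::mutate(dx = 0L, dy = 0L, ncc = runif(dplyr::n()),
                    repaired = FALSE, weight = .data$ncc)
    tree <- maximum_spanning_tree(edges, grid)
    expect_equal(nrow(tree), 8)
    bf <- max_tree_weight_bruteforce(edges, 9, vid)
    expect_equal(sum(tree$weight), bf, tolerance = 1e-12,
                 label = paste("seed", s))
    # independent library cross-check
    ig <- igraph::graph_from_edgelist(
      cbind(vid(edges$row, edges$col), vid(edges$row2, edges$col2)),
      directed = FALSE)
    igraph::E(ig)$weight <- -edges$weight
    igt <- igraph::mst(ig)
    expect_equal(sum(tree$weight), -sum(igraph::E(igt)$weight),
                 tolerance = 1e-12)
  }
})

test_that("tree is spanning and acyclic for random grids up to 6x6", {
  for (s in 1:10) {
    set.seed(100 + s)
    rows <- sample(1:6, 1); cols <- sample(1:6, 1)
    if (rows * cols == 1) next
    grid <- list(rows = rows, cols = cols)
    edges <- neighbor_pairs(grid) |>
      dplyr::mutate(dx = 1L, dy = 0L, ncc = runif(dplyr::n()),
                    repaired = FALSE, weight = .data$ncc)
    tree <- maximum_spanning_tree(edges, grid)
    expect_equal(nrow(tree), rows * cols - 1)
    ig <- igraph::graph_from_edgelist(
      cbind(tree$row * cols + tree$col + 1,
            tree$row2 * cols + tree$col2 + 1), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, rows * cols - igraph::vcount(ig)))
    expect_true(igraph::is_connected(ig))
    expect_equal(igraph::ecount(ig), igraph::vcount(ig) - 1) # acyclic
  }
})

test_that("compose_positions sums displacements along the tree", {
  g12 <- tile_grid(replicate(2, matrix(runif(1040 * 1040), 1040), simplify = FALSE),
                   1, 2)
  tree <- tibble::tibble(direction = "H", row = 0L, col = 0L, row2 = 0L,
                         col2 = 1L, dx = 936L, dy = 0L, ncc = 0.9,
                         repaired = FALSE, weight = 0.9)
  lay <- compose_positions(tree, g12)
  expect_equal(lay$x, c(0L, 936L))
  expect_equal(lay$y, c(0L, 0L))
  expect_equal(attr(lay, "mosaic_width"), 1976)
  expect_equal(attr(lay, "mosaic_height"), 1040)
})

test_that("layout is invariant to traversal direction after normalization", {
  # a chain tree laid right-to-left must give the same normalized positions
  g13 <- tile_grid(replicate(3, matrix(runif(100 * 100), 100), simplify = FALSE),
                   1, 3)
  tree <- tibble::tibble(direction = "H", row = 0L, col = 0:1, row2 = 0L,
                         col2 = 1:2, dx = 90L, dy = 0L, ncc = 0.9,
                         repaired = FALSE, weight = 0.9)
  lay1 <- compose_positions(tree, g13)
  lay2 <- compose_positions(tree[2:1, ], g13)
  expect_equal(as.data.frame(lay1)[, c("row", "col", "x", "y")],
               as.data.frame(lay2)[, c("row", "col", "x", "y")],
               ignore_attr = TRUE)
})

test_that("noiseless stitched positions equal generator ground truth", {
  acq <- cached("noiseless_3x3", {
    src <- generate_source(31, 420, 420, "texture")
    simulate_acquisition(src, 3, 3, 96, 96, overlap_pct = 10, seed = 31)
  })
  res <- stitch_grid(acq$grid)
  expect_equal(max(layout_errors(res$layout, acq$truth_layout)), 0)

  # overlay mosaic reproduces the source exactly on covered pixels
  mos <- render_mosaic(res$layout, acq$grid, "overlay")
  for (i in seq_len(nrow(res$layout))) {
    p <- res$layout[i, ]
    patch <- mos[(p$y + 1):(p$y + 96), (p$x + 1):(p$x + 96)]
    tp <- acq$truth_layout[acq$truth_layout$row == p$row &
                             acq$truth_layout$col == p$col, ]
    src_patch <- acq$source[(tp$y + 1):(tp$y + 96), (tp$x + 1):(tp$x + 96)]
    expect_lt(max(abs(patch - src_patch)), 1e-9)
  }
  expect_equal(blank_pixel_count(mos, res$layout, acq$grid), 0)
})

test_that("blend modes agree where tiles agree", {
  acq <- cached("noiseless_3x3", {
    src <- generate_source(31, 420, 420, "texture")
    simulate_acquisition(src, 3, 3, 96, 96, overlap_pct = 10, seed = 31)
  })
  res <- stitch_grid(acq$grid)
  mo <- render_mosaic(res$layout, acq$grid, "overlay")
  ma <- render_mosaic(res$layout, acq$grid, "average")
  ml <- render_mosaic(res$layout, acq$grid, "linear")
  # noiseless tiles agree in overlaps, so all modes give the same mosaic
  expect_lt(max(abs(mo - ma)), 1e-9)
  expect_lt(max(abs(mo - ml)), 1e-9)

  # single tile: mosaic equals the tile under every mode
  g1 <- tile_grid(list(matrix(runif(64 * 64), 64)), 1, 1)
  lay1 <- tibble::tibble(row = 0L, col = 0L, x = 0L, y = 0L, edge_ncc = NA_real_)
  attr(lay1, "mosaic_width") <- 64; attr(lay1, "mosaic_height") <- 64
  for (mode in c("overlay", "average", "linear")) {
    expect_equal(render_mosaic(lay1, g1, mode), grid_tile(g1, 0, 0),
                 ignore_attr = TRUE, label = mode)
  }
})

test_that("linear blend weights are positive and flip-symmetric", {
  for (dims in list(c(8, 8), c(7, 9), c(16, 5))) {
    w <- linear_blend_weights(dims[1], dims[2])
    expect_true(all(w > 0))
    expect_equal(w, w[, ncol(w):1])
    expect_equal(w, w[nrow(w):1, ])
  }
})

test_that("apply_layout re-renders other channels at fixed positions", {
  acq <- cached("noiseless_3x3", {
    src <- generate_source(31, 420, 420, "texture")
    simulate_acquisition(src, 3, 3, 96, 96, overlap_pct = 10, seed = 31)
  })
  res <- stitch_grid(acq$grid)
  m1 <- render_mosaic(res$layout, acq$grid, "overlay")
  expect_equal(apply_layout(res$layout, acq$grid), m1)

  # inverted-intensity channel: pointwise op commutes with placement
  inv_tiles <- lapply(acq$grid$tiles, function(t) 255 - t)
  inv <- tile_grid(inv_tiles, 3, 3)
  expect_equal(apply_layout(res$layout, inv), 255 - m1)

  bad <- tile_grid(replicate(6, matrix(0, 96, 96), simplify = FALSE), 2, 3)
  expect_error(apply_layout(res$layout, bad), "shape")
})
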