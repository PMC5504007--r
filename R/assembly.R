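#' Build the weighted tile-adjacency graph
#'
#' One vertex per tile, one edge per adjacent pair weighted by its ncc.
#' Edges whose displacement lies within `4r` of the stage model's nominal
#' displacement (per axis) are "physically plausible" and get their weight
#' boosted by +1 -- since ncc is at most 1 this lifts every plausible edge
#' above every implausible one. Invalid-ncc edges carry a sentinel-low
#' weight so they are chosen only when needed for connectivity.
#'
#' @param translations Optimized table (see [optimize_translations()]).
#' @param model A [stage_model()].
#' @param grid A [tile_grid()].
#' @return The translation table with a `weight` column (an edge list; use
#'   [maximum_spanning_tree()] to extract the tree).
#' @export
build_tile_graph <- function(translations, model, grid) {
  nom <- nominal_displacement(model, translations$direction,
                              grid$tile_w, grid$tile_h)
  r4 <- 4 * model$r
  plaus <- !is.na(translations$ncc) &
    abs(translations$dx - nom$dx) <= r4 &
    abs(translations$dy - nom$dy) <= r4
  translations |>
    dplyr::mutate(
      plausible = plaus,
      weight = dplyr::case_when(
        is.na(.data$ncc) ~ -1e9,
        plaus ~ .data$ncc + 1,
        TRUE ~ .data$ncc
      )
    )
}

#' Maximum spanning tree of the tile graph
#'
#' Kruskal's algorithm on the edge list: edges are taken in decreasing
#' weight (ties broken by direction H before V, then row, then column, so
#' the tree is deterministic) and added unless they close a cycle. The grid
#' graph is connected, so the result has exactly `rows*cols - 1` edges.
#'
#' @param graph Edge-list tibble from [build_tile_graph()] (needs `weight`).
#' @param grid A [tile_grid()] or list with `rows`, `cols`.
#' @return The subset of edge rows forming the maximum spanning tree.
#' @export
maximum_spanning_tree <- function(graph, grid) {
  n <- grid$rows * grid$cols
  vid <- function(row, col) row * grid$cols + col + 1L
  ord <- order(-graph$weight, graph$direction, graph$row, graph$col)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(graph))
  taken <- 0L
  for (e in ord) {
    u <- find(vid(graph$row[e], graph$col[e]))
    v <- find(vid(graph$row2[e], graph$col2[e]))
    if (u != v) {
      parent[u] <- v
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  if (taken != n - 1L) stop("maximum_spanning_tree: graph is disconnected")
  graph[keep, ]
}

#' Compose absolute tile positions from a spanning tree
#'
#' Starting from tile (0,0) at position (0,0), positions propagate along
#' tree edges: crossing an edge forward (west tile to east, or north to
#' south) adds its `(dx, dy)`; crossing backward subtracts it. Positions are
#' then translated so the minimum x and minimum y are both 0.
#'
#' @param tree Edge rows from [maximum_spanning_tree()].
#' @param grid A [tile_grid()].
#' @return A `mosaic_layout` tibble with columns `row`, `col`, `x`, `y`,
#'   `edge_ncc` (ncc of the edge that placed the tile; `NA` for the root)
#'   and attributes `tree_edges`, `mosaic_width`, `mosaic_height`.
#' @export
compose_positions <- function(tree, grid) {
  rows <- grid$rows; cols <- grid$cols
  n <- rows * cols
  vid <- function(row, col) row * cols + col + 1L
  adj <- vector("list", n)
  for (e in seq_len(nrow(tree))) {
    u <- vid(tree$row[e], tree$col[e])
    v <- vid(tree$row2[e], tree$col2[e])
    adj[[u]] <- c(adj[[u]], list(list(to = v, dx = tree$dx[e], dy = tree$dy[e],
                                      ncc = tree$ncc[e])))
    adj[[v]] <- c(adj[[v]], list(list(to = u, dx = -tree$dx[e], dy = -tree$dy[e],
                                      ncc = tree$ncc[e])))
  }
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); encc <- rep(NA_real_, n)
  x[1] <- 0; y[1] <- 0
  queue <- 1L
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (ed in adj[[u]]) {
      v <- ed$to
      if (is.na(x[v])) {
        x[v] <- x[u] + ed$dx
        y[v] <- y[u] + ed$dy
        encc[v] <- ed$ncc
        queue <- c(queue, v)
      }
    }
  }
  if (anyNA(x)) stop("compose_positions: tree does not span all tiles")
  x <- as.integer(x - min(x)); y <- as.integer(y - min(y))
  idx <- seq_len(n) - 1L
  layout <- tibble::tibble(
    row = idx %/% cols, col = idx %% cols, x = x, y = y, edge_ncc = encc
  )
  attr(layout, "tree_edges") <- tree
  attr(layout, "mosaic_width") <- max(x) + grid$tile_w
  attr(layout, "mosaic_height") <- max(y) + grid$tile_h
  class(layout) <- c("mosaic_layout", class(layout))
  layout
}

#' Render the blended mosaic
#'
#' Places every tile at its layout position on a zero-initialized canvas.
#' Blending modes: `"overlay"` writes tiles in row-major order, last tile
#' wins in overlaps; `"average"` takes the per-pixel mean of all contributing
#' tiles; `"linear"` takes a weighted mean with per-tile weight
#' `w(u,v) = (min(u+1, W-u)/ceil(W/2)) * (min(v+1, H-v)/ceil(H/2))`
#' (peaks at the tile center, falls toward 0 at the borders), which feathers
#' seams. Accumulation is in floating point; the result is clipped to the
#' grid's bit depth and rounded.
#'
#' @param layout A [compose_positions()] layout (or any tibble with `row`,
#'   `col`, `x`, `y` and `mosaic_width`/`mosaic_height` attributes).
#' @param grid A [tile_grid()].
#' @param mode One of `"overlay"`, `"average"`, `"linear"`.
#' @return The mosaic as a numeric matrix.
#' @export
render_mosaic <- function(layout, grid, mode = c("overlay", "average", "linear")) {
  mode <- match.arg(mode)
  w <- attr(layout, "mosaic_width") %||% (max(layout$x) + grid$tile_w)
  h <- attr(layout, "mosaic_height") %||% (max(layout$y) + grid$tile_h)
  canvas <- matrix(0, h, w)
  lay <- layout[order(layout$row, layout$col), ]
  if (mode == "overlay") {
    for (i in seq_len(nrow(lay))) {
      t <- grid_tile(grid, lay$row[i], lay$col[i])
      canvas[(lay$y[i] + 1):(lay$y[i] + grid$tile_h),
             (lay$x[i] + 1):(lay$x[i] + grid$tile_w)] <- t
    }
  } else {
    wt <- if (mode == "linear") linear_blend_weights(grid$tile_w, grid$tile_h)
          else matrix(1, grid$tile_h, grid$tile_w)
    acc <- matrix(0, h, w)
    for (i in seq_len(nrow(lay))) {
      ry <- (lay$y[i] + 1):(lay$y[i] + grid$tile_h)
      rx <- (lay$x[i] + 1):(lay$x[i] + grid$tile_w)
      t <- grid_tile(grid, lay$row[i], lay$col[i])
      canvas[ry, rx] <- canvas[ry, rx] + t * wt
      acc[ry, rx] <- acc[ry, rx] + wt
    }
    covered <- acc > 0
    canvas[covered] <- canvas[covered] / acc[covered]
  }
  mx <- 2^(grid$bits %||% 16L) - 1
  canvas <- pmin(pmax(canvas, 0), mx)
  canvas
}

#' Center-weighted blending mask for linear blending
#'
#' @param w,h Tile width and height in px.
#' @return An `h x w` weight matrix, positive everywhere, symmetric under
#'   horizontal and vertical flips.
#' @export
linear_blend_weights <- function(w, h) {
  u <- 0:(w - 1); v <- 0:(h - 1)
  wu <- pmin(u + 1, w - u) / ceiling(w / 2)
  wv <- pmin(v + 1, h - v) / ceiling(h / 2)
  outer(wv, wu)
}

#' Render another channel with a precomputed layout
#'
#' Re-uses the positions computed on one channel (or time point) for a grid
#' of the same shape and tile size -- no translation recomputation.
#'
#' @param layout A [compose_positions()] layout.
#' @param other_grid A [tile_grid()] with identical dimensions and tile size.
#' @param mode Blend mode, as in [render_mosaic()].
#' @return The mosaic as a numeric matrix.
#' @export
apply_layout <- function(layout, other_grid, mode = "overlay") {
  need <- c(max(layout$row) + 1L, max(layout$col) + 1L)
  if (other_grid$rows != need[1] || other_grid$cols != need[2]) {
    stop("apply_layout: grid shape (", other_grid$rows, "x", other_grid$cols,
         ") does not match layout (", need[1], "x", need[2], ")")
  }
  render_mosaic(layout, other_grid, mode)
}
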