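#' Construct a tile grid
#'
#' A `tile_grid` holds the R x C acquisition grid of same-sized grayscale
#' tiles. Tiles are stored row-major; grid indices are 0-based with row 0 at
#' the top and column 0 at the left. Pixel coordinates throughout the package
#' are 0-based with x growing rightward and y growing downward.
#'
#' @param tiles List of numeric matrices (one per tile, row-major order:
#'   all of row 0 left to right, then row 1, ...). Each matrix has
#'   `dim = c(tile_h, tile_w)`.
#' @param rows,cols Grid dimensions (positive integers).
#' @param paths Optional character vector of source identifiers, row-major,
#'   same length as `tiles`.
#' @param bits Bit depth of the source data (8 or 16); used when tiles are
#'   written back to disk. Default 16.
#'
#' @return An object of class `tile_grid`.
#' @export
#' @examples
#' tiles <- replicate(4, matrix(runif(64), 8, 8), simplify = FALSE)
#' g <- tile_grid(tiles, rows = 2, cols = 2)
#' g$tile_w
tile_grid <- function(tiles, rows, cols, paths = NULL, bits = 16L) {
  stopifnot(rows >= 1, cols >= 1)
  if (length(tiles) != rows * cols) {
    stop("expected ", rows * cols, " tiles, got ", length(tiles),
         " (grids with missing tiles are not supported)")
  }
  dims <- vapply(tiles, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all tiles must share one size; found differing dimensions")
  }
  if (!is.null(paths) && length(paths) != length(tiles)) {
    stop("`paths` must have one entry per tile")
  }
  structure(
    list(
      tiles = tiles, rows = as.integer(rows), cols = as.integer(cols),
      tile_h = dims[1, 1], tile_w = dims[2, 1],
      paths = paths %||% sprintf("tile_r%d_c%d", rep(seq_len(rows) - 1L, each = cols),
                                 rep(seq_len(cols) - 1L, times = rows)),
      bits = as.integer(bits)
    ),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %d x %d px (%d-bit)\n",
              x$rows, x$cols, x$tile_h, x$tile_w, x$bits))
  invisible(x)
}

#' Fetch one tile's raster by 0-based grid position
#'
#' @param grid A [tile_grid()].
#' @param row,col 0-based grid indices.
#' @return The tile's numeric matrix.
#' @export
grid_tile <- function(grid, row, col) {
  stopifnot(inherits(grid, "tile_grid"),
            row >= 0, row < grid$rows, col >= 0, col < grid$cols)
  grid$tiles[[row * grid$cols + col + 1L]]
}

#' Enumerate adjacent tile pairs
#'
#' Every west-to-east (`"H"`) and north-to-south (`"V"`) adjacent pair of the
#' grid, each exactly once. An interior tile takes part in four pairs, an edge
#' tile in three and a corner tile in two.
#'
#' @param grid A [tile_grid()], or a list with `rows` and `cols`.
#' @return A tibble with columns `direction` (`"H"` or `"V"`), `row`, `col`
#'   (0-based position of the first -- west or north -- tile of the pair),
#'   `row2`, `col2` (the second tile). Row count is
#'   `rows*(cols-1) + (rows-1)*cols`.
#' @export
#' @examples
#' neighbor_pairs(list(rows = 2, cols = 2))
neighbor_pairs <- function(grid) {
  rows <- grid$rows
  cols <- grid$cols
  h <- if (cols > 1) {
    tidyr::expand_grid(direction = "H", row = 0:(rows - 1L), col = 0:(cols - 2L))
  } else {
    tibble::tibble(direction = character(), row = integer(), col = integer())
  }
  v <- if (rows > 1) {
    tidyr::expand_grid(direction = "V", row = 0:(rows - 2L), col = 0:(cols - 1L))
  } else {
    tibble::tibble(direction = character(), row = integer(), col = integer())
  }
  dplyr::bind_rows(h, v) |>
    dplyr::mutate(
      row2 = .data$row + (.data$direction == "V"),
      col2 = .data$col + (.data$direction == "H")
    )
}
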