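#' Stitch a tile grid end to end
#'
#' Runs the full pipeline: pairwise translations by phase correlation
#' ([compute_translations()]), stage-model estimation or user override
#' ([build_stage_model()]), median/4r repair ([filter_translations()]),
#' constrained hill-climb refinement ([optimize_translations()]), maximum
#' spanning tree assembly ([maximum_spanning_tree()]) and position
#' composition ([compose_positions()]).
#'
#' @param grid A [tile_grid()].
#' @param overlap,alpha,r Optional user-supplied stage parameters (percent,
#'   degrees, px); supplied values bypass estimation.
#' @param backlash_tol Overlap tolerance in percentage points (default 3).
#' @param n_peaks Phase-correlation peaks to evaluate (default 2).
#' @param ncc_min Minimum ncc to trust an entry during estimation
#'   (default 0.5).
#' @param min_overlap_px Minimum valid overlap for [ncc()]; default
#'   `max(25, 1% of tile area)`.
#' @return A `stitch_result` list: `layout` (a `mosaic_layout`), `model`
#'   (the [stage_model()] used), `translations` (raw), `optimized`
#'   (filtered + refined), `grid`.
#' @export
#' @examples
#' src <- generate_source(seed = 3, 320, 320, "texture")
#' acq <- simulate_acquisition(src, 2, 2, 96, 96, overlap_pct = 20, seed = 3)
#' res <- stitch_grid(acq$grid)
#' res$layout
stitch_grid <- function(grid, overlap = NULL, alpha = NULL, r = NULL,
                        backlash_tol = 3, n_peaks = 2L, ncc_min = 0.5,
                        min_overlap_px = NULL) {
  raw <- compute_translations(grid, n_peaks = n_peaks,
                              min_overlap_px = min_overlap_px)
  model <- build_stage_model(raw, grid, overlap = overlap, alpha = alpha,
                             r = r, backlash_tol = backlash_tol,
                             ncc_min = ncc_min)
  filt <- filter_translations(raw, model, grid)
  opt <- optimize_translations(filt, model, grid,
                               min_overlap_px = min_overlap_px)
  graph <- build_tile_graph(opt, model, grid)
  tree <- maximum_spanning_tree(graph, grid)
  layout <- compose_positions(tree, grid)
  if (!is.null(grid$paths)) layout$file <- grid$paths
  structure(
    list(layout = layout, model = model, translations = raw,
         optimized = opt, grid = grid),
    class = "stitch_result"
  )
}

#' @export
print.stitch_result <- function(x, ...) {
  cat(sprintf("<stitch_result> %d x %d grid, mosaic %d x %d px\n",
              x$grid$rows, x$grid$cols,
              attr(x$layout, "mosaic_width"), attr(x$layout, "mosaic_height")))
  print(x$model)
  invisible(x)
}

#' @rdname stitch_grid
#' @param x A `stitch_result`.
#' @param ... Unused.
#' @method tidy stitch_result
#' @export
tidy.stitch_result <- function(x, ...) {
  tibble::as_tibble(x$layout)
}

#' @rdname stitch_grid
#' @method glance stitch_result
#' @export
glance.stitch_result <- function(x, ...) {
  valid <- !is.na(x$optimized$ncc)
  dplyr::bind_cols(
    tibble::tibble(
      rows = x$grid$rows, cols = x$grid$cols,
      mosaic_width = attr(x$layout, "mosaic_width"),
      mosaic_height = attr(x$layout, "mosaic_height"),
      mean_ncc = mean(x$optimized$ncc[valid]),
      n_repaired = sum(x$optimized$repaired)
    ),
    glance(x$model)
  )
}

#' Plot a mosaic layout
#'
#' Tile footprints at their stitched positions, colored by the ncc of the
#' spanning-tree edge that placed each tile (the root is gray). The y axis
#' is reversed to match image coordinates (y grows downward).
#'
#' @param object A `mosaic_layout` (from [compose_positions()]) or a
#'   `stitch_result`.
#' @param tile_w,tile_h Tile size (taken from the result's grid when a
#'   `stitch_result` is given).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mosaic_layout
#' @export
autoplot.mosaic_layout <- function(object, tile_w, tile_h, ...) {
  ggplot2::ggplot(tibble::as_tibble(object)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x, xmax = .data$x + tile_w,
      ymin = .data$y, ymax = .data$y + tile_h,
      fill = .data$edge_ncc
    ), color = "white", alpha = 0.9) +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$x + tile_w / 2, y = .data$y + tile_h / 2,
      label = sprintf("%d,%d", .data$row, .data$col)
    ), size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "gray70", limits = c(-1, 1)) +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "edge ncc",
                  title = "Stitched tile layout") +
    ggplot2::coord_equal()
}

#' @rdname autoplot.mosaic_layout
#' @method autoplot stitch_result
#' @export
autoplot.stitch_result <- function(object, ...) {
  autoplot.mosaic_layout(object$layout, tile_w = object$grid$tile_w,
                         tile_h = object$grid$tile_h, ...)
}

#' @rdname autoplot.mosaic_layout
#' @method autoplot accuracy_report
#' @export
autoplot.accuracy_report <- function(object, ...) {
  ggplot2::ggplot(object$matches, ggplot2::aes(.data$d_err, .data$s_err)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "centroid distance error (px)",
                  y = "area error (%)",
                  title = sprintf("ROI accuracy (FP+FN = %d)",
                                  object$fp + object$fn))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
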