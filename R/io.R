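#' Map grid positions to acquisition filenames
#'
#' Automated microscopes name tiles either by row/column or by a sequential
#' position index, starting from any corner, in row-major, column-major or
#' serpentine order. The pattern uses brace placeholders whose repeat count
#' sets the zero padding: `{rr}`/`{ccc}` for row/column indices (0-based) or
#' `{ppp}` for a sequential index beginning at `start_index`.
#'
#' @param pattern Filename pattern containing `{r...}` + `{c...}`, or
#'   `{p...}`.
#' @param rows,cols Grid dimensions.
#' @param origin Corner where acquisition started: `"top-left"` (default),
#'   `"top-right"`, `"bottom-left"`, `"bottom-right"`.
#' @param numbering `"row-major"` (default), `"column-major"`,
#'   `"serpentine-row"`, `"serpentine-col"`.
#' @param start_index First sequential index (default 1).
#' @return A `rows x cols` character matrix: entry `[r+1, c+1]` is the file
#'   of the tile at grid position (r, c) with row 0 at the top, col 0 at the
#'   left.
#' @export
#' @examples
#' resolve_grid_filenames("img_r{rr}_c{cc}.tif", 2, 2)
#' resolve_grid_filenames("t_{ppp}.tif", 2, 2, numbering = "serpentine-row")
resolve_grid_filenames <- function(pattern, rows, cols,
                                   origin = c("top-left", "top-right",
                                              "bottom-left", "bottom-right"),
                                   numbering = c("row-major", "column-major",
                                                 "serpentine-row",
                                                 "serpentine-col"),
                                   start_index = 1L) {
  origin <- match.arg(origin)
  numbering <- match.arg(numbering)
  rc <- regmatches(pattern, regexec("\\{(r+)\\}", pattern))[[1]]
  cc <- regmatches(pattern, regexec("\\{(c+)\\}", pattern))[[1]]
  pp <- regmatches(pattern, regexec("\\{(p+)\\}", pattern))[[1]]
  has_rc <- length(rc) > 0 && length(cc) > 0
  has_p <- length(pp) > 0
  if (!has_rc && !has_p) {
    stop("pattern needs either {r...} and {c...} or {p...} placeholders")
  }
  pad <- function(i, width, what) {
    if (any(i > 10^width - 1)) {
      stop("index ", max(i), " overflows the ", width, "-digit {",
           what, "} padding")
    }
    formatC(i, width = width, flag = "0")
  }
  # acquisition-frame indices (ar, ac): where the microscope believed it was,
  # counted from the acquisition's origin corner
  out <- matrix(NA_character_, rows, cols)
  for (r in 0:(rows - 1L)) for (c in 0:(cols - 1L)) {
    ar <- if (origin %in% c("bottom-left", "bottom-right")) rows - 1L - r else r
    ac <- if (origin %in% c("top-right", "bottom-right")) cols - 1L - c else c
    if (has_rc) {
      f <- sub("\\{r+\\}", pad(ar, nchar(rc[2]), "r"), pattern)
      f <- sub("\\{c+\\}", pad(ac, nchar(cc[2]), "c"), f)
    } else {
      k <- switch(numbering,
        "row-major" = ar * cols + ac,
        "column-major" = ac * rows + ar,
        "serpentine-row" = ar * cols + if (ar %% 2 == 0) ac else cols - 1L - ac,
        "serpentine-col" = ac * rows + if (ac %% 2 == 0) ar else rows - 1L - ar
      )
      f <- sub("\\{p+\\}", pad(k + start_index, nchar(pp[2]), "p"), pattern)
    }
    out[r + 1L, c + 1L] <- f
  }
  out
}

#' Read one grayscale tile
#'
#' Reads an 8/16-bit grayscale TIFF or PNG into an integer-valued numeric
#' matrix (0..255 or 0..65535). Multi-page TIFFs use the first page with a
#' warning; RGB images are rejected.
#'
#' @param path File path (`.tif`, `.tiff`, `.png`).
#' @return Numeric matrix with attribute `bits` (8 or 16).
#' @export
read_tile <- function(path) {
  if (!file.exists(path)) stop("tile file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (is.list(img)) {
      if (length(img) > 1) {
        warning("multi-page TIFF ", basename(path), ": using first page")
      }
      img <- img[[1]]
    }
    bits <- if (max(img) > 255 || isTRUE(attr(img, "bits.per.sample") == 16)) 16L else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path)
    bits <- 8L
    if (!is.null(attr(img, "bit.depth")) && attr(img, "bit.depth") == 16) bits <- 16L
    img <- round(img * (2^bits - 1))
  } else {
    stop("unsupported tile format: ", path)
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1) stop("RGB/multi-channel tile not supported: ", path,
                              " (convert to grayscale upstream)")
    img <- img[, , 1]
  }
  img <- img + 0
  attr(img, "bits") <- bits
  img
}

#' Write one grayscale tile
#'
#' @param img Numeric matrix with integer values in range for `bits`.
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @param bits Bit depth, 8 or 16 (default from the image's `bits` attribute,
#'   else 16).
#' @return `path`, invisibly.
#' @export
write_tile <- function(img, path, bits = attr(img, "bits") %||% 16L) {
  mx <- 2^bits - 1
  scaled <- pmin(pmax(round(img), 0), mx) / mx
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else {
    stop("unsupported tile format: ", path)
  }
  invisible(path)
}

#' Read a tile grid from disk
#'
#' @param dir Directory containing the tiles.
#' @param pattern,rows,cols,origin,numbering,start_index As in
#'   [resolve_grid_filenames()].
#' @return A [tile_grid()].
#' @export
read_tile_grid <- function(dir, pattern, rows, cols, origin = "top-left",
                           numbering = "row-major", start_index = 1L) {
  files <- resolve_grid_filenames(pattern, rows, cols, origin, numbering,
                                  start_index)
  tiles <- vector("list", rows * cols)
  bits <- 16L
  for (r in 0:(rows - 1L)) for (c in 0:(cols - 1L)) {
    p <- file.path(dir, files[r + 1L, c + 1L])
    if (!file.exists(p)) {
      stop("missing tile at grid (", r, ", ", c, "): ", p)
    }
    img <- read_tile(p)
    bits <- max(bits, attr(img, "bits"))
    tiles[[r * cols + c + 1L]] <- img
  }
  tile_grid(tiles, rows, cols, paths = as.vector(t(files)), bits = bits)
}

#' Write a tile grid to disk
#'
#' @param grid A [tile_grid()].
#' @param dir Output directory (created if needed).
#' @param pattern,origin,numbering,start_index As in
#'   [resolve_grid_filenames()].
#' @return The filename matrix, invisibly.
#' @export
write_tile_grid <- function(grid, dir, pattern = "tile_r{rr}_c{cc}.tif",
                            origin = "top-left", numbering = "row-major",
                            start_index = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- resolve_grid_filenames(pattern, grid$rows, grid$cols, origin,
                                  numbering, start_index)
  for (r in 0:(grid$rows - 1L)) for (c in 0:(grid$cols - 1L)) {
    write_tile(grid_tile(grid, r, c), file.path(dir, files[r + 1L, c + 1L]),
               bits = grid$bits)
  }
  invisible(files)
}

#' Write / read a positions file
#'
#' One line per tile, bit-exact format:
#' `file: <name>; corr: <ncc, 10 decimals or -1.0>; position: (<x>, <y>); grid: (<col>, <row>);`
#'
#' @param layout A [compose_positions()] layout (columns `row`, `col`, `x`,
#'   `y`, `edge_ncc`); `file` column or the grid's paths may supply names.
#' @param path Output file.
#' @param files Optional character vector of filenames, row-major.
#' @return `write_positions`: `path` invisibly. `read_positions`: a
#'   `mosaic_layout` tibble with columns `row`, `col`, `x`, `y`, `edge_ncc`,
#'   `file`.
#' @export
write_positions <- function(layout, path, files = NULL) {
  lay <- layout[order(layout$row, layout$col), ]
  nm <- files %||%
    (if ("file" %in% names(lay)) lay$file else NULL) %||%
    sprintf("tile_r%d_c%d.tif", lay$row, lay$col)
  encc <- if ("edge_ncc" %in% names(lay)) lay$edge_ncc else rep(NA_real_, nrow(lay))
  corr <- ifelse(is.na(encc), "-1.0", sprintf("%.10f", encc))
  lines <- sprintf("file: %s; corr: %s; position: (%d, %d); grid: (%d, %d);",
                   nm, corr, lay$x, lay$y, lay$col, lay$row)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rx <- paste0("^file: (.+); corr: (-?[0-9.]+); ",
               "position: \\((-?[0-9]+), (-?[0-9]+)\\); ",
               "grid: \\(([0-9]+), ([0-9]+)\\);\\s*$")
  m <- regmatches(lines, regexec(rx, lines))
  bad <- which(vapply(m, length, 1L) != 7L)
  if (length(bad) > 0) {
    stop("malformed positions line ", bad[1], ": ", lines[bad[1]])
  }
  f <- vapply(m, `[[`, "", 2)
  corr <- as.numeric(vapply(m, `[[`, "", 3))
  layout <- tibble::tibble(
    row = as.integer(vapply(m, `[[`, "", 7)),
    col = as.integer(vapply(m, `[[`, "", 6)),
    x = as.integer(vapply(m, `[[`, "", 4)),
    y = as.integer(vapply(m, `[[`, "", 5)),
    edge_ncc = ifelse(corr < 0, NA_real_, corr),
    file = f
  ) |> dplyr::arrange(.data$row, .data$col)
  class(layout) <- c("mosaic_layout", class(layout))
  layout
}

#' Write / read an ROI table
#'
#' CSV with header `label,x,y,area`.
#'
#' @param rois Tibble with columns `label`, `x`, `y`, `area`.
#' @param path CSV path.
#' @return `write_rois`: `path` invisibly. `read_rois`: the tibble.
#' @export
write_rois <- function(rois, path) {
  readr::write_csv(rois[, c("label", "x", "y", "area")], path)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), x = readr::col_double(),
    y = readr::col_double(), area = readr::col_double()
  ))
}
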