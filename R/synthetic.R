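#' Generate a synthetic source image
#'
#' Produces the large "specimen" raster that [simulate_acquisition()] cuts
#' into tiles. Three content types are available:
#'
#' * `"blobs"`: Gaussian blobs placed by a Poisson process on a low-noise
#'   background -- a stand-in for sparse cell colonies. Each blob's centroid
#'   and half-maximum area are recorded as an ROI.
#' * `"texture"`: low-pass filtered white noise, feature-rich everywhere.
#' * `"flat"`: a constant image, for degenerate-case testing.
#'
#' Intensities are scaled to `[1, peak]` (minimum 1) so that the value 0 is
#' reserved for blank (uncovered) mosaic pixels.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param width,height Raster dimensions in px.
#' @param content One of `"blobs"`, `"texture"`, `"flat"`.
#' @param blob_density Expected blobs per pixel (blobs content only).
#'   Default 1e-4.
#' @param blob_sigma Blob radius parameter in px (Gaussian sd). Default 6.
#' @param peak Maximum intensity (default 255).
#' @return A list with `image` (numeric matrix, `height x width`) and `rois`
#'   (tibble `label`, `x`, `y`, `area`; empty for texture/flat). Centroids are
#'   0-based pixel coordinates in the source frame.
#' @export
generate_source <- function(seed, width, height,
                            content = c("texture", "blobs", "flat"),
                            blob_density = 1e-4, blob_sigma = 6, peak = 255) {
  content <- match.arg(content)
  set.seed(as.integer(seed))
  rois <- tibble::tibble(label = character(), x = double(), y = double(),
                         area = double())
  if (content == "flat") {
    return(list(image = matrix(peak / 2, height, width), rois = rois))
  }
  if (content == "texture") {
    img <- pink_noise(height, width)
  } else {
    n <- stats::rpois(1, blob_density * width * height)
    img <- matrix(0, height, width)
    if (n > 0) {
      cx <- stats::runif(n, 0, width - 1)
      cy <- stats::runif(n, 0, height - 1)
      amp <- stats::runif(n, 0.6, 1)
      xg <- 0:(width - 1); yg <- 0:(height - 1)
      for (i in seq_len(n)) {
        gx <- exp(-((xg - cx[i])^2) / (2 * blob_sigma^2))
        gy <- exp(-((yg - cy[i])^2) / (2 * blob_sigma^2))
        img <- img + amp[i] * outer(gy, gx)
      }
      # half-maximum footprint of an isotropic Gaussian: pi * (sigma*sqrt(2 ln 2))^2
      rois <- tibble::tibble(
        label = sprintf("blob_%03d", seq_len(n)),
        x = cx, y = cy,
        area = pi * (blob_sigma * sqrt(2 * log(2)))^2
      )
    }
    img <- img + 0.02 * smooth_noise(height, width, sigma = 1)
  }
  rng <- range(img)
  if (diff(rng) == 0) {
    img[] <- peak / 2
  } else {
    img <- 1 + (img - rng[1]) / diff(rng) * (peak - 1)
  }
  list(image = img, rois = rois)
}

freq_axis <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

# broadband 1/f ("pink") noise -- the standard spectral model of natural
# images; keeps enough high-frequency content for phase correlation
pink_noise <- function(h, w) {
  z <- matrix(stats::rnorm(h * w), h, w)
  f2 <- outer(freq_axis(h)^2, freq_axis(w)^2, `+`)
  amp <- 1 / sqrt(f2 + (1 / max(h, w))^2)
  Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / length(z)
}

# low-pass filtered white noise via FFT with a Gaussian transfer function
smooth_noise <- function(h, w, sigma = 2) {
  z <- matrix(stats::rnorm(h * w), h, w)
  g <- exp(-2 * pi^2 * sigma^2 * outer(freq_axis(h)^2, freq_axis(w)^2, `+`))
  Re(stats::fft(stats::fft(z) * g, inverse = TRUE)) / length(z)
}

#' Simulate a grid acquisition with known ground truth
#'
#' Emulates a motorized-stage acquisition: the stage visits an R x C grid of
#' nominal positions spaced `tile_extent * (1 - overlap/100)` apart, each
#' position perturbed by per-axis jitter of magnitude `r_px` (the stage
#' repeatability) plus an optional backlash offset added to x on odd rows
#' (serpentine actuator reversal). The camera axes are rotated by `alpha_deg`
#' relative to the stage axes, so a pure horizontal stage step H is observed
#' as `(H cos a, -H sin a)` and a vertical step V as `(V sin a, V cos a)`.
#' Camera positions are rounded to integer pixels and each tile is cut from
#' the source at its position; Gaussian pixel noise and a multiplicative
#' intensity decay on re-imaged overlap strips (a photobleaching stand-in)
#' can be added.
#'
#' @param source Source raster (numeric matrix) or the list returned by
#'   [generate_source()].
#' @param rows,cols Grid dimensions.
#' @param tile_w,tile_h Tile size in px.
#' @param overlap_pct Nominal overlap percent (0-100).
#' @param alpha_deg Camera angle in degrees (small; applied to stage
#'   positions, not as an image rotation).
#' @param r_px Stage repeatability in px; jitter is drawn uniformly from
#'   `[-r, r]` per axis (`jitter = "gaussian"` uses sd `r/2` truncated to
#'   `[-r, r]`).
#' @param backlash_px Constant x offset added on odd rows (default 0).
#' @param noise_sigma Gaussian pixel noise sd, in intensity units (default 0).
#' @param bleach_factor Multiplier (`<= 1`) applied to the west/north overlap
#'   strips of tiles acquired after their neighbor (default 1 = no decay).
#' @param seed Integer seed.
#' @param jitter `"uniform"` (default) or `"gaussian"`.
#' @return A `synthetic_acquisition` list: `grid` (a [tile_grid()]),
#'   `truth_layout` (tibble `row`, `col`, `x`, `y`, min-normalized),
#'   `truth_model` (a [stage_model()]), `source`, `rois` (source-frame,
#'   shifted into mosaic frame), `seed`.
#' @export
simulate_acquisition <- function(source, rows, cols, tile_w, tile_h,
                                 overlap_pct = 10, alpha_deg = 0, r_px = 0,
                                 backlash_px = 0, noise_sigma = 0,
                                 bleach_factor = 1, seed = 1L,
                                 jitter = c("uniform", "gaussian")) {
  jitter <- match.arg(jitter)
  rois <- tibble::tibble(label = character(), x = double(), y = double(),
                         area = double())
  if (is.list(source) && !is.matrix(source)) {
    rois <- source$rois %||% rois
    source <- source$image
  }
  set.seed(as.integer(seed))
  step_x <- tile_w * (1 - overlap_pct / 100)
  step_y <- tile_h * (1 - overlap_pct / 100)
  jit <- function(n) {
    if (r_px == 0) return(rep(0, n))
    if (jitter == "uniform") stats::runif(n, -r_px, r_px)
    else pmax(-r_px, pmin(r_px, stats::rnorm(n, 0, r_px / 2)))
  }
  pos <- tidyr::expand_grid(row = 0:(rows - 1L), col = 0:(cols - 1L)) |>
    dplyr::mutate(
      sx = .data$col * step_x + jit(dplyr::n()) + ifelse(.data$row %% 2 == 1, backlash_px, 0),
      sy = .data$row * step_y + jit(dplyr::n())
    )
  a <- alpha_deg * pi / 180
  # camera frame = [[cos a, sin a], [-sin a, cos a]] %*% stage frame
  pos <- pos |>
    dplyr::mutate(
      x = round(.data$sx * cos(a) + .data$sy * sin(a)),
      y = round(-.data$sx * sin(a) + .data$sy * cos(a))
    )
  ox <- min(pos$x); oy <- min(pos$y)
  pos$x <- as.integer(pos$x - ox); pos$y <- as.integer(pos$y - oy)
  if (max(pos$x) + tile_w > ncol(source) || max(pos$y) + tile_h > nrow(source)) {
    stop("simulate_acquisition: grid footprint exceeds the source image (",
         max(pos$y) + tile_h, " x ", max(pos$x) + tile_w, " needed)")
  }
  ov_x <- as.integer(round(tile_w * overlap_pct / 100))
  ov_y <- as.integer(round(tile_h * overlap_pct / 100))
  tiles <- vector("list", rows * cols)
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    t <- source[(p$y + 1):(p$y + tile_h), (p$x + 1):(p$x + tile_w), drop = FALSE]
    if (bleach_factor < 1) {
      if (p$col > 0 && ov_x > 0) t[, 1:ov_x] <- t[, 1:ov_x] * bleach_factor
      if (p$row > 0 && ov_y > 0) t[1:ov_y, ] <- t[1:ov_y, ] * bleach_factor
    }
    if (noise_sigma > 0) {
      t <- t + matrix(stats::rnorm(length(t), 0, noise_sigma), nrow(t))
    }
    tiles[[p$row * cols + p$col + 1L]] <- t
  }
  truth_model <- stage_model(
    overlap_h = overlap_pct, overlap_v = overlap_pct, alpha = alpha_deg,
    r = max(1, r_px), backlash_tol = 3, h_valid = TRUE, v_valid = TRUE
  )
  structure(
    list(
      grid = tile_grid(tiles, rows, cols),
      truth_layout = pos[, c("row", "col", "x", "y")],
      truth_model = truth_model,
      source = source,
      rois = rois,
      seed = as.integer(seed)
    ),
    class = "synthetic_acquisition"
  )
}

#' Corrupt a random subset of a translation table
#'
#' Emulates registration failures from feature-poor overlap regions: a seeded
#' random fraction of entries is replaced by uniform random displacements with
#' a low ncc score. Used to exercise the median/4r repair filter.
#'
#' @param translations Table from [compute_translations()].
#' @param fraction Fraction of entries to corrupt, in `[0, 1]`.
#' @param magnitude Maximum absolute corrupted displacement in px
#'   (default 500).
#' @param seed Integer seed.
#' @return The table with corrupted entries and a logical `corrupted` column.
#' @export
corrupt_translations <- function(translations, fraction, magnitude = 500,
                                 seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(as.integer(seed))
  n <- nrow(translations)
  k <- round(fraction * n)
  idx <- if (k > 0) sample.int(n, k) else integer()
  translations$corrupted <- FALSE
  if (k > 0) {
    translations$corrupted[idx] <- TRUE
    translations$dx[idx] <- as.integer(round(stats::runif(k, -magnitude, magnitude)))
    translations$dy[idx] <- as.integer(round(stats::runif(k, -magnitude, magnitude)))
    translations$ncc[idx] <- stats::runif(k, 0, 0.2)
  }
  translations
}
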