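#' Phase correlation surface of two equally sized tiles
#'
#' Inverse 2-D Fourier transform of the normalized cross-power spectrum
#' `F(a) * Conj(F(b)) / max(|.|, eps)`. For `b` equal to `a` cyclically
#' shifted so that b's origin sits at `(dx, dy)` in a's frame, the surface
#' peaks at index `(dy mod H, dx mod W)` (0-based, row = y). The guard
#' `eps = 1e-12 * max |cross-power|` prevents division blow-up at
#' zero-magnitude frequencies. No window function is applied; inputs are
#' promoted to double before the FFT.
#'
#' @param a,b Numeric matrices of identical dimensions.
#' @return A numeric matrix of the same shape with attribute `degenerate`
#'   (TRUE when the cross-power spectrum is identically zero, e.g. two
#'   constant images, in which case the surface is flat zero).
#' @export
phase_correlation <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("phase_correlation: tiles differ in shape")
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("phase_correlation: non-finite pixel values")
  }
  cp <- stats::fft(a + 0) * Conj(stats::fft(b + 0))
  m <- Mod(cp)
  mx <- max(m)
  # degenerate when the spectrum is zero everywhere but the DC term (e.g.
  # constant images): no spatial structure to correlate
  m_ac <- m
  m_ac[1, 1] <- 0
  if (mx == 0 || max(m_ac) <= 1e-12 * mx) {
    surf <- matrix(0, nrow(a), ncol(a))
    attr(surf, "degenerate") <- TRUE
    return(surf)
  }
  surf <- Re(stats::fft(cp / pmax(m, 1e-12 * mx), inverse = TRUE)) / length(a)
  attr(surf, "degenerate") <- FALSE
  surf
}

#' Locate the top peaks of a phase-correlation surface
#'
#' Peaks are selected in decreasing surface value. After each selection the
#' 3 x 3 wrap-around neighborhood of the chosen cell is masked, so successive
#' peaks are distinct features rather than adjacent samples of one lobe.
#'
#' @param surface Numeric matrix (e.g. from [phase_correlation()]).
#' @param n Number of peaks to return (default 2).
#' @return Integer matrix with `n` rows and columns `row`, `col` (0-based).
#' @export
find_peaks <- function(surface, n = 2L) {
  stopifnot(n >= 1)
  h <- nrow(surface); w <- ncol(surface)
  if (n > length(surface)) stop("find_peaks: n exceeds surface size")
  s <- surface
  out <- matrix(NA_integer_, n, 2, dimnames = list(NULL, c("row", "col")))
  for (k in seq_len(n)) {
    if (all(is.na(s))) stop("find_peaks: fewer than n unmasked cells")
    i <- which.max(s) # first index on ties: deterministic
    r <- (i - 1L) %% h
    cc <- (i - 1L) %/% h
    out[k, ] <- c(r, cc)
    rr <- ((r + (-1:1)) %% h) + 1L
    cw <- ((cc + (-1:1)) %% w) + 1L
    s[rr, cw] <- NA_real_
  }
  out
}

#' Four periodic interpretations of a phase-correlation peak
#'
#' A Fourier-domain peak index is ambiguous: each of its two coordinates may
#' represent a positive shift or its negative periodic alias. The four
#' candidates for peak `(row, col)` in an `H x W` surface are
#' `(col, row)`, `(col, row - H)`, `(col - W, row)`, `(col - W, row - H)`
#' as `(dx, dy)` displacements.
#'
#' @param peak Integer vector `(row, col)`, 0-based.
#' @param shape Integer vector `(H, W)`.
#' @return A 4 x 2 integer matrix with columns `dx`, `dy`.
#' @export
candidate_translations <- function(peak, shape) {
  r <- peak[[1]]; cc <- peak[[2]]
  h <- shape[[1]]; w <- shape[[2]]
  stopifnot(r >= 0, r < h, cc >= 0, cc < w)
  m <- cbind(dx = c(cc, cc, cc - w, cc - w),
             dy = c(r, r - h, r, r - h))
  storage.mode(m) <- "integer"
  m
}

#' Normalized cross-correlation of the overlap under a displacement
#'
#' Places tile `b`'s origin at `(dx, dy)` in `a`'s pixel frame, extracts the
#' two coinciding rectangular regions and returns their Pearson correlation.
#' Returns `NA` (invalid) when the overlap has fewer than `min_overlap_px`
#' pixels or either region has zero variance.
#'
#' @param a,b Numeric matrices of identical dimensions.
#' @param dx,dy Integer displacement of b's origin relative to a's origin
#'   (x rightward, y downward).
#' @param min_overlap_px Minimum overlap pixel count for a valid score.
#'   Default: `max(25, ceiling(0.01 * tile area))`.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when invalid.
#' @export
ncc <- function(a, b, dx, dy, min_overlap_px = default_min_overlap(a)) {
  if (!all(dim(a) == dim(b))) stop("ncc: tiles differ in shape")
  h <- nrow(a); w <- ncol(a)
  x0 <- max(0L, dx); x1 <- min(w, w + dx) # [x0, x1) in a's frame, 0-based
  y0 <- max(0L, dy); y1 <- min(h, h + dy)
  if (x1 - x0 <= 0 || y1 - y0 <= 0) return(NA_real_)
  if ((x1 - x0) * (y1 - y0) < min_overlap_px) return(NA_real_)
  ra <- a[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  rb <- b[(y0 - dy + 1):(y1 - dy), (x0 - dx + 1):(x1 - dx), drop = FALSE]
  va <- as.vector(ra); vb <- as.vector(rb)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Default minimum overlap for ncc validity
#'
#' At least 25 pixels and at least 1 percent of the tile area; correlations
#' over smaller overlaps are statistically meaningless.
#'
#' @param a A tile matrix (used for its area).
#' @return Integer pixel count.
#' @export
default_min_overlap <- function(a) {
  max(25L, as.integer(ceiling(0.01 * length(a))))
}

#' Pairwise translation between two adjacent tiles
#'
#' Runs [phase_correlation()], takes the top `n_peaks` peaks, scores the four
#' periodic interpretations of each with [ncc()] and returns the candidate
#' with the highest valid score. Ties are broken by peak rank then candidate
#' order, so the result is deterministic.
#'
#' @inheritParams ncc
#' @param n_peaks Number of phase-correlation peaks to consider (default 2).
#' @return A one-row tibble with columns `dx`, `dy`, `ncc` (`ncc` is `NA`
#'   when no candidate produced a valid score; `dx`, `dy` are then `NA` too).
#' @export
#' @examples
#' src <- matrix(stats::runif(96 * 96), 96, 96)
#' a <- src[1:64, 1:64]; b <- src[3:66, 11:74]  # true offset dx = 10, dy = 2
#' pairwise_translation(a, b)
pairwise_translation <- function(a, b, n_peaks = 2L,
                                 min_overlap_px = default_min_overlap(a)) {
  surf <- phase_correlation(a, b)
  if (isTRUE(attr(surf, "degenerate"))) {
    return(tibble::tibble(dx = NA_integer_, dy = NA_integer_, ncc = NA_real_))
  }
  peaks <- find_peaks(surf, n_peaks)
  best <- NULL
  for (k in seq_len(nrow(peaks))) {
    cand <- candidate_translations(peaks[k, ], dim(a))
    for (j in seq_len(nrow(cand))) {
      s <- ncc(a, b, cand[j, "dx"], cand[j, "dy"], min_overlap_px)
      if (!is.na(s) && (is.null(best) || s > best$ncc)) {
        best <- list(dx = cand[j, "dx"], dy = cand[j, "dy"], ncc = s)
      }
    }
  }
  if (is.null(best)) {
    tibble::tibble(dx = NA_integer_, dy = NA_integer_, ncc = NA_real_)
  } else {
    tibble::tibble(dx = as.integer(best$dx), dy = as.integer(best$dy),
                   ncc = best$ncc)
  }
}

#' Compute the full translation table of a grid
#'
#' Applies [pairwise_translation()] to every adjacent pair from
#' [neighbor_pairs()]. The result replaces the classical pair of H and V
#' translation matrices with one long table: the `"H"` rows are the
#' west-to-east pairs (rows x (cols-1) of them), the `"V"` rows the
#' north-to-south pairs ((rows-1) x cols).
#'
#' @param grid A [tile_grid()].
#' @inheritParams pairwise_translation
#' @return A tibble with columns `direction`, `row`, `col`, `row2`, `col2`,
#'   `dx`, `dy`, `ncc`, `repaired` (all FALSE here; set by
#'   [filter_translations()]).
#' @export
compute_translations <- function(grid, n_peaks = 2L,
                                 min_overlap_px = NULL) {
  stopifnot(inherits(grid, "tile_grid"))
  mop <- min_overlap_px %||% default_min_overlap(grid$tiles[[1]])
  pairs <- neighbor_pairs(grid)
  res <- purrr::pmap(pairs, function(direction, row, col, row2, col2) {
    pairwise_translation(grid_tile(grid, row, col), grid_tile(grid, row2, col2),
                         n_peaks = n_peaks, min_overlap_px = mop)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res)) |>
    dplyr::mutate(repaired = FALSE)
}
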