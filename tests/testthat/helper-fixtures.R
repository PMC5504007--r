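# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# two crops of one textured source with a known integer offset
texture_pair <- function(seed, dx, dy, w = 64, h = 64) {
  src <- cached(paste0("src", seed, "_", w, "_", h),
                generate_source(seed, 3 * w, 3 * h, "texture"))$image
  x0 <- w; y0 <- h # a's origin, leaving room for negative offsets
  a <- src[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)]
  b <- src[(y0 + dy + 1):(y0 + dy + h), (x0 + dx + 1):(x0 + dx + w)]
  list(a = a, b = b)
}

# small jittered acquisition reused by several suites
std_acq <- function(seed = 7, rows = 3, cols = 3, tile = 96, overlap = 20,
                    alpha = 1, r = 2, noise = 2) {
  key <- paste("acq", seed, rows, cols, tile, overlap, alpha, r, noise,
               sep = "_")
  cached(key, {
    span <- ceiling((max(rows, cols) - 1) * tile * (1 - overlap / 100) +
                      tile + 8 * (r + 2))
    src <- generate_source(seed + 100, span, span, "texture")
    simulate_acquisition(src, rows, cols, tile, tile, overlap_pct = overlap,
                         alpha_deg = alpha, r_px = r, noise_sigma = noise,
                         seed = seed)
  })
}

# brute-force Pearson correlation of the overlap under (dx, dy): the
# double-loop oracle, independent of ncc()'s vectorized extraction
ncc_oracle <- function(a, b, dx, dy, min_px = 25) {
  va <- c(); vb <- c()
  h <- nrow(a); w <- ncol(a)
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    xb <- x - dx; yb <- y - dy
    if (xb >= 0 && xb < w && yb >= 0 && yb < h) {
      va <- c(va, a[y + 1, x + 1]); vb <- c(vb, b[yb + 1, xb + 1])
    }
  }
  if (length(va) < min_px) return(NA_real_)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

# exhaustive ncc argmax over the (4r+1)^2 window: the hill-climb oracle
window_argmax <- function(a, b, dx0, dy0, r, min_px = 25) {
  best <- NULL
  for (dx in (dx0 - 2 * r):(dx0 + 2 * r)) {
    for (dy in (dy0 - 2 * r):(dy0 + 2 * r)) {
      s <- ncc(a, b, dx, dy, min_px)
      if (!is.na(s) && (is.null(best) || s > best$ncc)) {
        best <- list(dx = dx, dy = dy, ncc = s)
      }
    }
  }
  best
}

# all spanning trees of a small edge list by exhaustive edge-subset search
max_tree_weight_bruteforce <- function(edges, n_vertices, vid) {
  m <- nrow(edges)
  best <- -Inf
  combos <- utils::combn(m, n_vertices - 1)
  for (k in seq_len(ncol(combos))) {
    sel <- combos[, k]
    parent <- seq_len(n_vertices)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    acyclic <- TRUE
    for (e in sel) {
      u <- find(vid(edges$row[e], edges$col[e]))
      v <- find(vid(edges$row2[e], edges$col2[e]))
      if (u == v) { acyclic <- FALSE; break }
      parent[u] <- v
    }
    if (acyclic) best <- max(best, sum(edges$weight[sel]))
  }
  best
}

layout_errors <- function(layout, truth) {
  j <- dplyr::inner_join(tibble::as_tibble(layout), truth,
                         by = c("row", "col"), suffix = c("", "_true"))
  pmax(abs(j$x - j$x_true), abs(j$y - j$y_true))
}
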