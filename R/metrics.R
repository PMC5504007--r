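#' Centroid distance error between a reference and a computed ROI
#'
#' Euclidean distance `sqrt((x_m - x_c)^2 + (y_m - y_c)^2)` between the
#' measured (reference) and computed centroid of a region of interest.
#'
#' @param ref,comp Numeric vectors `(x, y)` or one-row data frames with `x`,
#'   `y` columns, in a common frame.
#' @return Distance in px.
#' @export
centroid_distance_error <- function(ref, comp) {
  p <- function(z) if (is.data.frame(z)) c(z$x[[1]], z$y[[1]]) else as.numeric(z[1:2])
  a <- p(ref); b <- p(comp)
  sqrt(sum((a - b)^2))
}

#' Signed percent area error
#'
#' `(A_c - A_m) / A_m * 100`: positive when the computed region is larger
#' than the reference.
#'
#' @param area_ref Reference (measured) area in px^2, `> 0`.
#' @param area_comp Computed area in px^2.
#' @return Signed percent.
#' @export
area_error <- function(area_ref, area_comp) {
  if (any(area_ref <= 0)) stop("area_error: reference area must be positive")
  (area_comp - area_ref) / area_ref * 100
}

#' Kabsch rigid alignment of two paired 2-D point sets
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' of the computed points onto the reference points; used to remove the
#' rigid frame offset (camera angle + origin shift) between stage-reported
#' and mosaic-derived centroids before distance errors are measured.
#'
#' @param ref,comp Matrices or data frames of paired points (n x 2, columns
#'   x, y), `n >= 2`, not all coincident.
#' @return List with `rotation` (2 x 2), `translation` (length 2),
#'   `angle_deg`, `rmsd`, and `aligned` (comp mapped onto ref's frame:
#'   `comp %*% t(R) + t`).
#' @export
kabsch_align <- function(ref, comp) {
  pm <- function(z) {
    if (is.data.frame(z)) z <- cbind(z$x, z$y)
    as.matrix(z)
  }
  a <- pm(ref); b <- pm(comp)
  stopifnot(nrow(a) == nrow(b))
  if (nrow(a) < 2) stop("kabsch_align: need at least 2 paired points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (all(a0 == 0) || all(b0 == 0)) stop("kabsch_align: all points coincident")
  s <- svd(t(b0) %*% a0)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, d)) %*% t(s$u)
  tr <- ca - as.vector(rot %*% cb)
  aligned <- t(rot %*% t(b)) + matrix(tr, nrow(b), 2, byrow = TRUE)
  list(
    rotation = rot,
    translation = tr,
    angle_deg = atan2(rot[2, 1], rot[1, 1]) * 180 / pi,
    rmsd = sqrt(mean(rowSums((aligned - a)^2))),
    aligned = aligned
  )
}

#' Match reference and computed ROIs by the Hungarian algorithm
#'
#' Builds a similarity matrix (default: negative centroid distance;
#' `"ncc_patch"` correlates image patches around the centroids when both
#' images are supplied) and solves the rectangular assignment maximizing
#' total similarity. Any matched pair farther apart than `max_dist` is then
#' unmatched: the reference ROI counts as missed (FN) and the computed one
#' as added (FP); unmatched leftovers count likewise.
#'
#' @param ref,comp Tibbles with columns `x`, `y` (and `label`, `area` if
#'   present).
#' @param similarity `"neg_distance"` (default) or `"ncc_patch"`.
#' @param max_dist Deletion threshold in px; conventionally half the smaller
#'   field-of-view dimension. Required (no FOV is known here).
#' @param ref_image,comp_image Rasters for `"ncc_patch"` similarity.
#' @param patch Half-size in px of the square patch for `"ncc_patch"`
#'   (default 16).
#' @return List with `matches` (tibble `ref_idx`, `comp_idx`, `distance`),
#'   `fp`, `fn`.
#' @export
match_rois <- function(ref, comp, similarity = c("neg_distance", "ncc_patch"),
                       max_dist, ref_image = NULL, comp_image = NULL,
                       patch = 16L) {
  similarity <- match.arg(similarity)
  nr <- nrow(ref); nc <- nrow(comp)
  if (nr == 0 || nc == 0) {
    return(list(matches = tibble::tibble(ref_idx = integer(),
                                         comp_idx = integer(),
                                         distance = double()),
                fp = nc, fn = nr))
  }
  dmat <- sqrt(outer(ref$x, comp$x, `-`)^2 + outer(ref$y, comp$y, `-`)^2)
  sim <- if (similarity == "neg_distance") {
    -dmat
  } else {
    stopifnot(!is.null(ref_image), !is.null(comp_image))
    s <- matrix(-1, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      pa <- crop_patch(ref_image, ref$x[i], ref$y[i], patch)
      pb <- crop_patch(comp_image, comp$x[j], comp$y[j], patch)
      if (!is.null(pa) && !is.null(pb) && stats::sd(pa) > 0 && stats::sd(pb) > 0) {
        s[i, j] <- stats::cor(as.vector(pa), as.vector(pb))
      }
    }
    s
  }
  # solve_LSAP minimizes cost over rows <= cols
  cost <- max(sim) - sim
  if (nr <= nc) {
    ass <- clue::solve_LSAP(cost)
    pairs <- cbind(seq_len(nr), as.integer(ass))
  } else {
    ass <- clue::solve_LSAP(t(cost))
    pairs <- cbind(as.integer(ass), seq_len(nc))
  }
  dist <- dmat[pairs]
  ok <- dist <= max_dist
  list(
    matches = tibble::tibble(ref_idx = pairs[ok, 1], comp_idx = pairs[ok, 2],
                             distance = dist[ok]),
    fp = nc - sum(ok),
    fn = nr - sum(ok)
  )
}

crop_patch <- function(img, x, y, half) {
  x <- round(x); y <- round(y)
  x0 <- x - half; x1 <- x + half; y0 <- y - half; y1 <- y + half
  if (x0 < 0 || y0 < 0 || x1 >= ncol(img) || y1 >= nrow(img)) return(NULL)
  img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
}

#' Count blank pixels inside the covered region
#'
#' A blank pixel is a zero-intensity pixel -- neither background nor
#' foreground -- inside the region the tiles are supposed to cover. A
#' correctly stitched mosaic of a strictly positive source has none.
#'
#' @param mosaic Numeric matrix.
#' @param layout Optional [compose_positions()] layout with a `tile_w`/
#'   `tile_h`-bearing `grid`; when given, the hull is the union of the
#'   placed tile rectangles. When omitted the whole mosaic is the hull.
#' @param grid The [tile_grid()] that produced the layout (required with
#'   `layout`).
#' @return Count of zero pixels strictly inside the hull.
#' @export
blank_pixel_count <- function(mosaic, layout = NULL, grid = NULL) {
  if (is.null(layout)) return(sum(mosaic == 0))
  stopifnot(!is.null(grid))
  hull <- matrix(FALSE, nrow(mosaic), ncol(mosaic))
  for (i in seq_len(nrow(layout))) {
    hull[(layout$y[i] + 1):(layout$y[i] + grid$tile_h),
         (layout$x[i] + 1):(layout$x[i] + grid$tile_w)] <- TRUE
  }
  sum(mosaic == 0 & hull)
}

#' Reference-based accuracy report
#'
#' Orchestrates the full scoring of a stitched result against reference
#' measurements: rigid (Kabsch) alignment of the computed centroids onto the
#' reference frame, Hungarian matching with the half-FOV deletion rule,
#' per-pair centroid distance ([centroid_distance_error()]) and signed area
#' errors ([area_error()]), and FP/FN counts.
#'
#' @param ref,comp ROI tibbles with columns `x`, `y`, `area` (and optionally
#'   `label`).
#' @param max_dist Deletion threshold in px (e.g. half the smaller FOV
#'   dimension). Matches farther than this count as FN + FP.
#' @param align Kabsch-align `comp` onto `ref` first (default TRUE). Needs
#'   equal-length preliminary matching, so alignment uses a first Hungarian
#'   pass on raw coordinates.
#' @return An `accuracy_report` list: `matches` (tibble with `d_err`,
#'   `s_err`), `fp`, `fn`, `summary` (one-row tibble with mean/sd of both
#'   errors and the counts), `alignment`.
#' @export
evaluate_accuracy <- function(ref, comp, max_dist, align = TRUE) {
  if (nrow(ref) == 0 || nrow(comp) == 0) {
    stop("evaluate_accuracy: empty ROI set")
  }
  alignment <- NULL
  comp_use <- comp
  if (align && nrow(ref) >= 2 && nrow(comp) >= 2) {
    pre <- match_rois(ref, comp, max_dist = Inf)
    if (nrow(pre$matches) >= 2) {
      ka <- kabsch_align(ref[pre$matches$ref_idx, c("x", "y")],
                         comp[pre$matches$comp_idx, c("x", "y")])
      al <- cbind(comp$x, comp$y)
      al <- t(ka$rotation %*% t(al)) + matrix(ka$translation, nrow(al), 2,
                                              byrow = TRUE)
      comp_use$x <- al[, 1]; comp_use$y <- al[, 2]
      alignment <- ka[c("rotation", "translation", "angle_deg", "rmsd")]
    }
  }
  m <- match_rois(ref, comp_use, max_dist = max_dist)
  matches <- m$matches |>
    dplyr::mutate(
      d_err = .data$distance,
      s_err = area_error(ref$area[.data$ref_idx], comp$area[.data$comp_idx]),
      ref_label = if ("label" %in% names(ref)) ref$label[.data$ref_idx] else NA_character_
    )
  summary <- tibble::tibble(
    n_matched = nrow(matches), fp = m$fp, fn = m$fn,
    d_err_mean = mean(matches$d_err), d_err_sd = stats::sd(matches$d_err),
    s_err_mean = mean(matches$s_err), s_err_sd = stats::sd(matches$s_err)
  )
  structure(
    list(matches = matches, fp = m$fp, fn = m$fn, summary = summary,
         alignment = alignment),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  cat(sprintf("  matched: %d   FP: %d   FN: %d   (FP+FN: %d)\n",
              nrow(x$matches), x$fp, x$fn, x$fp + x$fn))
  cat(sprintf("  D_err: %.2f +/- %.2f px\n",
              x$summary$d_err_mean, x$summary$d_err_sd))
  cat(sprintf("  S_err: %.2f +/- %.2f %%\n",
              x$summary$s_err_mean, x$summary$s_err_sd))
  if (!is.null(x$alignment)) {
    cat(sprintf("  frame: rotation %.3f deg, RMSD %.3f px\n",
                x$alignment$angle_deg, x$alignment$rmsd))
  }
  invisible(x)
}

#' @rdname evaluate_accuracy
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) x$matches

#' @rdname evaluate_accuracy
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) x$summary
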