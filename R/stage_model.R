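#' Construct a stage model
#'
#' The mechanical model of a motorized microscope stage as seen by the
#' camera: the nominal tile overlap per direction, the camera angle between
#' stage and camera axes, the stage repeatability `r` (positional uncertainty
#' when revisiting a commanded position, which bounds the error of any
#' pairwise translation to +/-2r per axis), and the actuator backlash
#' tolerance used to decide whether an estimated overlap is trustworthy.
#'
#' @param overlap_h,overlap_v Percent overlap in `(0, 100)` for horizontal
#'   (west-east) and vertical (north-south) pairs.
#' @param alpha Camera angle in degrees.
#' @param r Stage repeatability in px (scalar, `>= 1`).
#' @param backlash_tol Overlap-error tolerance in percentage points
#'   (default 3).
#' @param h_valid,v_valid Whether each direction's estimate is trusted.
#' @param r_x,r_y Optional per-axis repeatability diagnostics.
#' @param estimated Named logical vector marking which fields were estimated
#'   (vs user-supplied).
#' @return An object of class `stage_model`.
#' @export
stage_model <- function(overlap_h, overlap_v, alpha = 0, r = 1,
                        backlash_tol = 3, h_valid = TRUE, v_valid = TRUE,
                        r_x = r, r_y = r,
                        estimated = c(overlap = FALSE, alpha = FALSE, r = FALSE)) {
  stopifnot(r >= 1, backlash_tol > 0,
            overlap_h > 0, overlap_h < 100, overlap_v > 0, overlap_v < 100)
  structure(
    list(overlap_h = overlap_h, overlap_v = overlap_v, alpha = alpha,
         r = r, backlash_tol = backlash_tol,
         h_valid = isTRUE(h_valid), v_valid = isTRUE(v_valid),
         r_x = r_x, r_y = r_y, estimated = estimated),
    class = "stage_model"
  )
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf(
    "<stage_model> overlap H/V: %.2f%%/%.2f%%  alpha: %.3f deg  r: %g px  backlash tol: %g%%\n",
    x$overlap_h, x$overlap_v, x$alpha, x$r, x$backlash_tol))
  cat(sprintf("  trusted: H=%s V=%s\n", x$h_valid, x$v_valid))
  invisible(x)
}

#' @rdname stage_model
#' @param x A `stage_model`.
#' @param ... Unused.
#' @method tidy stage_model
#' @export
tidy.stage_model <- function(x, ...) {
  tibble::tibble(
    parameter = c("overlap_h", "overlap_v", "alpha", "r", "backlash_tol"),
    value = c(x$overlap_h, x$overlap_v, x$alpha, x$r, x$backlash_tol),
    unit = c("percent", "percent", "degree", "px", "percent"),
    estimated = c(rep(unname(x$estimated["overlap"]), 2),
                  unname(x$estimated["alpha"]), unname(x$estimated["r"]), FALSE)
  )
}

#' @rdname stage_model
#' @method glance stage_model
#' @export
glance.stage_model <- function(x, ...) {
  tibble::tibble(overlap_h = x$overlap_h, overlap_v = x$overlap_v,
                 alpha = x$alpha, r = x$r, backlash_tol = x$backlash_tol,
                 h_valid = x$h_valid, v_valid = x$v_valid)
}

#' Mark plausible translation-table entries
#'
#' An entry is usable for stage-parameter estimation when its ncc is valid
#' and at least `ncc_min`, and its primary displacement (dx for H pairs, dy
#' for V pairs) lies in the physically plausible band
#' `[0.25 * tile extent, tile extent)`: any genuine adjacent pair overlaps
#' by less than three quarters of a tile, and a band edge well below the
#' nominal step avoids rejecting legitimately jittered entries even at 50
#' percent overlap, where the step is half the tile. A direction with no
#' surviving entry is untrusted.
#'
#' @param translations Table from [compute_translations()] (any subset).
#' @param grid A [tile_grid()] (for the tile extents).
#' @param ncc_min Minimum ncc to trust an entry (default 0.5).
#' @return The table with a logical `plausible` column.
#' @export
select_valid <- function(translations, grid, ncc_min = 0.5) {
  extent <- ifelse(translations$direction == "H", grid$tile_w, grid$tile_h)
  primary <- ifelse(translations$direction == "H", translations$dx, translations$dy)
  translations$plausible <- !is.na(translations$ncc) &
    translations$ncc >= ncc_min &
    !is.na(primary) & primary >= 0.25 * extent & primary < extent
  translations
}

#' Estimate overlap percent from selected entries
#'
#' `overlap = 100 * (1 - median(primary displacement) / tile extent)`,
#' clamped to (0, 100).
#'
#' @param primary Numeric vector of primary displacements (dx for H, dy
#'   for V) of the selected entries.
#' @param tile_extent Tile width (H) or height (V) in px.
#' @return Percent overlap, or `NA` when no entries were given.
#' @export
estimate_overlap <- function(primary, tile_extent) {
  if (length(primary) == 0) return(NA_real_)
  ov <- 100 * (1 - stats::median(primary) / tile_extent)
  min(max(ov, 1e-9), 100 - 1e-9)
}

#' Estimate the camera angle from selected entries
#'
#' The camera observes a horizontal stage step H as `(H cos a, -H sin a)`
#' and a vertical step V as `(V sin a, V cos a)`, so each H pair contributes
#' the angle `atan2(-dy, dx)` and each V pair `atan2(dx, dy)`. The estimate
#' is the pooled median, in degrees.
#'
#' @param h_dx,h_dy Displacements of the selected H entries.
#' @param v_dx,v_dy Displacements of the selected V entries.
#' @return Camera angle in degrees, or `NA` when no entries were given.
#' @export
estimate_camera_angle <- function(h_dx, h_dy, v_dx = double(), v_dy = double()) {
  ang <- c(atan2(-h_dy, h_dx), atan2(v_dx, v_dy))
  if (length(ang) == 0) return(NA_real_)
  stats::median(ang) * 180 / pi
}

#' Estimate stage repeatability from selected entries
#'
#' For each direction and each axis, the spread of selected displacements is
#' summarized as half the central 95 percent span (2.5 to 97.5 percentile);
#' `r` is the ceiling of the largest of the four spreads, floored at 1 px.
#' Per-axis maxima are returned as diagnostics.
#'
#' @param h_dx,h_dy,v_dx,v_dy Displacements of the selected entries per
#'   direction (any may be empty).
#' @return A list with `r`, `r_x`, `r_y`.
#' @export
estimate_repeatability <- function(h_dx = double(), h_dy = double(),
                                   v_dx = double(), v_dy = double()) {
  half_span <- function(v) {
    if (length(v) < 2) return(0)
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    (q[2] - q[1]) / 2
  }
  r_x <- max(half_span(h_dx), half_span(v_dx))
  r_y <- max(half_span(h_dy), half_span(v_dy))
  list(r = max(1, ceiling(max(r_x, r_y))), r_x = r_x, r_y = r_y)
}

#' Build a stage model from translation tables
#'
#' Estimates overlap, camera angle and repeatability from the plausible
#' entries of the translation table (see [select_valid()]). Any parameter
#' supplied by the user is copied verbatim and not estimated. If the
#' estimated overlap of a trusted direction deviates from a user-declared
#' nominal overlap by more than `backlash_tol` percentage points, that
#' estimate is deemed unreliable (actuator backlash beyond tolerance): the
#' nominal value is used instead and `r` is widened to
#' `backlash_tol * tile extent / 100` so the optimizer can still reach the
#' true offsets.
#'
#' @param translations Table from [compute_translations()].
#' @param grid A [tile_grid()].
#' @param overlap,alpha,r Optional user-supplied values (percent, degrees,
#'   px); when given they bypass estimation.
#' @param backlash_tol Overlap-error tolerance in percentage points
#'   (default 3).
#' @param ncc_min Minimum ncc to trust an entry (default 0.5).
#' @return A [stage_model()].
#' @export
build_stage_model <- function(translations, grid, overlap = NULL, alpha = NULL,
                              r = NULL, backlash_tol = 3, ncc_min = 0.5) {
  user_all <- !is.null(overlap) && !is.null(alpha) && !is.null(r)
  if (user_all) {
    return(stage_model(
      overlap_h = overlap, overlap_v = overlap, alpha = alpha, r = max(1, r),
      backlash_tol = backlash_tol,
      estimated = c(overlap = FALSE, alpha = FALSE, r = FALSE)
    ))
  }
  sel <- select_valid(translations, grid, ncc_min = ncc_min)
  hs <- sel[sel$direction == "H" & sel$plausible, ]
  vs <- sel[sel$direction == "V" & sel$plausible, ]
  h_valid <- nrow(hs) > 0
  v_valid <- nrow(vs) > 0
  if (!h_valid && !v_valid && is.null(overlap)) {
    stop("cannot model stage: no trusted translations and no user parameters")
  }

  if (is.null(overlap)) {
    overlap_h <- if (h_valid) estimate_overlap(hs$dx, grid$tile_w) else NA_real_
    overlap_v <- if (v_valid) estimate_overlap(vs$dy, grid$tile_h) else NA_real_
    # fall back on the other direction when one is untrusted
    if (is.na(overlap_h)) overlap_h <- overlap_v
    if (is.na(overlap_v)) overlap_v <- overlap_h
    ov_est <- TRUE
  } else {
    overlap_h <- overlap_v <- overlap
    ov_est <- FALSE
  }

  if (is.null(alpha)) {
    alpha_v <- if (h_valid || v_valid) {
      estimate_camera_angle(hs$dx, hs$dy, vs$dx, vs$dy)
    } else 0
    a_est <- TRUE
  } else {
    alpha_v <- alpha
    a_est <- FALSE
  }

  if (is.null(r)) {
    rep_est <- estimate_repeatability(hs$dx, hs$dy, vs$dx, vs$dy)
    r_v <- rep_est$r; r_x <- rep_est$r_x; r_y <- rep_est$r_y
    r_est <- TRUE
  } else {
    r_v <- max(1, r); r_x <- r_v; r_y <- r_v
    r_est <- FALSE
  }

  # backlash plausibility: when the user declared a nominal overlap, the
  # estimate from the tables must agree within backlash_tol percentage
  # points; beyond that the estimate is deemed unreliable, the nominal value
  # is kept and r is widened so the optimizer can still reach true offsets
  if (!is.null(overlap) && (h_valid || v_valid)) {
    est_h <- if (h_valid) estimate_overlap(hs$dx, grid$tile_w) else overlap
    est_v <- if (v_valid) estimate_overlap(vs$dy, grid$tile_h) else overlap
    if (max(abs(est_h - overlap), abs(est_v - overlap)) > backlash_tol) {
      r_v <- max(r_v, ceiling(backlash_tol * max(grid$tile_w, grid$tile_h) / 100))
    }
  }

  stage_model(
    overlap_h = overlap_h, overlap_v = overlap_v, alpha = alpha_v, r = r_v,
    backlash_tol = backlash_tol, h_valid = h_valid, v_valid = v_valid,
    r_x = r_x, r_y = r_y,
    estimated = c(overlap = ov_est, alpha = a_est, r = r_est)
  )
}

#' Nominal displacement of a pair direction under a stage model
#'
#' The model's expected `(dx, dy)` for an H or V pair: the nominal stage step
#' (tile extent minus overlap) observed through the camera-angle rotation.
#'
#' @param model A [stage_model()].
#' @param direction `"H"` or `"V"` (vectorized).
#' @param tile_w,tile_h Tile size in px.
#' @return A tibble with columns `dx`, `dy` (doubles, not rounded).
#' @export
nominal_displacement <- function(model, direction, tile_w, tile_h) {
  a <- model$alpha * pi / 180
  h_step <- tile_w * (1 - model$overlap_h / 100)
  v_step <- tile_h * (1 - model$overlap_v / 100)
  tibble::tibble(
    dx = ifelse(direction == "H", h_step * cos(a), v_step * sin(a)),
    dy = ifelse(direction == "H", -h_step * sin(a), v_step * cos(a))
  )
}
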