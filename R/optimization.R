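#' Repair unreliable translations with the median/4r filter
#'
#' Within one column of the H table all pairs share the same stage step, and
#' likewise within one row of the V table, up to the +/-2r repeatability
#' bound. H entries are therefore filtered column-wise and V entries
#' row-wise: any entry whose dx or dy deviates from the line median (over
#' valid entries) by more than `4 * r` is replaced by the line's
#' (median dx, median dy) and marked `repaired` with its ncc invalidated
#' (recomputed later by [optimize_translations()]). Lines with no valid entry
#' take the direction's table-wide median; if no valid entries exist at all,
#' the model's nominal displacements are used. Applying the filter twice
#' gives the same result as applying it once.
#'
#' @param translations Table from [compute_translations()].
#' @param model A [stage_model()].
#' @param grid A [tile_grid()] (for nominal displacements when a direction
#'   has no valid entries).
#' @return The table with repaired entries (`repaired = TRUE`, `ncc = NA`).
#' @export
filter_translations <- function(translations, model, grid) {
  r4 <- 4 * model$r
  med1 <- function(v) if (length(v) == 0) NA_real_ else stats::median(v)
  fix_direction <- function(tbl, line_var, dir) {
    lines <- split(seq_len(nrow(tbl)), tbl[[line_var]])
    # stage 1 per line: grow the rejected set to a fixed point so the filter
    # is idempotent -- deviants are dropped from the median, the median
    # recomputed over the survivors, and deviation re-checked until stable
    survivors <- logical(nrow(tbl))
    line_med <- lapply(lines, function(idx) {
      d <- tbl[idx, ]
      bad <- is.na(d$dx) | is.na(d$dy) | is.na(d$ncc) | d$repaired
      mdx <- NA_integer_; mdy <- NA_integer_
      repeat {
        if (!any(!bad)) { mdx <- NA_integer_; mdy <- NA_integer_; break }
        mdx <- as.integer(round(med1(d$dx[!bad])))
        mdy <- as.integer(round(med1(d$dy[!bad])))
        bad2 <- bad | abs(d$dx - mdx) > r4 | abs(d$dy - mdy) > r4
        if (identical(bad2, bad)) break
        bad <- bad2
      }
      survivors[idx[!bad]] <<- TRUE
      c(mdx, mdy)
    })
    # stage 2: lines with no survivors fall back on the direction-wide
    # median over surviving entries, or the model's nominal displacement
    # when the whole direction failed
    if (any(survivors)) {
      glob <- c(as.integer(round(med1(tbl$dx[survivors]))),
                as.integer(round(med1(tbl$dy[survivors]))))
    } else {
      nom <- nominal_displacement(model, dir, grid$tile_w, grid$tile_h)[1, ]
      glob <- c(as.integer(round(nom$dx)), as.integer(round(nom$dy)))
    }
    for (ln in names(lines)) {
      idx <- lines[[ln]]
      m <- line_med[[ln]]
      if (is.na(m[1])) m <- glob
      rep_idx <- idx[!survivors[idx]]
      tbl$dx[rep_idx] <- m[1]
      tbl$dy[rep_idx] <- m[2]
      tbl$ncc[rep_idx] <- NA_real_
      tbl$repaired[rep_idx] <- TRUE
    }
    tbl
  }
  h <- translations[translations$direction == "H", ]
  v <- translations[translations$direction == "V", ]
  if (nrow(h) > 0) h <- fix_direction(h, "col", "H")
  if (nrow(v) > 0) v <- fix_direction(v, "row", "V")
  dplyr::bind_rows(h, v) |>
    dplyr::arrange(dplyr::desc(.data$direction == "H"), .data$row, .data$col)
}

#' Constrained hill climbing on the ncc surface
#'
#' Greedy steepest ascent over the integer displacement lattice: from
#' `start`, all unvisited 8-connected neighbors are scored with [ncc()]
#' (lazily, memoized) and the best one is taken; the walk never leaves the
#' square window of side `4 * bound_r` centered on the start
#' (`|dx - dx0| <= 2r` and `|dy - dy0| <= 2r`) and stops at a local maximum.
#'
#' @param a,b Tile rasters (same shape).
#' @param start_dx,start_dy Starting displacement (integers).
#' @param bound_r Stage repeatability bound in px (`>= 1`).
#' @param min_overlap_px Passed to [ncc()].
#' @return A one-row tibble `dx`, `dy`, `ncc` (ncc `NA` if no valid score was
#'   found anywhere reachable; dx, dy then equal the start).
#' @export
hill_climb <- function(a, b, start_dx, start_dy, bound_r,
                       min_overlap_px = default_min_overlap(a)) {
  stopifnot(bound_r >= 1)
  lim <- floor(2 * bound_r)
  memo <- new.env(parent = emptyenv())
  score <- function(dx, dy) {
    key <- paste0(dx, ",", dy)
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- ncc(a, b, dx, dy, min_overlap_px)
    memo[[key]] <- s
    s
  }
  cur <- c(start_dx, start_dy)
  cur_s <- score(cur[1], cur[2])
  if (is.na(cur_s)) {
    # start invalid: take the best valid neighbor if any, else give up
    best <- NULL
    for (ddx in -1:1) for (ddy in -1:1) {
      if (ddx == 0 && ddy == 0) next
      s <- score(cur[1] + ddx, cur[2] + ddy)
      if (!is.na(s) && (is.null(best) || s > best$s)) {
        best <- list(p = cur + c(ddx, ddy), s = s)
      }
    }
    if (is.null(best)) {
      return(tibble::tibble(dx = as.integer(start_dx),
                            dy = as.integer(start_dy), ncc = NA_real_))
    }
    cur <- best$p; cur_s <- best$s
  }
  repeat {
    best <- NULL
    for (ddx in -1:1) for (ddy in -1:1) {
      if (ddx == 0 && ddy == 0) next
      nx <- cur[1] + ddx; ny <- cur[2] + ddy
      if (abs(nx - start_dx) > lim || abs(ny - start_dy) > lim) next
      s <- score(nx, ny)
      if (!is.na(s) && s > cur_s && (is.null(best) || s > best$s)) {
        best <- list(p = c(nx, ny), s = s)
      }
    }
    if (is.null(best)) break
    cur <- best$p; cur_s <- best$s
  }
  tibble::tibble(dx = as.integer(cur[1]), dy = as.integer(cur[2]), ncc = cur_s)
}

#' Optimize every translation within the (4r)^2 window
#'
#' Refines each (possibly repaired) translation by [hill_climb()] bounded by
#' the model's repeatability. Repaired entries get their ncc recomputed at
#' the median displacement first, so the ascent property (final ncc never
#' below starting ncc) holds for every entry.
#'
#' @param translations Filtered table (see [filter_translations()]).
#' @param model A [stage_model()].
#' @param grid A [tile_grid()].
#' @param min_overlap_px Passed to [ncc()].
#' @return The table with optimized `dx`, `dy`, `ncc`.
#' @export
optimize_translations <- function(translations, model, grid,
                                  min_overlap_px = NULL) {
  mop <- min_overlap_px %||% default_min_overlap(grid$tiles[[1]])
  out <- purrr::pmap(
    translations[, c("direction", "row", "col", "row2", "col2", "dx", "dy")],
    function(direction, row, col, row2, col2, dx, dy) {
      a <- grid_tile(grid, row, col)
      b <- grid_tile(grid, row2, col2)
      hill_climb(a, b, dx, dy, bound_r = model$r, min_overlap_px = mop)
    })
  out <- dplyr::bind_rows(out)
  translations$dx <- out$dx
  translations$dy <- out$dy
  translations$ncc <- out$ncc
  translations
}
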