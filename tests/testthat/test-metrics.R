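test_that("centroid distance error is the Euclidean distance", {
  expect_equal(centroid_distance_error(c(0, 0), c(3, 4)), 5)
  expect_equal(centroid_distance_error(c(2, 7), c(2, 7)), 0)
  expect_equal(centroid_distance_error(c(1, 1), c(4, 5)), 5)
  # metric properties on random points
  set.seed(8)
  for (k in 1:20) {
    p <- runif(2); q <- runif(2); z <- runif(2)
    expect_equal(centroid_distance_error(p, q), centroid_distance_error(q, p))
    expect_lte(centroid_distance_error(p, z),
               centroid_distance_error(p, q) + centroid_distance_error(q, z) + 1e-12)
  }
})

test_that("area error is the signed percent difference", {
  expect_equal(area_error(100, 110), 10)
  expect_equal(area_error(150, 150), 0)
  expect_equal(area_error(200, 150), -25)
  expect_error(area_error(0, 10), "positive")
})

test_that("kabsch recovers exact rigid transforms", {
  set.seed(14)
  ref <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  th <- 5 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ctr <- colMeans(ref)
  comp <- sweep(sweep(ref, 2, ctr) %*% t(rot), 2, ctr, `+`)
  ka <- kabsch_align(ref, comp)
  expect_equal(abs(ka$angle_deg), 5, tolerance = 1e-9)
  expect_lt(ka$rmsd, 1e-9)
  expect_equal(det(ka$rotation), 1, tolerance = 1e-9)

  # pure translation
  kt <- kabsch_align(ref, sweep(ref, 2, c(-10, 7), `+`))
  expect_equal(kt$rotation, diag(2), tolerance = 1e-9)
  expect_equal(kt$translation, c(10, -7), tolerance = 1e-9)

  expect_error(kabsch_align(ref[1, , drop = FALSE], ref[1, , drop = FALSE]),
               "at least 2")
})

test_that("kabsch RMSD is at or below a fine rotation grid search", {
  set.seed(15)
  ref <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  comp <- ref + matrix(rnorm(20, 0, 0.1), 10)
  ka <- kabsch_align(ref, comp)
  expect_equal(det(ka$rotation), 1, tolerance = 1e-9)
  grid_best <- Inf
  for (deg in seq(-2, 2, by = 0.01)) {
    th <- deg * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rc <- comp %*% t(rot)
    # optimal translation for a fixed rotation is the centroid difference
    tr <- colMeans(ref) - colMeans(rc)
    rmsd <- sqrt(mean(rowSums((sweep(rc, 2, tr, `+`) - ref)^2)))
    grid_best <- min(grid_best, rmsd)
  }
  expect_lte(ka$rmsd, grid_best + 1e-12)
})

test_that("hungarian matching is optimal and applies the distance cutoff", {
  ref <- tibble::tibble(x = c(0, 100), y = c(0, 0), area = 1)
  comp <- tibble::tibble(x = c(98, 1), y = c(0, 0), area = 1)
  m <- match_rois(ref, comp, max_dist = 50)
  # nearest assignment: ref1 <-> comp2, ref2 <-> comp1
  expect_equal(m$matches$comp_idx[m$matches$ref_idx == 1], 2)
  expect_equal(m$matches$comp_idx[m$matches$ref_idx == 2], 1)
  expect_equal(m$fp + m$fn, 0)

  # identical sets: all matched at distance 0
  mi <- match_rois(ref, ref, max_dist = 50)
  expect_equal(nrow(mi$matches), 2)
  expect_equal(max(mi$matches$distance), 0)

  # far-away computed ROI becomes FP and leaves a reference unmatched (FN)
  comp2 <- tibble::tibble(x = c(1, 500), y = c(0, 0), area = 1)
  m2 <- match_rois(ref, comp2, max_dist = 50)
  expect_equal(m2$fp, 1)
  expect_equal(m2$fn, 1)
})

test_that("hungarian total similarity beats 1000 random permutations", {
  set.seed(16)
  for (trial in 1:5) {
    n <- sample(4:8, 1)
    ref <- tibble::tibble(x = runif(n, 0, 100), y = runif(n, 0, 100), area = 1)
    comp <- tibble::tibble(x = runif(n, 0, 100), y = runif(n, 0, 100), area = 1)
    m <- match_rois(ref, comp, max_dist = Inf)
    total <- -sum(m$matches$distance)
    d <- sqrt(outer(ref$x, comp$x, `-`)^2 + outer(ref$y, comp$y, `-`)^2)
    for (k in 1:1000) {
      perm <- sample.int(n)
      expect_lte(-sum(d[cbind(seq_len(n), perm)]), total + 1e-9)
    }
  }
})

test_that("blank pixels are counted inside the covered hull only", {
  g <- tile_grid(replicate(2, matrix(5, 20, 20), simplify = FALSE), 1, 2)
  lay <- tibble::tibble(row = 0L, col = 0:1, x = c(0L, 18L), y = 0L)
  mos <- matrix(5, 20, 38)
  expect_equal(blank_pixel_count(mos, lay, g), 0)
  # a 10x10 hole inside the hull
  mos2 <- mos
  mos2[5:14, 5:14] <- 0
  expect_equal(blank_pixel_count(mos2, lay, g), 100)
  # zeros outside the hull are not blanks
  mos3 <- cbind(mos, matrix(0, 20, 5))
  expect_equal(blank_pixel_count(mos3, lay, g), 0)
  expect_equal(blank_pixel_count(matrix(1, 4, 4)), 0)
})

test_that("evaluate reports zero error for identical sets and removes rigid offsets", {
  set.seed(17)
  ref <- tibble::tibble(label = sprintf("c%d", 1:15),
                        x = runif(15, 0, 500), y = runif(15, 0, 500),
                        area = runif(15, 50, 150))
  r0 <- evaluate_accuracy(ref, ref, max_dist = 170)
  expect_equal(r0$summary$d_err_mean, 0)
  expect_equal(r0$summary$s_err_mean, 0)
  expect_equal(r0$fp + r0$fn, 0)

  # a 1-degree frame rotation (camera angle) is removed by Kabsch alignment
  th <- 1 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p <- as.matrix(ref[, c("x", "y")]) %*% t(rot)
  comp <- ref
  comp$x <- p[, 1] + 40; comp$y <- p[, 2] - 25
  r1 <- evaluate_accuracy(ref, comp, max_dist = 170)
  expect_lt(r1$summary$d_err_mean, 1e-6)
  expect_equal(r1$fp + r1$fn, 0)
  expect_equal(abs(r1$alignment$angle_deg), 1, tolerance = 1e-6)

  # report is invariant to any global rigid transform of the computed set
  th2 <- -2 * pi / 180
  rot2 <- matrix(c(cos(th2), sin(th2), -sin(th2), cos(th2)), 2)
  p2 <- as.matrix(comp[, c("x", "y")]) %*% t(rot2)
  comp2 <- comp
  comp2$x <- p2[, 1] - 13; comp2$y <- p2[, 2] + 8
  r2 <- evaluate_accuracy(ref, comp2, max_dist = 170)
  expect_equal(r1$summary$d_err_mean, r2$summary$d_err_mean, tolerance = 1e-6)
  expect_equal(r1$summary$s_err_mean, r2$summary$s_err_mean, tolerance = 1e-6)
})

test_that("mean distance error under isotropic jitter follows the Rayleigh mean", {
  set.seed(18)
  n <- 400
  sigma <- 5
  ref <- tibble::tibble(label = sprintf("c%d", 1:n),
                        x = runif(n, 0, 5000), y = runif(n, 0, 5000),
                        area = 100)
  comp <- ref
  comp$x <- comp$x + rnorm(n, 0, sigma)
  comp$y <- comp$y + rnorm(n, 0, sigma)
  rep <- evaluate_accuracy(ref, comp, max_dist = 500, align = FALSE)
  rayleigh_mean <- sigma * sqrt(pi / 2)
  expect_lt(abs(rep$summary$d_err_mean - rayleigh_mean) / rayleigh_mean, 0.2)
  expect_equal(rep$fp + rep$fn, 0)
})

test_that("tidy and glance expose the report tables", {
  ref <- tibble::tibble(label = c("a", "b"), x = c(0, 10), y = c(0, 0),
                        area = c(100, 200))
  comp <- tibble::tibble(label = c("a", "b"), x = c(0, 10), y = c(1, 0),
                         area = c(110, 200))
  rep <- evaluate_accuracy(ref, comp, max_dist = 100, align = FALSE)
  expect_equal(nrow(tidy(rep)), 2)
  expect_equal(glance(rep)$n_matched, 2)
  expect_equal(sort(tidy(rep)$s_err), c(0, 10))
})
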