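make_pts <- function(P, width = NULL) {
  df <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3])
  if (!is.null(width)) df$width <- width
  df
}

test_that("collinear points give a path graph; clusters are reported", {
  P <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  g <- build_neighbor_graph(make_pts(P), k = 2)
  expect_equal(igraph::vcount(g), 3)
  comp <- attr(g, "components")
  expect_equal(comp$no, 1)
  # geodesic end-to-end equals 2 (middle point bridges the ends)
  expect_equal(igraph::distances(g)[1, 3], 2)

  P2 <- rbind(P, P + matrix(rep(c(100, 0, 0), 3), 3, byrow = TRUE))
  expect_message(g2 <- build_neighbor_graph(make_pts(P2), k = 2),
                 "2 disconnected components")
  expect_equal(attr(g2, "components")$no, 2)
  expect_error(build_neighbor_graph(make_pts(P[1, , drop = FALSE])), "2 points")
})

test_that("graph geodesics approximate the helix arclength", {
  set.seed(12)
  hx <- curve_helix(10, 15, 2)
  # jitter well below the sample spacing, so hop lengths track arclength
  P <- curve_points(hx, seq(0, 1, length.out = 400)) +
    matrix(stats::rnorm(1200, 0, 0.05), ncol = 3)
  g <- build_neighbor_graph(make_pts(P), k = 8)
  D <- igraph::distances(g)
  expect_equal(max(D), curve_length(hx), tolerance = 0.05)
})

test_that("points on a straight segment yield the exact segment as path", {
  set.seed(3)
  t <- sort(stats::runif(60))
  P <- cbind(0, 0, -5 + 30 * t)  # segment from z = -5 to z = 25
  g <- build_neighbor_graph(make_pts(P, width = 1), k = 4)
  p <- extract_principal_curve(g, make_pts(P, width = 1))
  expect_equal(max(p$arclength), max(P[, 3]) - min(P[, 3]), tolerance = 1e-6)
  # endpoints are the extreme points, ordered extracellular (high Z) first
  expect_equal(p$z[1], max(P[, 3]))
  expect_equal(p$z[nrow(p)], min(P[, 3]))
  expect_true(all(diff(p$arclength) > 0))
})

test_that("permuting the input point order leaves the path unchanged", {
  set.seed(5)
  hx <- curve_helix(8, 12, 1.5)
  P <- curve_points(hx, seq(0, 1, length.out = 300)) +
    matrix(stats::rnorm(900, 0, 0.2), ncol = 3)
  pts <- make_pts(P, width = rep(1, 300))
  g <- build_neighbor_graph(pts, k = 6)
  p1 <- extract_principal_curve(g, pts)
  perm <- sample(300)
  pts2 <- pts[perm, ]
  g2 <- build_neighbor_graph(pts2, k = 6)
  p2 <- extract_principal_curve(g2, pts2)
  same <- isTRUE(all.equal(as.data.frame(p1), as.data.frame(p2),
                           tolerance = 1e-8, check.attributes = FALSE))
  rev2 <- as.data.frame(p2)[nrow(p2):1, ]
  rev2$arclength <- max(p2$arclength) - rev2$arclength
  rownames(rev2) <- NULL
  same_rev <- isTRUE(all.equal(as.data.frame(p1), rev2, tolerance = 1e-8,
                               check.attributes = FALSE))
  expect_true(same || same_rev)
})

test_that("helix point clouds are recovered within tight distance bounds", {
  set.seed(9)
  hx <- curve_helix(10, 15, 2)
  P <- curve_points(hx, seq(0, 1, length.out = 1200)) +
    matrix(stats::rnorm(3600, 0, 0.3), ncol = 3)
  pts <- make_pts(P, width = rep(1, 1200))
  g <- build_neighbor_graph(pts, k = 8)
  p <- extract_principal_curve(g, pts)
  d <- curve_distance(hx, as.matrix(p[, c("x", "y", "z")]))
  expect_lt(mean(d), 0.5)
  expect_equal(max(p$arclength), curve_length(hx), tolerance = 0.05)
  # smoothing never lengthens the curve beyond the endpoint geodesic
  D <- igraph::distances(g)
  expect_lte(max(p$arclength), max(D) * 1.001)
  # no sharp turns after smoothing
  V <- diff(as.matrix(p[, c("x", "y", "z")]))
  cosang <- rowSums(V[-1, ] * V[-nrow(V), ]) /
    (sqrt(rowSums(V[-1, ]^2)) * sqrt(rowSums(V[-nrow(V), ]^2)))
  expect_true(all(cosang > 0))
})

test_that("the isomap backend agrees with geodesic ordering on tube clouds", {
  set.seed(14)
  seg <- curve_segment(c(0, 0, 0), c(4, 3, 20))
  P <- curve_points(seg, seq(0, 1, length.out = 250)) +
    matrix(stats::rnorm(750, 0, 0.25), ncol = 3)
  pts <- make_pts(P, width = rep(1, 250))
  g <- build_neighbor_graph(pts, k = 6)
  p1 <- extract_principal_curve(g, pts, backend = "geodesic")
  p2 <- extract_principal_curve(g, pts, backend = "isomap")
  # orderings agree up to direction reversal (local swaps of nearly
  # coincident points aside), so the two curves trace the same geometry
  expect_equal(nrow(p1), nrow(p2))
  r <- stats::cor(p1$z, p2$z, method = "spearman")
  expect_gt(abs(r), 0.999)
  d <- min(mean(abs(p1$z - p2$z)), mean(abs(p1$z - rev(p2$z))))
  expect_lt(d, 0.2)
})

test_that("degenerate ridge sets are rejected", {
  P <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  g <- build_neighbor_graph(make_pts(P), k = 2)
  expect_error(extract_principal_curve(g, make_pts(P)), "fewer than 4")
})

test_that("width profiles average per arclength bin and omit empty bins", {
  p <- structure(data.frame(arclength = seq(0, 9.5, by = 0.5),
                            x = 0, y = 0, z = seq(0, 9.5, by = 0.5),
                            width = 2),
                 class = c("permeation_path", "data.frame"))
  wp <- path_width_profile(p, 1)
  expect_true(all(wp$mean_width == 2))
  expect_equal(nrow(wp), 10)

  # widths linear in arclength: bin means match bin-center line values
  p$width <- 1 + 0.3 * p$arclength
  wp <- path_width_profile(p, 2)
  line_at_mid <- 1 + 0.3 * wp$s_mid
  expect_true(all(abs(wp$mean_width - line_at_mid) <= 0.3 * 2 / 2 + 1e-9))

  # a gap in arclength leaves its bin absent, not zero
  p2 <- p[p$arclength < 3 | p$arclength > 6, ]
  wp2 <- path_width_profile(p2, 1)
  expect_false(any(wp2$s_lo %in% c(4, 5)))
  expect_error(path_width_profile(p, 0), "bin")
})

vertical_path <- function(z_top = 25, z_bot = 0, w = 1.8, x0 = 1, y0 = -2) {
  z <- seq(z_top, z_bot, by = -0.25)
  structure(data.frame(arclength = z_top - z, x = x0, y = y0, z = z,
                       width = w),
            class = c("permeation_path", "data.frame"))
}

test_that("umbrella windows tile the stated Z ranges with width-based radii", {
  p <- vertical_path()
  w <- make_umbrella_windows(p, z_hi = 17.5, z_lo = 5.5, spacing = 1,
                             ext_hi = 22.5, ext_lo = 18.5)
  expect_equal(sum(w$kind == "main"), 13)
  expect_equal(sum(w$kind == "extension"), 5)
  expect_equal(w$center_z, seq(22.5, 5.5, by = -1)[c(1:5, 6:18)])
  # constant path width: every restraint radius equals it
  expect_true(all(abs(w$radius - 1.8) < 1e-9))
  # straight vertical path: all centers on (x0, y0)
  expect_equal(w$x, rep(1, nrow(w)), tolerance = 1e-9)
  expect_equal(w$y, rep(-2, nrow(w)), tolerance = 1e-9)
  # centers evenly spaced in Z
  expect_equal(unique(round(diff(w$center_z), 9)), -1)
})

test_that("window construction rejects paths that do not cover the range", {
  p <- vertical_path(z_top = 15)
  expect_error(make_umbrella_windows(p, 17.5, 5.5, 1, NULL, NULL),
               "does not span")
  zig <- vertical_path()
  zig$z[50] <- zig$z[48]  # non-monotonic wiggle inside the window range
  expect_error(make_umbrella_windows(zig, 17.5, 5.5, 1, NULL, NULL),
               "not monotonic")
  expect_error(make_umbrella_windows(vertical_path(), 5, 10, 1, NULL, NULL),
               "z_hi")
})

test_that("window Z centers relate affinely to path arclength on a near-vertical path", {
  # gently waving path, so the relation is near- but not exactly affine
  z <- seq(25, 0, by = -0.25)
  x <- 0.4 * sin(z / 4)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(z)^2)))
  p <- structure(data.frame(arclength = s, x = x, y = 0, z = z, width = 1),
                 class = c("permeation_path", "data.frame"))
  w <- make_umbrella_windows(p, 17.5, 5.5, 1, NULL, NULL)
  s_at <- stats::approx(p$z, p$arclength, xout = w$center_z)$y
  fit <- stats::lm(s_at ~ w$center_z)
  expect_gt(summary(fit)$r.squared, 0.999)
})
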