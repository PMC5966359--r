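#' Parametric 3D curves
#'
#' Constructors for the analytic curves used as ground truth throughout the
#' package: straight segments, circular helices and polylines. All curves are
#' parameterized by arclength fraction `t` in `[0, 1]`, so `curve_points(c, 0)`
#' and `curve_points(c, 1)` return the two endpoints and equal increments of
#' `t` correspond to equal increments of arclength.
#'
#' @param from,to numeric 3-vectors, segment endpoints in Angstrom.
#' @return an object of class `parametric_curve` with fields `kind`,
#'   `params` and `length` (total arclength in Angstrom).
#' @examples
#' seg <- curve_segment(c(0, 0, 0), c(0, 0, 10))
#' curve_length(seg)
#' @export
curve_segment <- function(from, to) {
  from <- as.numeric(from); to <- as.numeric(to)
  stopifnot(length(from) == 3, length(to) == 3)
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) stop("segment endpoints must be distinct")
  structure(list(kind = "segment", params = list(from = from, to = to),
                 length = len),
            class = "parametric_curve")
}

#' @rdname curve_segment
#' @param radius helix radius in Angstrom.
#' @param pitch rise per full turn in Angstrom.
#' @param turns number of turns (may be fractional).
#' @param center 3-vector, position of the helix axis at `t = 0`.
#' @param axis 3-vector, direction of the helix axis (default +z).
#' @param phase starting angle in radians.
#' @export
curve_helix <- function(radius, pitch, turns, center = c(0, 0, 0),
                        axis = c(0, 0, 1), phase = 0) {
  stopifnot(radius > 0, turns > 0, pitch >= 0)
  axis <- as.numeric(axis) / sqrt(sum(axis^2))
  len <- turns * sqrt((2 * pi * radius)^2 + pitch^2)
  structure(list(kind = "helix",
                 params = list(radius = radius, pitch = pitch, turns = turns,
                               center = as.numeric(center), axis = axis,
                               phase = phase),
                 length = len),
            class = "parametric_curve")
}

#' @rdname curve_segment
#' @param vertices numeric matrix with 3 columns, polyline vertices in order.
#' @export
curve_polyline <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, nrow(vertices) >= 2)
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len <= 0)) stop("polyline has zero-length segments")
  structure(list(kind = "polyline",
                 params = list(vertices = vertices, seg_len = seg_len),
                 length = sum(seg_len)),
            class = "parametric_curve")
}

# rotation taking +z onto a unit vector (Rodrigues)
.rot_z_to <- function(axis) {
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c_ <- sum(z * axis)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # flip about x for antiparallel axis
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Evaluate points on a parametric curve
#'
#' @param curve a `parametric_curve`.
#' @param t numeric vector of arclength fractions in `[0, 1]`.
#' @return numeric matrix `length(t) x 3` of positions in Angstrom.
#' @export
curve_points <- function(curve, t) {
  stopifnot(inherits(curve, "parametric_curve"))
  t <- as.numeric(t)
  p <- curve$params
  switch(curve$kind,
    segment = {
      outer(1 - t, p$from) + outer(t, p$to)
    },
    helix = {
      theta <- p$phase + t * p$turns * 2 * pi
      z <- t * p$turns * p$pitch
      local <- cbind(p$radius * cos(theta), p$radius * sin(theta), z)
      R <- .rot_z_to(p$axis)
      sweep(local %*% t(R), 2, p$center, "+")
    },
    polyline = {
      cl <- c(0, cumsum(p$seg_len))
      s <- t * curve$length
      idx <- pmin(findInterval(s, cl, rightmost.closed = TRUE), length(p$seg_len))
      frac <- (s - cl[idx]) / p$seg_len[idx]
      p$vertices[idx, , drop = FALSE] +
        (p$vertices[idx + 1, , drop = FALSE] - p$vertices[idx, , drop = FALSE]) * frac
    },
    stop("unknown curve kind"))
}

#' Unit tangent vectors along a curve
#'
#' @inheritParams curve_points
#' @return numeric matrix `length(t) x 3` of unit tangents.
#' @export
curve_tangent <- function(curve, t) {
  stopifnot(inherits(curve, "parametric_curve"))
  p <- curve$params
  switch(curve$kind,
    segment = {
      d <- (p$to - p$from) / curve$length
      matrix(d, nrow = length(t), ncol = 3, byrow = TRUE)
    },
    helix = {
      theta <- p$phase + t * p$turns * 2 * pi
      # d/ds of (r cos, r sin, z): tangent in local frame
      dtheta_ds <- 2 * pi * p$turns / curve$length
      dz_ds <- p$turns * p$pitch / curve$length
      local <- cbind(-p$radius * sin(theta) * dtheta_ds,
                     p$radius * cos(theta) * dtheta_ds,
                     rep(dz_ds, length(theta)))
      local <- local / sqrt(rowSums(local^2))
      local %*% t(.rot_z_to(p$axis))
    },
    polyline = {
      cl <- c(0, cumsum(p$seg_len))
      s <- t * curve$length
      idx <- pmin(findInterval(s, cl, rightmost.closed = TRUE), length(p$seg_len))
      seg <- diff(p$vertices)[idx, , drop = FALSE]
      seg / sqrt(rowSums(seg^2))
    },
    stop("unknown curve kind"))
}

#' Total arclength of a curve
#' @inheritParams curve_points
#' @return arclength in Angstrom.
#' @export
curve_length <- function(curve) {
  stopifnot(inherits(curve, "parametric_curve"))
  curve$length
}

#' Distance from points to a curve
#'
#' Minimum Euclidean distance from each query point to a dense discretization
#' of the curve; accurate to roughly `curve_length(curve) / n_eval`.
#'
#' @param curve a `parametric_curve`.
#' @param points numeric matrix `m x 3`.
#' @param n_eval number of curve evaluation points.
#' @return numeric vector of length `m`.
#' @export
curve_distance <- function(curve, points, n_eval = 4000) {
  points <- as.matrix(points)
  cp <- curve_points(curve, seq(0, 1, length.out = n_eval))
  dmin <- rep(Inf, nrow(points))
  # running minimum over curve samples keeps memory O(m)
  for (j in seq_len(n_eval)) {
    d <- (points[, 1] - cp[j, 1])^2 + (points[, 2] - cp[j, 2])^2 +
      (points[, 3] - cp[j, 3])^2
    dmin <- pmin(dmin, d)
  }
  sqrt(dmin)
}

#' @export
print.parametric_curve <- function(x, ...) {
  cat(sprintf("parametric_curve: %s, arclength %.3f A\n", x$kind, x$length))
  invisible(x)
}
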