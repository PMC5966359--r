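# Separable Gaussian and Gaussian-derivative filtering on 3D grids.
#
# Kernels are sampled Gaussian derivatives applied as banded kernel matrices,
# one matrix multiplication per axis. Rows are renormalized so that the
# discrete operators respond exactly like their continuous counterparts on
# low-order polynomials: order 0 rows sum to 1 (constants preserved, also at
# clipped boundary rows), order 1 kernels are zero-sum with unit first
# moment (exact on linear ramps), order 2 kernels are zero-sum with second
# moment 2 (exact second derivative of x^2).

.gauss_kernel_radius <- function(sigma_vox) max(3L, as.integer(ceiling(4 * sigma_vox)))

# 1D correlation weights w(o): out[i] = sum_o w(o) * in[i + o]
.gauss_kernel_1d <- function(sigma_vox, order) {
  R <- .gauss_kernel_radius(sigma_vox)
  o <- seq(-R, R)
  g <- exp(-o^2 / (2 * sigma_vox^2))
  w <- switch(as.character(order),
    "0" = g / sum(g),
    "1" = {
      w <- o / sigma_vox^2 * g            # = -g'(o), correlation form
      w / sum(o * w)                      # exact on ramps
    },
    "2" = {
      w <- (o^2 - sigma_vox^2) / sigma_vox^4 * g
      w <- w - mean(w)                    # zero response to constants
      w * 2 / sum(o^2 * w)                # exact on quadratics
    },
    stop("unsupported derivative order"))
  list(w = w, R = R, offsets = o)
}

# n x n banded kernel matrix; boundary rows are renormalized over their
# clipped support (sum 1 for order 0, sum 0 for orders 1 and 2)
.gauss_kernel_matrix <- function(n, sigma_vox, order) {
  k <- .gauss_kernel_1d(sigma_vox, order)
  K <- matrix(0, n, n)
  for (m in seq_along(k$offsets)) {
    o <- k$offsets[m]
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k$w[m]
  }
  if (order == 0) {
    K <- K / rowSums(K)
  } else {
    supp <- abs(row(K) - col(K)) <= k$R
    K <- K - supp * (rowSums(K) / rowSums(supp))
  }
  K
}

# apply kernel matrix along one axis of a 3D array
.apply_axis <- function(A, K, axis) {
  d <- dim(A)
  if (axis == 1) {
    array(K %*% matrix(A, d[1]), dim = d)
  } else if (axis == 2) {
    B <- aperm(A, c(2, 1, 3))
    B <- array(K %*% matrix(B, d[2]), dim = d[c(2, 1, 3)])
    aperm(B, c(2, 1, 3))
  } else {
    B <- aperm(A, c(3, 1, 2))
    B <- array(K %*% matrix(B, d[3]), dim = d[c(3, 1, 2)])
    aperm(B, c(2, 3, 1))
  }
}

# kernel matrices for one sigma: [[axis]][[order + 1]]
.gauss_kernel_matrixes <- function(dims, sigma_vox, order = 0:2) {
  lapply(1:3, function(ax) {
    lapply(order, function(od) .gauss_kernel_matrix(dims[ax], sigma_vox, od))
  })
}

# separable filter with per-axis derivative orders; kernels as built above,
# result scaled to physical units by voxel^(total order)
.sep_deriv <- function(A, kmats, orders, voxel) {
  for (ax in 1:3) A <- .apply_axis(A, kmats[[ax]][[orders[ax] + 1]], ax)
  A / voxel^sum(orders)
}

# convenience: smooth only (kernels may hold just order 0)
.apply_separable <- function(A, kmats) {
  for (ax in 1:3) A <- .apply_axis(A, kmats[[ax]][[1]], ax)
  A
}

#' Scale-space representation of a density map
#'
#' Computes, at each scale sigma (Angstrom), the Gaussian-smoothed volume and
#' all first and second Gaussian-derivative volumes (3 gradients, 6
#' independent Hessian components). Derivatives are computed with
#' Gaussian-derivative kernels, not finite differences of smoothed data, and
#' are expressed in physical units (per Angstrom, per Angstrom squared).
#'
#' @param map a [density_map()].
#' @param scales strictly increasing vector of Gaussian standard deviations
#'   in Angstrom; each must be at least half a voxel (an undersampled kernel
#'   is rejected).
#' @return a `scale_space` object: list with `map` (grid geometry), `scales`
#'   and per-scale volumes `L` (smoothed), `g` (list x, y, z) and `h` (list
#'   xx, yy, zz, xy, xz, yz).
#' @export
build_scale_space <- function(map, scales = default_ridge_scales()) {
  stopifnot(inherits(map, "density_map"))
  scales <- as.numeric(scales)
  if (length(scales) < 1) stop("need at least one scale")
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be strictly increasing")
  }
  if (any(scales < 0.5 * map$voxel)) {
    stop("scales below half a voxel are undersampled; smallest allowed: ",
         0.5 * map$voxel, " A")
  }
  vols <- lapply(scales, function(s) {
    sv <- s / map$voxel
    km <- .gauss_kernel_matrixes(map$dims, sv)
    list(
      sigma = s,
      L = .sep_deriv(map$values, km, c(0, 0, 0), map$voxel),
      g = list(x = .sep_deriv(map$values, km, c(1, 0, 0), map$voxel),
               y = .sep_deriv(map$values, km, c(0, 1, 0), map$voxel),
               z = .sep_deriv(map$values, km, c(0, 0, 1), map$voxel)),
      h = list(xx = .sep_deriv(map$values, km, c(2, 0, 0), map$voxel),
               yy = .sep_deriv(map$values, km, c(0, 2, 0), map$voxel),
               zz = .sep_deriv(map$values, km, c(0, 0, 2), map$voxel),
               xy = .sep_deriv(map$values, km, c(1, 1, 0), map$voxel),
               xz = .sep_deriv(map$values, km, c(1, 0, 1), map$voxel),
               yz = .sep_deriv(map$values, km, c(0, 1, 1), map$voxel)))
  })
  structure(list(origin = map$origin, voxel = map$voxel, dims = map$dims,
                 scales = scales, vols = vols),
            class = "scale_space")
}

#' Default detection scale grid
#'
#' 12 logarithmically spaced standard deviations from 0.6 to 4.8 Angstrom,
#' bracketing plausible channel-pore tube widths on sub-Angstrom voxel grids.
#' @param n number of scales.
#' @param from,to smallest and largest sigma in Angstrom.
#' @return numeric vector of scales.
#' @export
default_ridge_scales <- function(n = 12, from = 0.6, to = 4.8) {
  exp(seq(log(from), log(to), length.out = n))
}

#' @export
print.scale_space <- function(x, ...) {
  cat(sprintf("scale_space: %d x %d x %d grid, %d scales (%.2f .. %.2f A)\n",
              x$dims[1], x$dims[2], x$dims[3], length(x$scales),
              min(x$scales), max(x$scales)))
  invisible(x)
}

# closed-form eigenvalues of symmetric 3x3 matrices, vectorized; ascending
.eig3_sym <- function(hxx, hyy, hzz, hxy, hxz, hyz) {
  p1 <- hxy^2 + hxz^2 + hyz^2
  q <- (hxx + hyy + hzz) / 3
  p2 <- (hxx - q)^2 + (hyy - q)^2 + (hzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe <- p > 0
  pc <- ifelse(safe, p, 1)
  b11 <- (hxx - q) / pc; b22 <- (hyy - q) / pc; b33 <- (hzz - q) / pc
  b12 <- hxy / pc; b13 <- hxz / pc; b23 <- hyz / pc
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l3 <- q + 2 * p * cos(phi)
  l1 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  list(l1 = ifelse(safe, l1, q), l2 = ifelse(safe, l2, q),
       l3 = ifelse(safe, l3, q))
}

# trilinear interpolation of a 3D array at continuous 1-based voxel indices
.trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
  z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  v <- function(i, j, k) vol[cbind(i, j, k)]
  (1 - fx) * (1 - fy) * (1 - fz) * v(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * v(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * v(x0, y0 + 1, z0) +
    fx * fy * (1 - fz) * v(x0 + 1, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * v(x0, y0, z0 + 1) +
    fx * (1 - fy) * fz * v(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * v(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * v(x0 + 1, y0 + 1, z0 + 1)
}
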