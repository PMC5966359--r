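# Shared fixtures and independent oracle implementations.

# smooth non-negative random field on a cubic grid: heavily blurred white
# noise, shifted positive (input generation for the oracle-equivalence test)
random_smooth_map <- function(n = 16, seed = 1, blur_vox = 2) {
  set.seed(seed)
  v <- array(stats::rnorm(n^3), dim = c(n, n, n))
  # crude separable binomial blur, repeated; independent of package kernels
  blur1 <- function(a, ax) {
    idx <- seq_len(dim(a)[ax])
    lo <- pmax(idx - 1, 1); hi <- pmin(idx + 1, dim(a)[ax])
    pick <- function(i) switch(ax, a[i, , , drop = FALSE],
                               a[, i, , drop = FALSE], a[, , i, drop = FALSE])
    out <- a
    for (i in idx) {
      s <- (pick(lo[i]) + 2 * pick(i) + pick(hi[i])) / 4
      if (ax == 1) out[i, , ] <- s else if (ax == 2) out[, i, ] <- s
      else out[, , i] <- s
    }
    out
  }
  for (r in seq_len(round(blur_vox^2 * 2))) for (ax in 1:3) v <- blur1(v, ax)
  v <- v - min(v) + 0.05
  density_map(v, origin = c(0, 0, 0), voxel = 1)
}

# independent trilinear interpolation (naive eight-corner form)
tri3 <- function(vol, p) {
  d <- dim(vol)
  p <- pmin(pmax(p, 1), d)
  f <- pmin(floor(p), d - 1)
  t <- p - f
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wgt <- (if (cx) t[1] else 1 - t[1]) * (if (cy) t[2] else 1 - t[2]) *
      (if (cz) t[3] else 1 - t[3])
    acc <- acc + wgt * vol[f[1] + cx, f[2] + cy, f[3] + cz]
  }
  acc
}

# exhaustive per-voxel evaluation of the discrete curve-ridge conditions at
# one scale: two negative transverse eigenvalues, anisotropy gate, and
# sign change of the gradient projection across the voxel along each
# transverse eigenvector
oracle_ridge_voxels <- function(ss, scale_idx = 1, aniso = 2) {
  v <- ss$vols[[scale_idx]]
  d <- ss$dims
  R <- ionpath:::.gauss_kernel_radius(ss$scales[scale_idx] / ss$voxel)
  hits <- list()
  for (i in (R + 1):(d[1] - R)) for (j in (R + 1):(d[2] - R)) {
    for (k in (R + 1):(d[3] - R)) {
      H <- matrix(c(v$h$xx[i, j, k], v$h$xy[i, j, k], v$h$xz[i, j, k],
                    v$h$xy[i, j, k], v$h$yy[i, j, k], v$h$yz[i, j, k],
                    v$h$xz[i, j, k], v$h$yz[i, j, k], v$h$zz[i, j, k]), 3, 3)
      ev <- eigen(H, symmetric = TRUE)
      l <- rev(ev$values)  # ascending
      # same degenerate-Hessian floor as the production strength measure
      if (!(l[2] < -ionpath:::.hessian_tol(ss, scale_idx))) next
      if (!(abs(l[2]) >= aniso * abs(l[3]))) next
      e1 <- ev$vectors[, 3]; e2 <- ev$vectors[, 2]
      pr <- function(dirv, s) {
        q <- c(i, j, k) + s * dirv
        tri3(v$g$x, q) * dirv[1] + tri3(v$g$y, q) * dirv[2] +
          tri3(v$g$z, q) * dirv[3]
      }
      if (pr(e1, -1) * pr(e1, 1) > 0) next
      if (pr(e2, -1) * pr(e2, 1) > 0) next
      hits[[length(hits) + 1]] <- c(i, j, k)
    }
  }
  if (length(hits) == 0) return(matrix(integer(), 0, 3))
  do.call(rbind, hits)
}

# independent dwell segmentation over a frame series: scan the boolean
# in-region series and collect maximal contiguous runs
brute_dwell_frames <- function(inreg) {
  runs <- list()
  start <- NA
  for (i in seq_along(inreg)) {
    if (inreg[i] && is.na(start)) start <- i
    if ((!inreg[i] || i == length(inreg)) && !is.na(start)) {
      end <- if (inreg[i]) i else i - 1
      runs[[length(runs) + 1]] <- c(start, end)
      start <- NA
    }
  }
  runs
}

# toy trajectory: one ion with a prescribed z series at dt
one_ion_traj <- function(z, dt = 100, species = "Na", id = "ionA") {
  ion_trajectory(data.frame(frame = seq_along(z),
                            time_ps = (seq_along(z) - 1) * dt,
                            ion_id = id, species = species,
                            x = 0, y = 0, z = z),
                 dt_ps = dt, max_jump = Inf)
}

# one frame, one ion at the origin, carboxylate oxygens at given distances
coord_fixture <- function(dists, resids = 375, resnames = "ASP",
                          eletys = "OD1") {
  pr <- data.frame(frame = 1, resid = resids, resname = resnames,
                   elety = eletys, x = dists, y = 0, z = 0)
  tr <- one_ion_traj(0, dt = 2)
  tr$ions$x <- 0; tr$ions$y <- 0; tr$ions$z <- 0
  tr$protein <- pr
  tr
}

# rotation matrix about a unit axis by angle (radians)
rot_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
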