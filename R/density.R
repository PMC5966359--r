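#' 3D density maps
#'
#' A `density_map` is a regular isotropic 3D grid: a numeric array of
#' non-negative values with an `origin` (Angstrom position of the corner of
#' the first voxel), a `voxel` edge length, and a `normalized` flag. When
#' normalized, `sum(values) * voxel^3 == 1` within 1e-9 relative tolerance.
#'
#' @param values non-negative numeric 3D array.
#' @param origin numeric 3-vector, corner of voxel `[1,1,1]` in Angstrom.
#' @param voxel voxel edge in Angstrom, > 0.
#' @param normalized logical; assert the unit-integral property.
#' @return a `density_map` object.
#' @export
density_map <- function(values, origin = c(0, 0, 0), voxel = 1,
                        normalized = FALSE) {
  stopifnot(is.array(values), length(dim(values)) == 3, voxel > 0)
  if (any(values < 0)) stop("density values must be non-negative")
  if (normalized) {
    s <- sum(values) * voxel^3
    if (abs(s - 1) > 1e-9) stop("normalized map must integrate to 1")
  }
  structure(list(values = values, origin = as.numeric(origin),
                 voxel = voxel, dims = dim(values), normalized = normalized),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d x %d voxels @ %.3g A, origin (%.2f, %.2f, %.2f)%s\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel,
              x$origin[1], x$origin[2], x$origin[3],
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Voxel center coordinates of a map axis
#' @param map a [density_map()].
#' @param axis 1, 2 or 3.
#' @return numeric vector of voxel-center coordinates in Angstrom.
#' @export
map_axis <- function(map, axis) {
  map$origin[axis] + (seq_len(map$dims[axis]) - 0.5) * map$voxel
}

#' Filter trajectory ions by a dwell criterion inside a Z slab
#'
#' Retains the positions of ions during contiguous in-region dwells of
#' duration at least `min_dwell`. An ion is "in region" at a frame when
#' `z_min < Z < z_max` (strict). A dwell is a maximal run of consecutive
#' in-region frames; its duration is `(n_frames - 1) * dt`, so a single-frame
#' visit has duration 0. A one-frame exit breaks a dwell. With
#' `mode = "cumulative"` the per-ion total in-region time is compared to
#' `min_dwell` instead and all in-region frames of qualifying ions are kept.
#'
#' Defaults select ions that stay in the selectivity-filter slab
#' (-5 A < Z < 20 A) for at least 1 ns.
#'
#' @param traj an [ion_trajectory()].
#' @param species species label to select.
#' @param z_min,z_max slab bounds in Angstrom.
#' @param min_dwell minimum dwell duration in ps.
#' @param mode `"contiguous"` (default) or `"cumulative"`.
#' @return an [ion_samples()] set with filter provenance in its metadata.
#' @export
filter_valid_samples <- function(traj, species = "Na", z_min = -5, z_max = 20,
                                 min_dwell = 1000,
                                 mode = c("contiguous", "cumulative")) {
  stopifnot(inherits(traj, "ion_trajectory"))
  mode <- match.arg(mode)
  if (z_min >= z_max) stop("z_min must be < z_max")
  if (min_dwell < 0) stop("min_dwell must be >= 0")
  dt <- traj$dt_ps
  di <- traj$ions[traj$ions$species == species, , drop = FALSE]
  tag <- sprintf("species=%s, %g A < Z < %g A, dwell >= %g ps (%s)",
                 species, z_min, z_max, min_dwell, mode)
  if (nrow(di) == 0) {
    warning("no ions of species '", species, "' in trajectory")
    return(ion_samples(data.frame(ion_id = character(), species = character(),
                                  time_ps = numeric(), x = numeric(),
                                  y = numeric(), z = numeric()),
                       dt_ps = dt, filter = tag))
  }
  keep <- logical(nrow(di))
  for (id in unique(di$ion_id)) {
    sel <- which(di$ion_id == id)
    sel <- sel[order(di$frame[sel])]
    inreg <- di$z[sel] > z_min & di$z[sel] < z_max
    runs <- .contiguous_runs(di$frame[sel], inreg)
    if (mode == "contiguous") {
      for (k in seq_len(nrow(runs))) {
        if ((runs$len[k] - 1) * dt >= min_dwell) {
          keep[sel[runs$start[k]:(runs$start[k] + runs$len[k] - 1)]] <- TRUE
        }
      }
    } else {
      tot <- sum(pmax(runs$len - 1, 0)) * dt
      if (tot >= min_dwell) keep[sel[inreg]] <- TRUE
    }
  }
  ion_samples(di[keep, c("ion_id", "species", "time_ps", "x", "y", "z")],
              dt_ps = dt, filter = tag)
}

#' Build a normalized 3D probability density map from ion samples
#'
#' Histograms the sample positions on an isotropic grid covering all samples
#' plus a margin of at least `3 * smoothing_sigma`, optionally convolves with
#' an isotropic Gaussian of standard deviation `smoothing_sigma`, and
#' normalizes to unit integral. The raw per-voxel sample counts are kept in
#' the `counts` attribute for the raw-count contour variant.
#'
#' @param samples an [ion_samples()] set with at least one sample.
#' @param voxel_size voxel edge in Angstrom (default 0.5).
#' @param smoothing_sigma Gaussian smoothing standard deviation in Angstrom,
#'   >= 0; 0 gives a pure histogram.
#' @return a normalized [density_map()].
#' @export
build_density_map <- function(samples, voxel_size = 0.5, smoothing_sigma = 1.0) {
  if (nrow(samples) == 0) stop("cannot build a density map from 0 samples")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (smoothing_sigma < 0) stop("smoothing_sigma must be >= 0")
  pos <- as.matrix(samples[, c("x", "y", "z")])
  margin <- max(3 * smoothing_sigma, voxel_size) + 2 * voxel_size
  lo <- apply(pos, 2, min) - margin
  dims <- as.integer(ceiling((apply(pos, 2, max) + margin - lo) / voxel_size))
  idx <- floor(sweep(pos, 2, lo) / voxel_size) + 1
  idx <- pmin(pmax(idx, 1), matrix(dims, nrow(idx), 3, byrow = TRUE))
  lin <- (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  vals <- counts
  if (smoothing_sigma > 0) {
    k <- .gauss_kernel_matrixes(dims, smoothing_sigma / voxel_size, order = 0)
    vals <- .apply_separable(vals, k)
  }
  vals[vals < 0] <- 0  # clip convolution round-off
  vals <- vals / (sum(vals) * voxel_size^3)
  out <- density_map(vals, origin = lo, voxel = voxel_size, normalized = TRUE)
  attr(out, "counts") <- counts
  out
}

#' Density level enclosing a probability fraction
#'
#' Returns the highest level `L` such that the superlevel set
#' `{density >= L}` contains at least `fraction` of the total probability
#' mass. Computed by sorting voxel masses in descending order and
#' accumulating, so superlevel sets for increasing fractions are nested, as
#' contour envelopes drawn at decreasing coverage must be. With
#' `weight = "count"` the accumulation runs over raw sample counts (voxels
#' still ranked by density), the alternative reading of "covering X% of the
#' density points".
#'
#' @param map a normalized [density_map()].
#' @param fraction target mass fraction in (0, 1].
#' @param weight `"mass"` (default) or `"count"` (needs the `counts`
#'   attribute written by [build_density_map()]).
#' @return the density level (same units as map values).
#' @export
contour_level_for_fraction <- function(map, fraction,
                                       weight = c("mass", "count")) {
  stopifnot(inherits(map, "density_map"))
  weight <- match.arg(weight)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  if (!map$normalized) stop("map must be normalized")
  v <- as.numeric(map$values)
  ord <- order(v, decreasing = TRUE)
  w <- if (weight == "mass") {
    v * map$voxel^3
  } else {
    cnt <- attr(map, "counts")
    if (is.null(cnt)) stop("map carries no raw counts; rebuild with build_density_map()")
    as.numeric(cnt) / sum(cnt)
  }
  cum <- cumsum(w[ord])
  i <- which(cum >= fraction - 1e-12)[1]
  if (is.na(i)) i <- length(ord)
  v[ord[i]]
}

#' 1D probability distribution of ion Z positions
#'
#' @param samples an [ion_samples()] set.
#' @param bin_width bin width in Angstrom, > 0.
#' @param z_range optional fixed `c(lo, hi)` range (e.g. to compare
#'   distributions of different sample subsets on common bins); defaults to
#'   the data range rounded out to bin multiples.
#' @return a `z_distribution`: data frame with `z_lo`, `z_hi`, `z_mid`,
#'   `prob` (summing to 1) and the species label as an attribute.
#' @export
z_distribution <- function(samples, bin_width = 0.5, z_range = NULL) {
  if (nrow(samples) == 0) stop("need at least one sample")
  if (bin_width <= 0) stop("bin_width must be positive")
  z <- samples$z
  if (is.null(z_range)) z_range <- range(z)
  lo <- floor(z_range[1] / bin_width) * bin_width
  hi <- ceiling(z_range[2] / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  h <- hist(z, breaks = edges, plot = FALSE)
  out <- data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1],
                    z_mid = h$mids, prob = h$counts / sum(h$counts))
  structure(out, species = unique(samples$species),
            class = c("z_distribution", "data.frame"))
}
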