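#' Ion sample sets
#'
#' An `ion_samples` object is a data frame with columns `ion_id`, `species`,
#' `time_ps`, `x`, `y`, `z` (positions in Angstrom) plus metadata attributes:
#' `dt_ps` (frame interval), `filter` (provenance of any validity filter
#' applied) and `frame_note` (coordinate convention; by convention Z = 0 is
#' the protein center of mass and Z is the pore axis).
#'
#' @param df data frame with the columns above.
#' @param dt_ps frame interval in ps.
#' @param filter filter provenance string or NULL if unfiltered.
#' @param frame_note free-text coordinate frame note.
#' @return an `ion_samples` object.
#' @export
ion_samples <- function(df, dt_ps = NA_real_, filter = NULL,
                        frame_note = "Z = 0 at protein center of mass") {
  need <- c("ion_id", "species", "time_ps", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("ion_samples needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  if (any(df$time_ps < 0)) stop("sample times must be non-negative")
  if (!all(is.finite(as.matrix(df[c("x", "y", "z")])))) {
    stop("sample positions must be finite")
  }
  structure(df, dt_ps = dt_ps, filter = filter, frame_note = frame_note,
            class = c("ion_samples", "data.frame"))
}

#' @export
print.ion_samples <- function(x, ...) {
  flt <- attr(x, "filter")
  cat(sprintf("ion_samples: %d positions, %d ions, species {%s}%s\n",
              nrow(x), length(unique(x$ion_id)),
              paste(unique(x$species), collapse = ","),
              if (is.null(flt)) " (unfiltered)" else paste0(" [", flt, "]")))
  invisible(x)
}

# evaluate with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Sample a Gaussian tube cloud around a curve
#'
#' Emulates the positional cloud of ions moving along a channel pathway: `n`
#' points at uniform random arclength positions on `curve`, displaced by an
#' isotropic Gaussian offset of standard deviation `sigma` in the plane
#' orthogonal to the local tangent, plus along-tangent jitter of the same
#' `sigma`. The cloud's true radial (2D) standard deviation therefore equals
#' `sigma`, which is the quantity ridge width estimation must recover.
#'
#' Synthetic frame times are assigned by cycling the samples over `n_frames`
#' frames at interval `dt_ps`; density construction only needs timestamps to
#' exist, not to carry dynamics.
#'
#' @param curve a [curve_segment()], [curve_helix()] or [curve_polyline()].
#' @param sigma transverse standard deviation in Angstrom, > 0.
#' @param n number of points, >= 1.
#' @param seed integer seed; fixed seeds give bit-identical clouds.
#' @param species species label for all points.
#' @param dt_ps synthetic frame interval in ps.
#' @param n_frames number of synthetic frames to cycle over.
#' @return an [ion_samples()] object; the seed used is recorded in the
#'   `seed` attribute.
#' @export
sample_tube_cloud <- function(curve, sigma, n, seed = 1L, species = "Na",
                              dt_ps = 20, n_frames = 1000L) {
  stopifnot(inherits(curve, "parametric_curve"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a positive number")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count")
  }
  n <- as.integer(n)
  .with_seed(seed, {
    t <- stats::runif(n)
    p <- curve_points(curve, t)
    tg <- curve_tangent(curve, t)
    # orthonormal frame (u, v) perpendicular to the tangent
    ref <- ifelse(abs(tg[, 3]) < 0.9, 3L, 1L)
    e <- matrix(0, n, 3); e[cbind(seq_len(n), ref)] <- 1
    u <- cbind(tg[, 2] * e[, 3] - tg[, 3] * e[, 2],
               tg[, 3] * e[, 1] - tg[, 1] * e[, 3],
               tg[, 1] * e[, 2] - tg[, 2] * e[, 1])
    u <- u / sqrt(rowSums(u^2))
    v <- cbind(tg[, 2] * u[, 3] - tg[, 3] * u[, 2],
               tg[, 3] * u[, 1] - tg[, 1] * u[, 3],
               tg[, 1] * u[, 2] - tg[, 2] * u[, 1])
    o1 <- stats::rnorm(n, 0, sigma)
    o2 <- stats::rnorm(n, 0, sigma)
    o3 <- stats::rnorm(n, 0, sigma)
    pos <- p + u * o1 + v * o2 + tg * o3
    out <- ion_samples(data.frame(
      ion_id = sprintf("ion%06d", seq_len(n)),
      species = species,
      time_ps = dt_ps * ((seq_len(n) - 1L) %% as.integer(n_frames)),
      x = pos[, 1], y = pos[, 2], z = pos[, 3]), dt_ps = dt_ps)
    attr(out, "seed") <- as.integer(seed)
    attr(out, "curve_kind") <- curve$kind
    out
  })
}

#' Sample an analytic scalar field onto a regular grid
#'
#' Builds a [density_map()] by evaluating a named analytic field at voxel
#' centers. Available fields:
#' \describe{
#'   \item{constant}{`value` everywhere.}
#'   \item{gaussian_blob}{`exp(-|r - center|^2 / (2 sigma^2))`.}
#'   \item{gaussian_tube}{`exp(-((x-cx)^2+(y-cy)^2) / (2 a^2))`, a straight
#'     tube along z (cross-section standard deviation `a`).}
#'   \item{helix_tube}{`exp(-d^2 / (2 a^2))` with `d` the distance to a helix
#'     given by `radius`, `pitch`, `turns`, `center`.}
#' }
#'
#' @param fn_spec list with element `name` plus the field's parameters.
#' @param bounds 2x3 matrix (rows = min, max) of the box in Angstrom.
#' @param voxel isotropic voxel edge in Angstrom, > 0.
#' @return an unnormalized [density_map()] (all values >= 0).
#' @export
analytic_density_grid <- function(fn_spec, bounds, voxel) {
  stopifnot(is.list(fn_spec), !is.null(fn_spec$name))
  bounds <- as.matrix(bounds)
  if (!is.numeric(voxel) || voxel <= 0) stop("voxel must be positive")
  if (any(bounds[2, ] - bounds[1, ] <= 0)) stop("bounds box is degenerate")
  dims <- pmax(1L, as.integer(round((bounds[2, ] - bounds[1, ]) / voxel)))
  origin <- bounds[1, ]
  ax <- lapply(1:3, function(d) origin[d] + (seq_len(dims[d]) - 0.5) * voxel)
  vals <- switch(fn_spec$name,
    constant = array(fn_spec$value %||% 1, dim = dims),
    gaussian_blob = {
      s <- fn_spec$sigma; ctr <- fn_spec$center %||% colMeans(bounds)
      gx <- exp(-(ax[[1]] - ctr[1])^2 / (2 * s^2))
      gy <- exp(-(ax[[2]] - ctr[2])^2 / (2 * s^2))
      gz <- exp(-(ax[[3]] - ctr[3])^2 / (2 * s^2))
      outer(outer(gx, gy), gz)
    },
    gaussian_tube = {
      a <- fn_spec$a; ctr <- fn_spec$center %||% c(0, 0)
      gx <- exp(-(ax[[1]] - ctr[1])^2 / (2 * a^2))
      gy <- exp(-(ax[[2]] - ctr[2])^2 / (2 * a^2))
      outer(outer(gx, gy), rep(1, dims[3]))
    },
    helix_tube = {
      a <- fn_spec$a
      hx <- curve_helix(fn_spec$radius, fn_spec$pitch, fn_spec$turns,
                        center = fn_spec$center %||% c(0, 0, 0))
      n_eval <- max(200L, as.integer(4 * hx$length / voxel))
      cp <- curve_points(hx, seq(0, 1, length.out = n_eval))
      X <- rep(ax[[1]], times = dims[2] * dims[3])
      Y <- rep(rep(ax[[2]], each = dims[1]), times = dims[3])
      Z <- rep(ax[[3]], each = dims[1] * dims[2])
      d2 <- rep(Inf, length(X))
      for (j in seq_len(n_eval)) {
        d2 <- pmin(d2, (X - cp[j, 1])^2 + (Y - cp[j, 2])^2 + (Z - cp[j, 3])^2)
      }
      array(exp(-d2 / (2 * a^2)), dim = dims)
    },
    stop("unknown analytic field: ", fn_spec$name))
  density_map(vals, origin = origin, voxel = voxel, normalized = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Event scripts for scripted toy trajectories
#'
#' An `event_script` is the ground truth for residence-time and trail tests:
#' per-ion lists of `(enter_ps, exit_ps, region)` intervals at a fixed frame
#' interval `dt_ps`. Intervals per ion must be disjoint, ordered, with
#' `enter < exit`, and all times multiples of `dt_ps`.
#'
#' @param intervals data frame with columns `ion_id`, `species`, `enter_ps`,
#'   `exit_ps`, `region`.
#' @param dt_ps frame interval in ps.
#' @return an `event_script` object.
#' @export
event_script <- function(intervals, dt_ps) {
  need <- c("ion_id", "species", "enter_ps", "exit_ps", "region")
  if (!all(need %in% names(intervals))) {
    stop("event_script needs columns: ", paste(need, collapse = ", "))
  }
  intervals <- as.data.frame(intervals)[need]
  stopifnot(dt_ps > 0)
  if (any(intervals$enter_ps >= intervals$exit_ps)) {
    stop("all intervals must have enter_ps < exit_ps")
  }
  tm <- c(intervals$enter_ps, intervals$exit_ps)
  if (any(abs(tm / dt_ps - round(tm / dt_ps)) > 1e-9)) {
    stop("all interval times must be multiples of dt_ps")
  }
  for (id in unique(intervals$ion_id)) {
    iv <- intervals[intervals$ion_id == id, ]
    iv <- iv[order(iv$enter_ps), ]
    if (nrow(iv) > 1 && any(iv$enter_ps[-1] < iv$exit_ps[-nrow(iv)])) {
      stop("overlapping intervals for ion ", id)
    }
  }
  structure(list(intervals = intervals[order(intervals$ion_id,
                                             intervals$enter_ps), ],
                 dt_ps = dt_ps),
            class = "event_script")
}

#' Expected frame-resolved dwell durations of an event script
#'
#' A scripted interval `[enter, exit)` sampled at frame interval `dt` covers
#' `(exit - enter) / dt` frames, whose first-to-last time span (the dwell
#' duration at frame resolution, `(n_frames - 1) * dt`) is
#' `exit - enter - dt`. This is the exact multiset that
#' [residence_times()] recovers from the scripted trajectory.
#'
#' @param script an [event_script()].
#' @param region region label to restrict to (default: all).
#' @return numeric vector of durations in ps.
#' @export
script_dwell_durations <- function(script, region = NULL) {
  stopifnot(inherits(script, "event_script"))
  iv <- script$intervals
  if (!is.null(region)) iv <- iv[iv$region == region, ]
  iv$exit_ps - iv$enter_ps - script$dt_ps
}

#' Build a toy trajectory from an event script
#'
#' Places each ion at a region-specific "inside" Z coordinate during its
#' scripted intervals (frames with `enter <= t < exit`) and at an "outside"
#' Z otherwise, so the scripted intervals are the exact ground truth for
#' dwell segmentation.
#'
#' @param script an [event_script()].
#' @param geometry list mapping each region label to
#'   `list(inside = c(x, y, z), outside = c(x, y, z))`; a single default
#'   mapping is used for regions not named.
#' @param t_end last frame time in ps (default: max scripted exit time).
#' @return an [ion_trajectory()] object.
#' @export
scripted_trajectory <- function(script, geometry = NULL, t_end = NULL) {
  stopifnot(inherits(script, "event_script"))
  dt <- script$dt_ps
  iv <- script$intervals
  if (is.null(t_end)) t_end <- if (nrow(iv)) max(iv$exit_ps) else 0
  times <- seq(0, t_end, by = dt)
  default_geom <- list(inside = c(0, 0, 0), outside = c(0, 0, 40))
  ions <- unique(iv[c("ion_id", "species")])
  if (nrow(ions) == 0) {
    return(ion_trajectory(
      ions = data.frame(frame = integer(), time_ps = numeric(),
                        ion_id = character(), species = character(),
                        x = numeric(), y = numeric(), z = numeric()),
      dt_ps = dt))
  }
  geom_for <- function(region) {
    if (!is.null(geometry) && !is.null(geometry[[region]])) geometry[[region]]
    else default_geom
  }
  recs <- lapply(seq_len(nrow(ions)), function(i) {
    id <- ions$ion_id[i]
    my <- iv[iv$ion_id == id, ]
    # rest position: the "outside" of the ion's first region's geometry
    pos <- matrix(geom_for(my$region[1])$outside, nrow = length(times),
                  ncol = 3, byrow = TRUE)
    for (j in seq_len(nrow(my))) {
      inside <- times >= my$enter_ps[j] & times < my$exit_ps[j]
      pos[inside, ] <- matrix(geom_for(my$region[j])$inside,
                              nrow = sum(inside), ncol = 3, byrow = TRUE)
    }
    data.frame(frame = seq_along(times), time_ps = times, ion_id = id,
               species = ions$species[i],
               x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
  # scripted ions teleport between region positions by construction
  ion_trajectory(ions = do.call(rbind, recs), dt_ps = dt, max_jump = Inf)
}
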