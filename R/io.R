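#' Read and write ion sample CSV
#'
#' The tabular interchange format for ion positions: columns `ion_id`,
#' `species`, `time_ps`, `x`, `y`, `z`.
#'
#' @param samples an [ion_samples()] object.
#' @param file path.
#' @return `read_samples_csv` returns an [ion_samples()] object.
#' @export
write_samples_csv <- function(samples, file) {
  utils::write.csv(as.data.frame(samples), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_samples_csv
#' @param dt_ps frame interval metadata to attach on read.
#' @export
read_samples_csv <- function(file, dt_ps = NA_real_) {
  ion_samples(utils::read.csv(file, stringsAsFactors = FALSE), dt_ps = dt_ps)
}

#' Read and write trajectory CSV
#'
#' Long-format trajectory interchange: columns `frame`, `time_ps`,
#' `ion_id`, `species`, `x`, `y`, `z`; optional companion file with protein
#' atom records (`frame`, `resid`, `resname`, `elety`, `x`, `y`, `z`).
#'
#' @param traj an [ion_trajectory()].
#' @param file path for the ion records.
#' @param protein_file optional path for the protein records.
#' @return `read_trajectory_csv` returns an [ion_trajectory()].
#' @export
write_trajectory_csv <- function(traj, file, protein_file = NULL) {
  utils::write.csv(traj$ions, file, row.names = FALSE)
  if (!is.null(protein_file) && !is.null(traj$protein)) {
    utils::write.csv(traj$protein, protein_file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @param dt_ps frame interval; inferred from the time stamps when NULL.
#' @export
read_trajectory_csv <- function(file, protein_file = NULL, dt_ps = NULL) {
  ions <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (is.null(dt_ps)) {
    tms <- sort(unique(ions$time_ps))
    dt_ps <- if (length(tms) > 1) min(diff(tms)) else 1
  }
  protein <- if (!is.null(protein_file)) {
    utils::read.csv(protein_file, stringsAsFactors = FALSE)
  } else NULL
  ion_trajectory(ions, dt_ps = dt_ps, protein = protein)
}

#' Write a trajectory in a minimal multi-frame XYZ dialect
#'
#' Each frame: an atom-count line, a comment line `time_ps=<t>`, then one
#' `<species> <x> <y> <z>` line per ion.
#'
#' @param traj an [ion_trajectory()].
#' @param file path.
#' @export
write_xyz_trajectory <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in sort(unique(traj$ions$frame))) {
    d <- traj$ions[traj$ions$frame == fr, ]
    writeLines(as.character(nrow(d)), con)
    writeLines(sprintf("time_ps=%g", d$time_ps[1]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", d$species, d$x, d$y, d$z), con)
  }
  invisible(file)
}

#' Write a density map as MRC/CCP4 (mode 2)
#'
#' Minimal MRC2014 writer: little-endian, 32-bit float data, isotropic
#' cell, origin recorded in the ORIGIN header words.
#'
#' @param map a [density_map()].
#' @param file path.
#' @export
write_mrc <- function(map, file) {
  stopifnot(inherits(map, "density_map"))
  con <- file(file, "wb")
  on.exit(close(con))
  d <- map$dims
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(map$values)
  wi(d)                                  # NX NY NZ
  wi(2)                                  # MODE 2: float32
  wi(c(0, 0, 0))                         # NXSTART..
  wi(d)                                  # MX MY MZ
  wf(d * map$voxel)                      # CELLA
  wf(c(90, 90, 90))                      # CELLB
  wi(c(1, 2, 3))                         # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))         # DMIN DMAX DMEAN
  wi(1)                                  # ISPG
  wi(0)                                  # NSYMBT
  wi(rep(0, 25))                         # EXTRA (words 25-49)
  wf(map$origin)                         # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(v))                       # RMS
  wi(0)                                  # NLABL
  writeBin(raw(200 * 4), con)            # labels
  writeBin(v, con, size = 4, endian = "little")
  invisible(file)
}

#' Read an MRC/CCP4 density map (modes 0, 1, 2)
#'
#' Counterpart of [write_mrc()]; accepts any axis-ordered map with an
#' isotropic cell (column/row/section permutations are resolved through the
#' MAPC/MAPR/MAPS words).
#'
#' @param file path.
#' @return a [density_map()] (not normalized; negative values, as appear in
#'   experimental maps, are clipped to 0 with a message).
#' @export
read_mrc <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  ri(3)                                   # nxstart
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                                   # cellb
  mapcrs <- ri(3)
  rf(3)                                   # dmin dmax dmean
  ri(1); nsymbt <- ri(1)
  ri(25)
  origin <- rf(3)
  readBin(con, "raw", 8)                  # MAP + MACHST
  rf(1); ri(1)
  readBin(con, "raw", 200 * 4)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  npts <- prod(nxyz)
  v <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", npts, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", npts, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", npts, size = 4, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  vox <- cella / mxyz
  if (max(vox) - min(vox) > 1e-4 * mean(vox)) {
    stop("anisotropic voxels not supported (", paste(signif(vox, 5),
                                                     collapse = ", "), ")")
  }
  A <- array(v, dim = nxyz)
  # bring axes to x, y, z order
  perm <- order(mapcrs)
  if (!all(perm == 1:3)) A <- aperm(A, perm)
  if (any(A < 0)) {
    message("clipping ", sum(A < 0), " negative voxels to 0")
    A[A < 0] <- 0
  }
  density_map(A, origin = origin, voxel = mean(vox), normalized = FALSE)
}

#' Export ridge points
#'
#' CSV columns: `x`, `y`, `z`, `sigma`, `strength`, `width`, `tx`, `ty`,
#' `tz`. The PDB form writes one pseudo-atom (HETATM, element C) per ridge
#' point with the width in the B-factor column, for display alongside the
#' protein structure.
#'
#' @param ridge a `ridge_points` data frame.
#' @param file path.
#' @export
write_ridge_csv <- function(ridge, file) {
  utils::write.csv(ridge[, c("x", "y", "z", "sigma", "strength", "width",
                             "tx", "ty", "tz")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ridge_csv
#' @param points data frame with `x`, `y`, `z` and optionally `width`.
#' @export
write_pdb_pseudo <- function(points, file) {
  b <- if ("width" %in% names(points)) points$width else rep(0, nrow(points))
  lines <- sprintf(
    "HETATM%5d  C   RDG A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(points)) %% 100000, seq_len(nrow(points)) %% 10000,
    points$x, points$y, points$z, 1.0, pmin(b, 99.99))
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Export a permeation path
#'
#' CSV columns: `arclength`, `x`, `y`, `z`, `width`.
#' @param path a `permeation_path`.
#' @param file path.
#' @export
write_path_csv <- function(path, file) {
  utils::write.csv(as.data.frame(path)[, c("arclength", "x", "y", "z",
                                           "width")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Export umbrella windows
#'
#' CSV mirrors the window table; the JSON restraint specification lists, per
#' window, the center, the local path tangent and the cylindrical restraint
#' radius, ready for building MD restraints downstream.
#'
#' @param windows a [make_umbrella_windows()] result.
#' @param path the `permeation_path` the windows were built on (for
#'   tangents).
#' @param file path.
#' @export
write_windows_csv <- function(windows, file) {
  utils::write.csv(windows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_windows_csv
#' @export
write_windows_json <- function(windows, path, file) {
  tangent_at <- function(zc) {
    i <- which.min(abs(path$z - zc))
    lo <- max(1, i - 1); hi <- min(nrow(path), i + 1)
    tv <- c(path$x[hi] - path$x[lo], path$y[hi] - path$y[lo],
            path$z[hi] - path$z[lo])
    nrm <- sqrt(sum(tv^2))
    if (nrm == 0) c(0, 0, -1) else tv / nrm
  }
  spec <- lapply(seq_len(nrow(windows)), function(i) {
    list(index = windows$index[i],
         center = c(windows$x[i], windows$y[i], windows$z[i]),
         axis = tangent_at(windows$center_z[i]),
         radius = windows$radius[i],
         kind = windows$kind[i])
  })
  jsonlite::write_json(spec, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read protein topology and coordinates from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb()` producing the single-frame protein
#' record table used by [ion_trajectory()]; standard MD trajectory formats
#' can be layered on the same records via bio3d's trajectory readers.
#'
#' @param file PDB path.
#' @return data frame with `frame`, `resid`, `resname`, `elety`, `x`, `y`,
#'   `z` (frame = 1).
#' @export
read_pdb_protein <- function(file) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  data.frame(frame = 1L, resid = a$resno, resname = a$resid,
             elety = a$elety, x = a$x, y = a$y, z = a$z)
}
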