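#' Ion trajectories
#'
#' Frame-indexed coordinates of ions and (optionally) selected protein atoms
#' and water oxygens, at a constant frame interval. Coordinates follow the
#' pore-axis convention: Z = 0 at the protein center of mass. A validation
#' pass rejects per-ion coordinate jumps larger than `max_jump` between
#' consecutive frames (periodic images must be unwrapped upstream).
#'
#' @param ions data frame with columns `frame`, `time_ps`, `ion_id`,
#'   `species`, `x`, `y`, `z`.
#' @param dt_ps frame interval in ps, > 0.
#' @param protein optional data frame with columns `frame`, `resid`,
#'   `resname`, `elety` (atom name), `x`, `y`, `z`; water oxygens may be
#'   included with resname HOH/TIP3/WAT/SOL and atom name OW/OH2/O.
#' @param max_jump validation threshold in Angstrom per frame (default 20).
#' @return an `ion_trajectory` object.
#' @export
ion_trajectory <- function(ions, dt_ps, protein = NULL, max_jump = 20) {
  need <- c("frame", "time_ps", "ion_id", "species", "x", "y", "z")
  if (!all(need %in% names(ions))) {
    stop("ions needs columns: ", paste(need, collapse = ", "))
  }
  stopifnot(dt_ps > 0)
  ions <- as.data.frame(ions)[order(ions$frame, ions$ion_id), ]
  if (nrow(ions) > 0) {
    tms <- unique(ions$time_ps)
    if (any(abs(tms / dt_ps - round(tms / dt_ps)) > 1e-6)) {
      stop("frame times are not on the dt_ps lattice")
    }
    for (id in unique(ions$ion_id)) {
      p <- ions[ions$ion_id == id, c("x", "y", "z")]
      if (nrow(p) > 1) {
        jump <- sqrt(rowSums(diff(as.matrix(p))^2))
        if (any(jump > max_jump)) {
          stop("ion ", id, " jumps more than ", max_jump,
               " A between frames; unwrap the trajectory first")
        }
      }
    }
  }
  structure(list(ions = ions, dt_ps = dt_ps, protein = protein,
                 frame_note = "Z = 0 at protein center of mass"),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("ion_trajectory: %d frames, %d ions, dt = %g ps%s\n",
              length(unique(x$ions$frame)), length(unique(x$ions$ion_id)),
              x$dt_ps,
              if (is.null(x$protein)) "" else sprintf(", %d protein-atom records",
                                                      nrow(x$protein))))
  invisible(x)
}

#' Z-slab region boundaries from side-chain atom statistics
#'
#' Estimates the upper and lower Z boundaries of a residue-defined region
#' (e.g. the DEKA constriction site, defined by the Cgamma, Cdelta, Nzeta
#' and Cbeta atoms of the Asp, Glu, Lys and Ala residues) from per-atom
#' means and standard deviations of Z over the trajectory:
#' `z_upper = max(mean + sd)`, `z_lower = min(mean - sd)` over the listed
#' atoms.
#'
#' @param traj an [ion_trajectory()] with protein records.
#' @param atom_spec data frame with columns `resid` and `elety` naming one
#'   side-chain heavy atom per residue.
#' @return a `region_bounds` list: `z_lower`, `z_upper` and the per-atom
#'   statistics table.
#' @export
region_bounds <- function(traj, atom_spec) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (is.null(traj$protein)) stop("trajectory has no protein records")
  atom_spec <- as.data.frame(atom_spec)
  n_frames <- length(unique(traj$protein$frame))
  stats_list <- lapply(seq_len(nrow(atom_spec)), function(i) {
    sel <- traj$protein$resid == atom_spec$resid[i] &
      traj$protein$elety == atom_spec$elety[i]
    zz <- traj$protein$z[sel]
    if (length(zz) == 0) {
      stop("atom ", atom_spec$elety[i], " of residue ", atom_spec$resid[i],
           " not found in trajectory")
    }
    if (length(zz) < 0.9 * n_frames) {
      stop("atom ", atom_spec$elety[i], " of residue ", atom_spec$resid[i],
           " present in fewer than 90% of frames")
    }
    data.frame(resid = atom_spec$resid[i], elety = atom_spec$elety[i],
               mean_z = mean(zz),
               sd_z = if (length(zz) > 1) stats::sd(zz) else 0)
  })
  st <- do.call(rbind, stats_list)
  structure(list(z_lower = min(st$mean_z - st$sd_z),
                 z_upper = max(st$mean_z + st$sd_z),
                 atoms = st),
            class = "region_bounds")
}

#' @export
print.region_bounds <- function(x, ...) {
  cat(sprintf("region_bounds: Z in [%.2f, %.2f] A from %d atoms\n",
              x$z_lower, x$z_upper, nrow(x$atoms)))
  invisible(x)
}

#' Residence times below a Z boundary
#'
#' One dwell per maximal contiguous run of frames with ion Z strictly below
#' `z_boundary`; the dwell duration is `(run length - 1) * dt`, so a
#' single-frame visit reports 0 ps. Typical use: residence of ions below the
#' extracellular boundary of the constriction-site region.
#'
#' @param traj an [ion_trajectory()].
#' @param species species label.
#' @param z_boundary boundary in Angstrom.
#' @return data frame with `ion_id`, `start_ps`, `duration_ps`.
#' @export
residence_times <- function(traj, species, z_boundary) {
  stopifnot(inherits(traj, "ion_trajectory"), is.finite(z_boundary))
  di <- traj$ions[traj$ions$species == species, , drop = FALSE]
  out <- list()
  for (id in unique(di$ion_id)) {
    sel <- di[di$ion_id == id, ]
    sel <- sel[order(sel$frame), ]
    below <- sel$z < z_boundary
    runs <- .contiguous_runs(sel$frame, below)
    for (k in seq_len(nrow(runs))) {
      out[[length(out) + 1]] <- data.frame(
        ion_id = id, start_ps = sel$time_ps[runs$start[k]],
        duration_ps = (runs$len[k] - 1) * traj$dt_ps)
    }
  }
  if (length(out) == 0) {
    return(data.frame(ion_id = character(), start_ps = numeric(),
                      duration_ps = numeric()))
  }
  do.call(rbind, out)
}

#' Time-dependent ion trails
#'
#' Per-ion `(time, Z)` series with a flag marking ions that have ever
#' entered the given Z region (strict inequalities), the quantity used to
#' color individual permeating ions in trail plots.
#'
#' @param traj an [ion_trajectory()].
#' @param species species label.
#' @param region numeric 2-vector `c(z_lower, z_upper)`.
#' @return data frame with `ion_id`, `time_ps`, `z`, `entered` (per-ion
#'   constant flag).
#' @export
ion_trails <- function(traj, species, region) {
  stopifnot(inherits(traj, "ion_trajectory"), length(region) == 2)
  di <- traj$ions[traj$ions$species == species, , drop = FALSE]
  di <- di[order(di$ion_id, di$frame), ]
  inreg <- di$z > region[1] & di$z < region[2]
  entered <- tapply(inreg, di$ion_id, any)
  data.frame(ion_id = di$ion_id, time_ps = di$time_ps, z = di$z,
             entered = as.logical(entered[di$ion_id]))
}

# maximal runs of TRUE flags over frame-ordered records; a gap in the frame
# numbering breaks a run (the ion left the recorded system)
.contiguous_runs <- function(frames, flag) {
  n <- length(flag)
  if (n == 0) return(data.frame(start = integer(), len = integer()))
  newrun <- c(TRUE, diff(frames) != 1 | flag[-1] != flag[-n])
  run_id <- cumsum(newrun)
  starts <- which(newrun)
  lens <- as.integer(tabulate(run_id))
  keep <- flag[starts]
  data.frame(start = starts[keep], len = lens[keep])
}

.carboxylate_atoms <- c("OD1", "OD2", "OE1", "OE2")
.water_resnames <- c("HOH", "TIP3", "WAT", "SOL")
.water_oxygens <- c("OW", "OH2", "O")

#' Ion-carboxylate coordination events
#'
#' Records an event for every (frame, ion, residue) triple whose minimum
#' distance from the ion to a carboxylate oxygen (OD1/OD2 of Asp, OE1/OE2 of
#' Glu) of the residue is strictly below `cutoff` (default 3.1 Angstrom, the
#' standard first-shell ion-carboxylate criterion).
#'
#' @param traj an [ion_trajectory()] with protein records.
#' @param ion_species species label of the coordinating ions.
#' @param acidic_residues integer vector of residue ids; each must carry
#'   carboxylate oxygens in the trajectory.
#' @param cutoff distance criterion in Angstrom.
#' @return data frame with `time_ps`, `ion_id`, `resid`, `resname`,
#'   `min_dist`.
#' @export
coordination_events <- function(traj, ion_species, acidic_residues,
                                cutoff = 3.1) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (is.null(traj$protein)) stop("trajectory has no protein records")
  pr <- traj$protein
  ox <- pr[pr$resid %in% acidic_residues & pr$elety %in% .carboxylate_atoms, ]
  missing <- setdiff(acidic_residues, unique(ox$resid))
  if (length(missing)) {
    stop("residue(s) without carboxylate oxygens: ",
         paste(missing, collapse = ", "))
  }
  di <- traj$ions[traj$ions$species == ion_species, , drop = FALSE]
  out <- list()
  for (fr in sort(unique(di$frame))) {
    ions_f <- di[di$frame == fr, ]
    ox_f <- ox[ox$frame == fr, ]
    if (nrow(ox_f) == 0) next
    for (i in seq_len(nrow(ions_f))) {
      d <- sqrt((ox_f$x - ions_f$x[i])^2 + (ox_f$y - ions_f$y[i])^2 +
                  (ox_f$z - ions_f$z[i])^2)
      md <- tapply(d, ox_f$resid, min)
      hit <- md < cutoff
      if (any(hit)) {
        rid <- as.integer(names(md)[hit])
        out[[length(out) + 1]] <- data.frame(
          time_ps = ions_f$time_ps[i], ion_id = ions_f$ion_id[i],
          resid = rid,
          resname = ox_f$resname[match(rid, ox_f$resid)],
          min_dist = as.numeric(md[hit]))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(time_ps = numeric(), ion_id = character(),
                      resid = integer(), resname = character(),
                      min_dist = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-residue coordination probability along Z
#'
#' For each Z bin, the fraction of ion-frames in the bin during which the
#' ion is coordinated by each residue (an event exists for that frame, ion
#' and residue). Bins with no ion-frames are absent from the output, not
#' zero.
#'
#' @param events a [coordination_events()] result.
#' @param samples the [ion_samples()] (ion-frames) of the same trajectory.
#' @param z_bins bin width in Angstrom.
#' @return data frame with `z_lo`, `z_hi`, `z_mid`, `resid`, `prob`,
#'   `n_frames`.
#' @export
coordination_probability_profile <- function(events, samples, z_bins = 1) {
  if (z_bins <= 0) stop("z_bins must be positive")
  if (nrow(samples) == 0) stop("no ion-frames supplied")
  b <- floor(samples$z / z_bins)
  key_s <- paste(samples$time_ps, samples$ion_id)
  resids <- sort(unique(events$resid))
  ub <- sort(unique(b))
  rows <- list()
  for (bb in ub) {
    in_bin <- b == bb
    nfr <- sum(in_bin)
    keys <- key_s[in_bin]
    for (rid in resids) {
      ekey <- paste(events$time_ps[events$resid == rid],
                    events$ion_id[events$resid == rid])
      rows[[length(rows) + 1]] <- data.frame(
        z_lo = bb * z_bins, z_hi = (bb + 1) * z_bins,
        z_mid = (bb + 0.5) * z_bins, resid = rid,
        prob = sum(keys %in% ekey) / nfr, n_frames = nfr)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(z_lo = numeric(), z_hi = numeric(), z_mid = numeric(),
                      resid = integer(), prob = numeric(),
                      n_frames = integer()))
  }
  do.call(rbind, rows)
}

#' First-shell coordination number of an ion
#'
#' Counts water oxygens within `shell_cutoff_water` plus carboxylate oxygens
#' within `shell_cutoff_carboxylate` of the ion in one frame. In the
#' selectivity-filter interior the loss of hydration waters is compensated
#' by carboxylate oxygens so the total typically stays at 5-6 for sodium.
#'
#' @param traj an [ion_trajectory()] whose protein records include water
#'   oxygens (resname HOH/TIP3/WAT/SOL) when a water shell is requested.
#' @param frame frame index.
#' @param ion_id ion identifier.
#' @param shell_cutoff_water,shell_cutoff_carboxylate first-shell cutoffs in
#'   Angstrom (defaults 3.1).
#' @return integer coordination number; components in the `water` and
#'   `carboxylate` attributes.
#' @export
coordination_number <- function(traj, frame, ion_id,
                                shell_cutoff_water = 3.1,
                                shell_cutoff_carboxylate = 3.1) {
  stopifnot(inherits(traj, "ion_trajectory"))
  ion <- traj$ions[traj$ions$frame == frame & traj$ions$ion_id == ion_id, ]
  if (nrow(ion) != 1) stop("ion ", ion_id, " not found in frame ", frame)
  pr <- traj$protein
  if (is.null(pr)) pr <- data.frame(frame = integer(), resid = integer(),
                                    resname = character(),
                                    elety = character(), x = numeric(),
                                    y = numeric(), z = numeric())
  pr <- pr[pr$frame == frame, ]
  wat <- pr[pr$resname %in% .water_resnames & pr$elety %in% .water_oxygens, ]
  if (shell_cutoff_water > 0 && nrow(wat) == 0 &&
      !any(traj$protein$resname %in% .water_resnames)) {
    stop("trajectory has no water oxygen records but a water shell was requested")
  }
  carb <- pr[pr$elety %in% .carboxylate_atoms, ]
  d_to <- function(df) {
    if (nrow(df) == 0) return(numeric(0))
    sqrt((df$x - ion$x)^2 + (df$y - ion$y)^2 + (df$z - ion$z)^2)
  }
  nw <- sum(d_to(wat) < shell_cutoff_water)
  nc <- sum(d_to(carb) < shell_cutoff_carboxylate)
  structure(as.integer(nw + nc), water = as.integer(nw),
            carboxylate = as.integer(nc))
}

#' Convert trajectory ion records to an ion sample set
#'
#' @param traj an [ion_trajectory()].
#' @param species optional species filter.
#' @return an [ion_samples()] object (unfiltered).
#' @export
trajectory_samples <- function(traj, species = NULL) {
  di <- traj$ions
  if (!is.null(species)) di <- di[di$species == species, , drop = FALSE]
  ion_samples(di[, c("ion_id", "species", "time_ps", "x", "y", "z")],
              dt_ps = traj$dt_ps)
}
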