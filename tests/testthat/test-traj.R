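protein_frames <- function(n_frames, atoms) {
  # atoms: data.frame(resid, resname, elety, x, y, z); replicated per frame
  do.call(rbind, lapply(seq_len(n_frames), function(fr) {
    cbind(frame = fr, atoms)
  }))
}

test_that("region bounds follow the mean +- sd rule over side-chain atoms", {
  # single atom at constant Z: degenerate bounds
  at <- data.frame(resid = 375, resname = "ASP", elety = "CG",
                   x = 0, y = 0, z = 10)
  tr <- one_ion_traj(rep(30, 5))
  tr$protein <- protein_frames(5, at)
  rb <- region_bounds(tr, data.frame(resid = 375, elety = "CG"))
  expect_equal(c(rb$z_lower, rb$z_upper), c(10, 10))

  # two atoms with (mu = 5, s = 0.5) and (mu = 9, s = 1.0): bounds 4.5, 10
  mk_z <- function(mu, s, n) mu + s * scale(stats::rnorm(n))[, 1]
  set.seed(2); n <- 40
  pr <- rbind(
    data.frame(frame = 1:n, resid = 375, resname = "ASP", elety = "CG",
               x = 0, y = 0, z = mk_z(5, 0.5, n)),
    data.frame(frame = 1:n, resid = 701, resname = "GLU", elety = "CD",
               x = 0, y = 0, z = mk_z(9, 1.0, n)))
  tr <- one_ion_traj(rep(30, n))
  tr$protein <- pr
  rb <- region_bounds(tr, data.frame(resid = c(375, 701),
                                     elety = c("CG", "CD")))
  expect_equal(rb$z_lower, 4.5, tolerance = 1e-9)
  expect_equal(rb$z_upper, 10.0, tolerance = 1e-9)

  # frame order permutation leaves the bounds unchanged
  tr2 <- tr
  tr2$protein <- pr[sample(nrow(pr)), ]
  rb2 <- region_bounds(tr2, data.frame(resid = c(375, 701),
                                       elety = c("CG", "CD")))
  expect_equal(c(rb2$z_lower, rb2$z_upper), c(rb$z_lower, rb$z_upper))

  expect_error(region_bounds(tr, data.frame(resid = 999, elety = "CG")),
               "999")
})

test_that("residence durations follow the (run - 1) * dt contract", {
  dt <- 2
  z <- rep(30, 200)
  z[51:151] <- 5  # below boundary frames 51..151 inclusive
  tr <- one_ion_traj(z, dt)
  rt <- residence_times(tr, "Na", z_boundary = 10)
  expect_equal(nrow(rt), 1)
  expect_equal(rt$duration_ps, 200)
  # never below: empty result
  expect_equal(nrow(residence_times(one_ion_traj(rep(30, 10)), "Na", 10)), 0)
  # single-frame visit reports 0 ps
  z2 <- rep(30, 10); z2[5] <- 5
  rt2 <- residence_times(one_ion_traj(z2, dt), "Na", 10)
  expect_equal(rt2$duration_ps, 0)
})

test_that("residence dwells partition the below-boundary frames exactly", {
  set.seed(7)
  dt <- 4
  z <- ifelse(stats::runif(400) < 0.3, 5, 30)
  tr <- one_ion_traj(z, dt)
  rt <- residence_times(tr, "Na", 10)
  # total frames covered by dwells equals the below-boundary frame count
  expect_equal(sum(rt$duration_ps / dt + 1), sum(z < 10))
  # dwell starts match the brute-force segmentation
  runs <- brute_dwell_frames(z < 10)
  expect_equal(nrow(rt), length(runs))
  expect_equal(sort(rt$start_ps),
               sort(vapply(runs, function(r) (r[1] - 1) * dt, numeric(1))))
})

test_that("ion trails flag exactly the ions that entered the region", {
  dt <- 2
  ions <- rbind(
    data.frame(frame = 1:50, time_ps = (0:49) * dt, ion_id = "above",
               species = "Na", x = 0, y = 0, z = 30),
    data.frame(frame = 1:50, time_ps = (0:49) * dt, ion_id = "dips",
               species = "Na", x = 0, y = 0,
               z = c(rep(30, 24), 5, rep(30, 25))))
  tr <- ion_trajectory(ions, dt_ps = dt, max_jump = 50)
  tl <- ion_trails(tr, "Na", region = c(-5, 12))
  expect_false(any(tl$entered[tl$ion_id == "above"]))
  expect_true(all(tl$entered[tl$ion_id == "dips"]))
  # flags equal a brute-force per-frame interval test over all ions
  for (id in unique(tl$ion_id)) {
    zz <- ions$z[ions$ion_id == id]
    expect_equal(unique(tl$entered[tl$ion_id == id]),
                 any(zz > -5 & zz < 12))
  }
})

test_that("the 3.1 A carboxylate criterion is strict", {
  # 3.0 A contact: coordinated
  ev <- coordination_events(coord_fixture(3.0), "Na", 375)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$min_dist, 3.0)
  # 3.2 A: not coordinated
  ev <- coordination_events(coord_fixture(3.2), "Na", 375)
  expect_equal(nrow(ev), 0)
  # exactly at the cutoff: excluded (strict inequality)
  ev <- coordination_events(coord_fixture(3.1), "Na", 375)
  expect_equal(nrow(ev), 0)
})

test_that("simultaneous coordination by two residues yields two events", {
  tr <- coord_fixture(c(2.8, 2.8), resids = c(375, 701),
                      resnames = c("ASP", "GLU"), eletys = c("OD1", "OE1"))
  ev <- coordination_events(tr, "Na", c(375, 701))
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$resid, c(375, 701))
  expect_equal(unique(ev$time_ps), 0)
})

test_that("residues without carboxylate oxygens are rejected by name", {
  tr <- coord_fixture(2.5)
  expect_error(coordination_events(tr, "Na", c(375, 1061)), "1061")
})

test_that("coordination probabilities recover planted per-bin rates", {
  set.seed(33)
  n <- 1000
  # ion-frames split between two Z bins with planted coordination rates
  z <- c(rep(0.5, n), rep(1.5, n))
  samp <- ion_samples(data.frame(
    ion_id = "a", species = "Na", time_ps = seq_len(2 * n) * 2.0,
    x = 0, y = 0, z = z))
  hit <- c(stats::runif(n) < 0.25, stats::runif(n) < 0.5)
  ev <- data.frame(time_ps = samp$time_ps[hit], ion_id = "a",
                   resid = 375, resname = "ASP", min_dist = 2.5)
  pr <- coordination_probability_profile(ev, samp, z_bins = 1)
  expect_equal(nrow(pr), 2)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_equal(pr$prob[pr$z_lo == 0], 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / n) / 0.25)
  expect_equal(pr$prob[pr$z_lo == 1], 0.5, tolerance = 3 * sqrt(0.5 * 0.5 / n) / 0.5)
  # event order is irrelevant
  pr2 <- coordination_probability_profile(ev[sample(nrow(ev)), ], samp, 1)
  expect_equal(pr2$prob, pr$prob)
  # no events: all probabilities 0, bins still reported
  pr0 <- coordination_probability_profile(ev[0, ], samp, 1)
  expect_true(nrow(pr0) == 0 || all(pr0$prob == 0))
})

test_that("coordination numbers count both oxygen shells", {
  # 4 water O at 2.3 A + 2 carboxylate O at 2.5 A -> 6
  wat <- data.frame(frame = 1, resid = 9000 + 1:4, resname = "HOH",
                    elety = "OW",
                    x = c(2.3, -2.3, 0, 0), y = c(0, 0, 2.3, -2.3), z = 0)
  carb <- data.frame(frame = 1, resid = c(375, 701),
                     resname = c("ASP", "GLU"), elety = c("OD1", "OE1"),
                     x = 0, y = 0, z = c(2.5, -2.5))
  tr <- one_ion_traj(0, dt = 2)
  tr$ions$z <- 0
  tr$protein <- rbind(wat, carb)
  cn <- coordination_number(tr, 1, "ionA")
  expect_equal(as.integer(cn), 6)
  expect_equal(attr(cn, "water"), 4L)
  expect_equal(attr(cn, "carboxylate"), 2L)

  # nothing within the cutoffs
  tr2 <- tr
  tr2$protein$x <- tr2$protein$x + 50
  tr2$protein$y <- tr2$protein$y + 50
  expect_equal(as.integer(coordination_number(tr2, 1, "ionA")), 0)

  # no water records and a water shell requested: explicit error
  tr3 <- tr
  tr3$protein <- carb
  expect_error(coordination_number(tr3, 1, "ionA"), "water")
  expect_equal(as.integer(coordination_number(tr3, 1, "ionA",
                                              shell_cutoff_water = 0)), 2)
})

test_that("shell counts match an exhaustive distance scan on random oxygens", {
  set.seed(44)
  n <- 60
  # oxygens on spheres just inside and just outside the cutoff
  r <- sample(c(3.05, 3.15), n, replace = TRUE)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- u * r
  pr <- data.frame(frame = 1, resid = 9000 + 1:n, resname = "HOH",
                   elety = "OW", x = pos[, 1], y = pos[, 2], z = pos[, 3])
  tr <- one_ion_traj(0, dt = 2)
  tr$ions$z <- 0
  tr$protein <- pr
  cn <- coordination_number(tr, 1, "ionA", shell_cutoff_carboxylate = 0)
  expect_equal(as.integer(cn), sum(sqrt(rowSums(pos^2)) < 3.1))
  expect_equal(as.integer(cn), sum(r == 3.05))
})

test_that("per-frame operations ignore ion record order within frames", {
  dt <- 2
  ions <- rbind(
    data.frame(frame = rep(1:30, 2), time_ps = rep((0:29) * dt, 2),
               ion_id = rep(c("a", "b"), each = 30), species = "Na",
               x = 0, y = 0, z = c(seq(30, 1, length.out = 30),
                                   rep(25, 30))))
  shuffled <- ions[sample(nrow(ions)), ]
  t1 <- ion_trajectory(ions, dt_ps = dt, max_jump = 50)
  t2 <- ion_trajectory(shuffled, dt_ps = dt, max_jump = 50)
  r1 <- residence_times(t1, "Na", 10)
  r2 <- residence_times(t2, "Na", 10)
  expect_equal(r1[order(r1$ion_id, r1$start_ps), ],
               r2[order(r2$ion_id, r2$start_ps), ], ignore_attr = TRUE)
  tl1 <- ion_trails(t1, "Na", c(-5, 20))
  tl2 <- ion_trails(t2, "Na", c(-5, 20))
  expect_equal(tl1[order(tl1$ion_id, tl1$time_ps), ],
               tl2[order(tl2$ion_id, tl2$time_ps), ], ignore_attr = TRUE)
})

test_that("trajectories with coordinate jumps are rejected", {
  z <- c(0, 0, 35, 0)
  expect_error(
    ion_trajectory(data.frame(frame = 1:4, time_ps = (0:3) * 2,
                              ion_id = "a", species = "Na",
                              x = 0, y = 0, z = z), dt_ps = 2),
    "unwrap")
})
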