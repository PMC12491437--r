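# Pose geometry: tilt/z-offset computation, the membrane-topology filter,
# and rigid-transform bookkeeping.

test_that("dock_pose rejects non-rotations", {
  expect_error(dock_pose(1, diag(3) * 2, c(0, 0, 0), 1), "orthonormal")
  refl <- diag(c(1, 1, -1))  # det -1
  expect_error(dock_pose(1, refl, c(0, 0, 0), 1), "orthonormal")
})

test_that("tilt and z-offset follow the closed-form definitions", {
  probe <- toy_probe()
  id <- identity_pose()
  m <- compute_topology(id, probe)
  expect_equal(m$tilt_rad, 0)
  expect_equal(m$z_offset_A, 0)

  # rotation about z leaves the z axis invariant: tilt 0
  rz <- dock_pose(2, gpcrdimer:::rot_z(pi / 2), c(0, 0, 0), 1)
  expect_equal(compute_topology(rz, probe)$tilt_rad, 0)

  # probe centered at origin, rotation about x by 0.5 rad, t = (0,0,7):
  # tilt 0.5, z-offset 7 (closed-form matrix evaluation)
  cen <- ca_centroid(probe)
  centered <- toy_structure(sweep(ca_coords(probe), 2, cen))
  rx <- dock_pose(3, gpcrdimer:::rot_axis(c(1, 0, 0), 0.5), c(0, 0, 7), 1)
  mm <- compute_topology(rx, centered)
  expect_equal(mm$tilt_rad, 0.5, tolerance = 1e-12)
  expect_equal(mm$z_offset_A, 7, tolerance = 1e-12)
})

test_that("tilt is invariant under z-rotation and translation", {
  probe <- toy_probe()
  set.seed(4)
  for (i in 1:10) {
    th <- runif(1, 0, 0.8)
    base <- gpcrdimer:::rot_axis(c(cos(runif(1, 0, 2 * pi)),
                                   sin(runif(1, 0, 2 * pi)), 0), th)
    spin <- gpcrdimer:::rot_z(runif(1, 0, 2 * pi))
    p1 <- dock_pose(1, base, runif(3, -10, 10), 1)
    p2 <- dock_pose(2, spin %*% base, runif(3, -10, 10), 1)
    expect_equal(compute_topology(p1, probe)$tilt_rad, th,
                 tolerance = 1e-9)
    expect_equal(compute_topology(p2, probe)$tilt_rad, th,
                 tolerance = 1e-9)
  }
})

test_that("the topology filter applies thresholds, ranking and keep-best", {
  probe <- toy_probe()
  cen <- ca_centroid(probe)
  mk <- function(id, tilt, z, score) {
    R <- gpcrdimer:::rot_axis(c(1, 0, 0), tilt)
    tz <- z - as.numeric(R %*% cen - cen)[3]
    dock_pose(id, R, c(0, 0, tz), score)
  }
  inside <- mk(1, 0.39, 5.9, 10)
  out_tilt <- mk(2, 0.41, 0, 9)
  out_z <- mk(3, 0.1, 6.5, 8)
  kept <- filter_poses(list(out_tilt, inside, out_z), probe)
  expect_equal(vapply(kept, `[[`, integer(1), "pose_id"), 1L)
  expect_equal(kept[[1]]$tilt_rad, 0.39, tolerance = 1e-9)

  # keep_best truncates by score before filtering
  many <- list(mk(1, 0.1, 0, 5), mk(2, 0.1, 0, 9), mk(3, 0.1, 0, 7))
  kept2 <- filter_poses(many, probe,
                        topology_filter_config(keep_best = 2))
  expect_equal(vapply(kept2, `[[`, integer(1), "pose_id"), c(2L, 3L))

  expect_message(empty <- filter_poses(list(), probe), "empty")
  expect_length(empty, 0)
})

test_that("filtering on simulated poses is exact and monotone in thresholds", {
  probe <- toy_probe()
  sim <- simulate_poses(pose_sim_config(1000, c(0, 0.8), c(-12, 12),
                                        seed = 1), probe)
  kept <- filter_poses(sim$poses, probe)
  expect_setequal(vapply(kept, `[[`, integer(1), "pose_id"),
                  sim$truth$pose_id[sim$truth$accept])
  n_base <- length(kept)
  # raising either threshold never shrinks the accepted set
  expect_gte(length(filter_poses(sim$poses, probe,
                                 topology_filter_config(tilt_max_rad = 0.6))),
             n_base)
  expect_gte(length(filter_poses(sim$poses, probe,
                                 topology_filter_config(z_offset_max_A = 9))),
             n_base)
})

test_that("pose tables round-trip through TSV", {
  probe <- toy_probe()
  sim <- simulate_poses(pose_sim_config(5, c(0, 0.5), c(-3, 3), seed = 2),
                        probe)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pose_table(sim$poses, path)
  back <- read_pose_table(path)
  for (i in 1:5) {
    expect_equal(back[[i]]$rotation, sim$poses[[i]]$rotation,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$translation, sim$poses[[i]]$translation,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$score, sim$poses[[i]]$score)
  }
})

test_that("rigid transforms are recovered from posed coordinates", {
  probe <- toy_probe()
  pose <- dock_pose(7, gpcrdimer:::rot_z(0.7) %*%
                      gpcrdimer:::rot_axis(c(1, 0, 0), 0.3),
                    c(4, -2, 6), 3)
  posed <- apply_pose(probe, pose)
  rec <- pose_from_coords(probe, posed)
  expect_equal(rec$rotation, pose$rotation, tolerance = 1e-9)
  expect_equal(rec$translation, pose$translation, tolerance = 1e-9)
})

test_that("PDB structures read into the container", {
  m <- toy_structure(rbind(c(1, 2, 3), c(4, 5, 6)), resno = c(10L, 11L))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(m, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), 2L)
  expect_equal(back$atoms$resno, c(10L, 11L))
  expect_equal(back$atoms$x, c(1, 4), tolerance = 1e-3)
  expect_equal(ca_coords(back)[2, ], c(x = 4, y = 5, z = 6),
               ignore_attr = TRUE, tolerance = 1e-3)
})
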