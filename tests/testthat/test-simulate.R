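# Synthetic-data generators: determinism, ground-truth consistency, and
# the documented geometric construction.

test_that("localization simulator handles zero and noise-free cases", {
  empty <- simulate_localizations(palm_sim_config(c("1" = 0), seed = 3))
  expect_equal(n_points(empty$map), 0L)
  expect_equal(nrow(empty$truth$receptors), 0L)

  dimer <- simulate_localizations(palm_sim_config(
    c("2" = 1), cluster_radius_nm = 10, loc_error_sd_nm = 0,
    blink_rate = 0, seed = 7))
  expect_equal(n_points(dimer$map), 2L)
  d <- dist(dimer$map$points[, c("x_nm", "y_nm")])
  expect_lte(as.numeric(d), 20)
})

test_that("localization counts follow the configured composition", {
  sim <- simulate_localizations(palm_sim_config(
    c("1" = 50, "2" = 30, "3" = 15, "5" = 5),
    cluster_radius_nm = 10, loc_error_sd_nm = 5, blink_rate = 0,
    min_center_sep_nm = 300, seed = 11))
  expect_equal(n_points(sim$map), 50 + 60 + 45 + 25)  # 180 receptors
  expect_equal(nrow(sim$truth$receptors), 180L)
  # truth membership partitions the receptor set
  expect_equal(sort(unique(sim$truth$receptors$receptor_id)), 1:180)
  tab <- table(table(sim$truth$receptors$complex_id))
  expect_equal(as.integer(tab[c("1", "2", "3", "5")]), c(50L, 30L, 15L, 5L))
})

test_that("simulators are bit-identical under a fixed seed and leave global RNG alone", {
  cfg <- palm_sim_config(c("1" = 20, "3" = 5), blink_rate = 0.5, seed = 42)
  set.seed(999); before <- runif(1)
  a <- simulate_localizations(cfg)
  b <- simulate_localizations(cfg)
  expect_identical(a$map$points, b$map$points)
  expect_identical(a$truth, b$truth)
  set.seed(999)
  expect_identical(runif(1), before)

  pcfg <- pose_sim_config(50, c(0, 0.8), c(-12, 12), seed = 42)
  probe <- toy_probe()
  expect_identical(simulate_poses(pcfg, probe)$truth,
                   simulate_poses(pcfg, probe)$truth)

  bcfg <- bret_sim_config("kinetics", list(k_per_s = 0.02, plateau = 0.05),
                          seq(3, 60, 3), noise_sd = 0.01, seed = 42)
  expect_identical(simulate_bret(bcfg), simulate_bret(bcfg))
})

test_that("infeasible center separation fails explicitly", {
  expect_error(simulate_localizations(palm_sim_config(
    c("1" = 500), roi_width_nm = 1000, roi_height_nm = 1000,
    min_center_sep_nm = 900, seed = 1)),
    "min separation")
})

test_that("pose truth matches topology recomputation to 1e-9", {
  probe <- toy_probe()
  sim <- simulate_poses(pose_sim_config(200, c(0, 0.8), c(-12, 12),
                                        seed = 5), probe)
  for (i in seq(1, 200, by = 7)) {
    m <- compute_topology(sim$poses[[i]], probe)
    expect_lt(abs(m$tilt_rad - sim$truth$tilt_rad[i]), 1e-9)
    expect_lt(abs(m$z_offset_A - sim$truth$z_offset_A[i]), 1e-9)
  }
  # degenerate ranges
  one <- simulate_poses(pose_sim_config(1, 0, 0, xy_jitter_A = 0, seed = 1),
                        probe)
  expect_equal(one$truth$tilt_rad, 0)
  expect_equal(one$truth$z_offset_A, 0)
  tilted <- simulate_poses(pose_sim_config(1, 0.5, 0, seed = 1), probe)
  expect_false(tilted$truth$accept)  # 0.5 > 0.4 rad
})

test_that("truth accept flag equals the brute-force threshold rule", {
  probe <- toy_probe()
  sim <- simulate_poses(pose_sim_config(1000, c(0, 0.8), c(-12, 12),
                                        seed = 1), probe)
  brute <- sim$truth$tilt_rad <= 0.4 & abs(sim$truth$z_offset_A) <= 6.0
  expect_identical(sim$truth$accept, brute)
})

test_that("noise-free BRET curves hit their closed-form values", {
  kin <- simulate_bret(bret_sim_config(
    "kinetics", list(k_per_s = 0.02, plateau = 0.05),
    c(1, 34.657), noise_sd = 0, seed = 1))
  expect_equal(kin$y[2], 0.025, tolerance = 1e-4)  # half-time point
  sat <- simulate_bret(bret_sim_config(
    "saturation", list(BRETmax = 0.3, BRET50 = 0.05),
    c(0.01, 0.05), noise_sd = 0, seed = 1))
  expect_equal(sat$y[2], 0.15)  # half-max at x = BRET50
  ec50 <- 10^-5.362
  dr <- simulate_bret(bret_sim_config(
    "dose_response", list(EC50_M = ec50, Emax = 100, baseline = 20),
    c(ec50 / 10, ec50), noise_sd = 0, seed = 1))
  expect_equal(dr$y[2], 60)  # midpoint response at EC50
})

test_that("config validation rejects bad inputs", {
  expect_error(palm_sim_config(c(10), seed = 1), "named")
  expect_error(palm_sim_config(c("2" = -1), seed = 1), "non-negative")
  expect_error(pose_sim_config(0, 0, 0, seed = 1), "> 0")
  expect_error(pose_sim_config(5, c(0, 4), 0, seed = 1), "tilt_range")
  expect_error(bret_sim_config("kinetics", list(k_per_s = 0.1),
                               1:5, seed = 1), "plateau")
  expect_error(bret_sim_config("kinetics",
                               list(k_per_s = 0.1, plateau = 0.05),
                               c(1, 1, 2), seed = 1), "increasing")
})
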