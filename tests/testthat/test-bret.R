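# BRET quantification: ratio arithmetic, trace construction, and the three
# nonlinear fits with their derived quantities.

test_that("net BRET subtracts the donor-only ratio", {
  donor <- data.frame(em475 = rep(100, 10), em535 = rep(55, 10))
  sample1 <- data.frame(em475 = rep(100, 10), em535 = rep(60, 10))
  nb <- net_bret(sample1, donor)
  expect_equal(nb$net_bret, 0.05)
  # a condition measured against itself is exactly zero
  expect_equal(net_bret(donor, donor)$net_bret, 0)
  # 10 cycles with ratios 0.50..0.59: mean 0.545, net 0.045
  ramp <- data.frame(em475 = rep(100, 10), em535 = seq(50, 59))
  fixed <- data.frame(em475 = rep(100, 10), em535 = rep(50, 10))
  expect_equal(net_bret(ramp, fixed)$net_bret, 0.045)
  # invariant to cycle order
  expect_equal(net_bret(ramp[sample(10), ], fixed)$net_bret, 0.045)
  # non-positive donor emission rejected with a message
  bad <- rbind(sample1, data.frame(em475 = 0, em535 = 10))
  expect_message(nb2 <- net_bret(bad, donor), "rejected 1")
  expect_equal(nb2$net_bret, 0.05)
  expect_equal(net_venus(c(500, 600), c(100, 100)), c(400, 500))
})

test_that("ligand-induced traces subtract basal and vehicle", {
  tr <- ligand_induced_trace(rep(0.5, 5), c(1, 2, 3), c(0.5, 0.5, 0.5))
  expect_equal(tr$y, c(0, 0, 0))
  tr2 <- ligand_induced_trace(0.5, 1, 0.55)
  expect_equal(tr2$y, 0.05)
  tr3 <- ligand_induced_trace(0.5, c(1, 2), c(0.6, 0.7),
                              vehicle_trace = c(0.01, 0.01))
  expect_equal(tr3$y, c(0.09, 0.19))
  expect_error(ligand_induced_trace(numeric(0), 1, 0.5), "basal")
  expect_error(ligand_induced_trace(0.5, c(2, 1), c(1, 1)), "increasing")
})

test_that("saturation fit recovers noise-free parameters to 1e-6 relative", {
  x <- seq(0.02, 0.6, length.out = 12)
  y <- 0.3 * x / (0.05 + x)
  fit <- fit_saturation(x, y)
  expect_true(fit$converged)
  expect_equal(fit$BRETmax, 0.3, tolerance = 1e-6)
  expect_equal(fit$BRET50, 0.05, tolerance = 1e-6)
  # flat response is flagged degenerate
  flat <- fit_saturation(x, rep(0, 12))
  expect_false(flat$converged)
  expect_equal(flat$BRETmax, 0)
  expect_error(fit_saturation(c(1, 1, 2), c(1, 1, 2)), "distinct")
})

test_that("kinetics fit recovers parameters and derived identities exactly", {
  t <- seq(3, 300, by = 3)
  y <- 0.05 * (1 - exp(-0.02 * t))
  fit <- fit_kinetics(data.frame(time_s = t, y = y))
  expect_true(fit$converged)
  expect_equal(fit$k_per_s, 0.02, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.05, tolerance = 1e-6)
  # derived fields are exact functions of the fitted parameters
  expect_equal(fit$halftime_s * fit$k_per_s, log(2), tolerance = 1e-15)
  expect_identical(fit$initial_rate, fit$k_per_s * fit$span)
  expect_identical(fit$span, fit$plateau - fit$y0)
  # ln(2)/k worked example: k = 0.01 -> halftime 69.31 s
  y2 <- 0.05 * (1 - exp(-0.01 * t))
  fit2 <- fit_kinetics(data.frame(time_s = t, y = y2))
  expect_equal(fit2$halftime_s, 69.31, tolerance = 1e-3)
  # free-y0 variant on a raw (unsubtracted) trace
  fit3 <- fit_kinetics(data.frame(time_s = t, y = y + 0.5), free_y0 = TRUE)
  expect_equal(fit3$y0, 0.5, tolerance = 1e-5)
  expect_equal(fit3$span, 0.05, tolerance = 1e-5)
  t5 <- c(30, 60, 120, 200, 300)  # long enough, but too few points
  expect_warning(fit_kinetics(data.frame(time_s = t5,
                                         y = 0.05 * (1 - exp(-0.02 * t5)))),
                 "fewer than 8")
})

test_that("dose-response fit reports -logEC50 and flags degeneracy", {
  conc <- 10^seq(-8, -3, length.out = 9)
  ec50 <- 10^-5.362
  y <- 10 + (90 - 10) / (1 + ec50 / conc)
  fit <- fit_dose_response(conc, y)
  expect_true(fit$converged)
  expect_equal(fit$neg_log_ec50, 5.362, tolerance = 1e-6)
  expect_equal(fit$Emax, 90, tolerance = 1e-4)
  expect_equal(fit$baseline, 10, tolerance = 1e-4)
  # variable slope recovers a constructed Hill coefficient
  yh <- 10 + 80 / (1 + (ec50 / conc)^1.5)
  fith <- fit_dose_response(conc, yh, variable_slope = TRUE)
  expect_equal(fith$hill, 1.5, tolerance = 1e-3)
  expect_equal(fith$neg_log_ec50, 5.362, tolerance = 1e-3)
  # constant response -> degenerate flag
  expect_false(fit_dose_response(conc, rep(5, 9))$converged)
  expect_error(fit_dose_response(c(1e-6, 2e-6, 3e-6, 4e-6), 1:4),
               "distinct")
})

test_that("bias factors are Emax/EC50 fold changes vs the reference", {
  tab <- data.frame(
    condition = c("WT", "WT", "mutant", "mutant"),
    pathway = c("Gi", "barr2", "Gi", "barr2"),
    Emax = c(100, 50, 100, 75),
    EC50_M = c(1e-9, 1e-5, 1e-9, 5e-6))
  out <- bias_factor(tab, reference = "WT")
  ref_rows <- out$condition == "WT"
  expect_true(all(out$fold_change[ref_rows] == 1))
  barr_mut <- out$fold_change[out$condition == "mutant" &
                              out$pathway == "barr2"]
  expect_equal(barr_mut, (75 / 5e-6) / (50 / 1e-5))  # 3x arrestin bias
  gi_mut <- out$fold_change[out$condition == "mutant" & out$pathway == "Gi"]
  expect_equal(gi_mut, 1)
  # Emax halved, EC50 unchanged: fold change 0.5
  tab2 <- data.frame(condition = c("a", "b"), pathway = "p",
                     Emax = c(100, 50), EC50_M = c(1e-6, 1e-6))
  expect_equal(bias_factor(tab2, "a")$fold_change, c(1, 0.5))
  expect_error(bias_factor(tab2, "missing"), "reference")
})

test_that("noisy simulation round-trips recover parameters (small scale)", {
  # kinetics: 25 seeds, sigma 0.002 -> median halftime near ln2/0.02
  ht <- vapply(1:25, function(s) {
    d <- simulate_bret(bret_sim_config(
      "kinetics", list(k_per_s = 0.02, plateau = 0.05),
      seq(3, 300, 3), noise_sd = 0.002, seed = s))
    fit_kinetics(data.frame(time_s = d$x, y = d$y))$halftime_s
  }, numeric(1))
  expect_lt(abs(median(ht) - log(2) / 0.02) / (log(2) / 0.02), 0.1)
})
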