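test_that("baseline signal averages exactly the requested pre-bolus frames", {
  dm <- c(2, 2, 1)
  sig <- array(500, c(dm, 10))
  ser <- dynamic_series(sig, (0:9) * 7.6, bolus_dynamic = 8, flip_angle = 10, tr = 5)
  expect_equal(baseline_signal(ser), array(500, dm))
  sig2 <- sig
  sig2[1, 1, 1, 1:3] <- c(400, 420, 440)
  ser2 <- dynamic_series(sig2, (0:9) * 7.6, 8, 10, 5)
  expect_equal(baseline_signal(ser2, 1:3)[1, 1, 1], 420)
  # default window covers exactly the 7 pre-bolus frames of a bolus-at-8 series
  counted <- array(0, c(dm, 10))
  counted[, , , 1:7] <- 1
  ser3 <- dynamic_series(counted, (0:9) * 7.6, 8, 10, 5)
  expect_equal(baseline_signal(ser3), array(1, dm))
  expect_error(baseline_signal(ser, 1:8), "before the bolus")
})

test_that("constant signal converts to zero concentration everywhere", {
  dm <- c(3, 3, 2)
  s0 <- spgr_signal(1000, 1.2, 5, 10)
  ser <- dynamic_series(array(s0, c(dm, 20)), (0:19) * 7.6, 8, 10, 5)
  t1m0 <- structure(list(t1 = array(1.2, dm), m0 = array(1000, dm),
                         valid = array(TRUE, dm), tr = 5),
                    class = "t1m0_maps")
  conc <- signal_to_concentration(ser, t1m0)
  expect_lt(max(abs(conc$concentration)), 1e-10)
  expect_equal(conc$n_noninvertible, 0)
})

test_that("conversion inverts the forward model across 0..5 mM", {
  dm <- c(1, 1, 1)
  cfg <- kinetics_config()
  cs <- c(0, 0.05, 0.2, 0.5, 1, 2, 5)
  n_t <- 7 + length(cs)
  r1t <- 1 / 1.2 + cfg$r1 * c(rep(0, 7), cs)
  sig <- array(spgr_signal(1000, 1 / r1t, 5, 10), c(dm, n_t))
  ser <- dynamic_series(sig, (0:(n_t - 1)) * 7.6, 8, 10, 5)
  t1m0 <- structure(list(t1 = array(1.2, dm), m0 = array(1000, dm),
                         valid = array(TRUE, dm), tr = 5),
                    class = "t1m0_maps")
  for (anch in c("baseline", "m0")) {
    conc <- signal_to_concentration(ser, t1m0, cfg = cfg, anchor = anch)
    expect_equal(as.vector(conc$concentration[1, 1, 1, 8:n_t]), cs,
                 tolerance = 1e-6)
  }
})

test_that("recovered concentration is linear in true concentration at small enhancement", {
  dm <- c(1, 1, 1)
  cfg <- kinetics_config()
  cs <- seq(0.001, 0.05, length.out = 20)
  n_t <- 7 + length(cs)
  r1t <- 1 / 1.0 + cfg$r1 * c(rep(0, 7), cs)
  sig <- array(spgr_signal(1000, 1 / r1t, 5, 10), c(dm, n_t))
  ser <- dynamic_series(sig, (0:(n_t - 1)) * 7.6, 8, 10, 5)
  t1m0 <- structure(list(t1 = array(1.0, dm), m0 = array(1000, dm),
                         valid = array(TRUE, dm), tr = 5),
                    class = "t1m0_maps")
  conc <- signal_to_concentration(ser, t1m0, cfg = cfg)
  slope <- coef(lm(as.vector(conc$concentration[1, 1, 1, 8:n_t]) ~ cs))[2]
  expect_equal(unname(slope), 1, tolerance = 0.01)
})

test_that("signal below baseline yields a retained negative concentration", {
  dm <- c(1, 1, 1)
  s0 <- spgr_signal(1000, 1.2, 5, 10)
  sig <- array(s0, c(dm, 10))
  sig[1, 1, 1, 9] <- s0 * 0.98
  ser <- dynamic_series(sig, (0:9) * 7.6, 8, 10, 5)
  t1m0 <- structure(list(t1 = array(1.2, dm), m0 = array(1000, dm),
                         valid = array(TRUE, dm), tr = 5),
                    class = "t1m0_maps")
  conc <- signal_to_concentration(ser, t1m0)
  expect_lt(conc$concentration[1, 1, 1, 9], 0)
  expect_equal(conc$n_noninvertible, 0)
})

test_that("signal above the saturation ceiling is flagged non-invertible", {
  dm <- c(1, 1, 1)
  s0 <- spgr_signal(1000, 1.2, 5, 10)
  sig <- array(s0, c(dm, 10))
  sig[1, 1, 1, 10] <- 1000 * sin(10 * pi / 180) * 1.01  # above M0 sin(theta)
  ser <- dynamic_series(sig, (0:9) * 7.6, 8, 10, 5)
  t1m0 <- structure(list(t1 = array(1.2, dm), m0 = array(1000, dm),
                         valid = array(TRUE, dm), tr = 5),
                    class = "t1m0_maps")
  conc <- signal_to_concentration(ser, t1m0)
  expect_true(is.na(conc$concentration[1, 1, 1, 10]))
  expect_equal(conc$n_noninvertible, 1)
})

test_that("plasma correction divides by 1 - Hct and averaging is order-invariant", {
  dm <- c(5, 5, 2)
  n_t <- 12
  conc <- structure(list(
    concentration = array(1.0, c(dm, n_t)),
    times_min = (0:(n_t - 1)) * 7.6 / 60, bolus_time_min = 7 * 7.6 / 60,
    bolus_dynamic = 8L, n_noninvertible = 0L, anchor = "baseline",
    r1 = 3.5, hematocrit = 0.42), class = "concentration_series")
  mask_all <- array(TRUE, dm)
  v <- extract_vif(conc, mask_all, kinetics_config(hematocrit = 0.42))
  expect_equal(v$cp, rep(1 / (1 - 0.42), n_t), tolerance = 1e-12)
  expect_equal(v$n_roi_voxels, prod(dm))
  # Hct -> 0 limit: plasma equals blood
  v0 <- extract_vif(conc, mask_all, kinetics_config(hematocrit = 1e-9))
  expect_equal(v0$cp, rep(1, n_t), tolerance = 1e-6)
  # 50-voxel mask of identical curves equals a single-voxel mask
  m1 <- array(FALSE, dm); m1[1, 1, 1] <- TRUE
  m50 <- array(FALSE, dm); m50[, , 1] <- TRUE
  expect_equal(extract_vif(conc, m50)$cp, extract_vif(conc, m1)$cp)
  # plasma correction strictly increases concentration for Hct in (0,1)
  for (h in c(0.1, 0.42, 0.9))
    expect_true(all(extract_vif(conc, m1, kinetics_config(hematocrit = h))$cp > 1))
  expect_error(extract_vif(conc, array(FALSE, dm)), "empty")
})

test_that("series validation rejects non-uniform or non-increasing time grids", {
  sig <- array(1, c(2, 2, 1, 5))
  expect_error(dynamic_series(sig, c(0, 1, 2, 3, 10), 2, 10, 5), "uniform")
  expect_error(dynamic_series(sig, c(0, 1, 1, 2, 3), 2, 10, 5), "increasing")
  expect_error(dynamic_series(sig, (0:4) * 7.6, 1, 10, 5), "bolus")
})
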