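make_vif <- function(cp, dt_min = 7.6 / 60, bolus = 8L) {
  structure(list(cp = cp, times_min = (seq_along(cp) - 1) * dt_min,
                 bolus_dynamic = bolus, n_roi_voxels = 50L,
                 hematocrit_used = 0.42), class = "vif_curve")
}

test_that("regressor integral is exact for constant and zero input", {
  n <- 20
  # constant cp = 1 from t = 0 (bolus at frame 1 ~ t = 0): integral = t
  vif1 <- make_vif(rep(1, n), dt_min = 0.1, bolus = 1L)
  reg <- build_regressors(vif1, fit_window = 1:n)
  expect_equal(reg$cp_integral, (0:(n - 1)) * 0.1, tolerance = 1e-12)
  reg0 <- build_regressors(make_vif(rep(0, n)), fit_window = 8:n)
  expect_true(all(reg0$cp == 0) && all(reg0$cp_integral == 0))
})

test_that("trapezoid integral of a biexponential input matches the closed form", {
  p <- aif_params(onset_time = 0)
  t <- seq(0, 30, by = 7.6 / 60)
  vif <- make_vif(population_aif(t, p), dt_min = 7.6 / 60, bolus = 1L)
  vif$bolus_dynamic <- 1L
  reg <- build_regressors(vif, fit_window = seq_along(t))
  exact <- population_aif_integral(p, 30)
  expect_lt(abs(reg$cp_integral[length(t)] - exact) / exact, 0.005)
})

test_that("curves inside the model's column space are fitted exactly", {
  t <- (0:159) * 7.6 / 60
  cp <- population_aif(t, aif_params())
  vif <- make_vif(cp)
  reg <- build_regressors(vif)
  ct <- 0.02 * reg$cp + 0.001 * reg$cp_integral
  fit <- patlak_fit_voxel(ct, reg)
  expect_equal(fit$vp, 0.02, tolerance = 1e-10)
  expect_equal(fit$ktrans, 0.001, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # zero-leakage voxel
  fit0 <- patlak_fit_voxel(0.015 * reg$cp, reg)
  expect_lt(abs(fit0$ktrans), 1e-10)
  expect_equal(fit0$vp, 0.015, tolerance = 1e-10)
})

test_that("estimates are scale-equivariant in a common concentration factor", {
  t <- (0:159) * 7.6 / 60
  vif <- make_vif(population_aif(t, aif_params()))
  reg <- build_regressors(vif)
  set.seed(2)
  ct <- 0.02 * reg$cp + 0.001 * reg$cp_integral + rnorm(160, 0, 0.01)
  f1 <- patlak_fit_voxel(ct, reg)
  vif2 <- make_vif(3 * vif$cp)
  f2 <- patlak_fit_voxel(3 * ct, build_regressors(vif2))
  expect_equal(f1$ktrans, f2$ktrans, tolerance = 1e-10)
  expect_equal(f1$vp, f2$vp, tolerance = 1e-10)
})

test_that("linear solution matches nonlinear least squares on random noiseless curves", {
  skip_if_not_installed("minpack.lm")
  t <- (0:159) * 7.6 / 60
  vif <- make_vif(population_aif(t, aif_params()))
  reg <- build_regressors(vif)
  set.seed(10)
  for (i in 1:100) {
    vp_true <- runif(1, 0.001, 0.06)
    kt_true <- runif(1, 1e-4, 8e-3)
    ct <- vp_true * reg$cp + kt_true * reg$cp_integral
    fit <- patlak_fit_voxel(ct, reg)
    w <- reg$fit_window
    nls_fit <- minpack.lm::nlsLM(
      y ~ vp * x1 + kt * x2,
      data = list(y = ct[w], x1 = reg$cp[w], x2 = reg$cp_integral[w]),
      start = list(vp = 0.01, kt = 1e-3))
    expect_equal(fit$vp, unname(coef(nls_fit)["vp"]), tolerance = 1e-8)
    expect_equal(fit$ktrans, unname(coef(nls_fit)["kt"]), tolerance = 1e-8)
    expect_equal(fit$vp, vp_true, tolerance = 1e-8)
    expect_equal(fit$ktrans, kt_true, tolerance = 1e-8)
  }
})

test_that("OLS solution beats every point of a brute-force grid in SSE", {
  t <- (0:159) * 7.6 / 60
  vif <- make_vif(population_aif(t, aif_params()))
  reg <- build_regressors(vif)
  w <- reg$fit_window
  set.seed(3)
  ct <- 0.02 * reg$cp + 3e-3 * reg$cp_integral + rnorm(160, 0, 0.02)
  fit <- patlak_fit_voxel(ct, reg)
  sse <- function(vp, kt)
    sum((ct[w] - vp * reg$cp[w] - kt * reg$cp_integral[w])^2)
  sse_fit <- sse(fit$vp, fit$ktrans)
  grid_vp <- seq(0.01, 0.03, length.out = 201)
  grid_kt <- seq(1.5e-3, 4.5e-3, length.out = 201)
  grid_min <- min(outer(grid_vp, grid_kt, Vectorize(sse)))
  expect_lte(sse_fit, grid_min + 1e-15)
})

test_that("degenerate designs and short windows are reported, not fitted", {
  vif <- make_vif(rep(0, 20))
  reg <- build_regressors(vif, fit_window = 8:20)
  fit <- patlak_fit_voxel(rep(0.1, 20), reg)
  expect_true(is.na(fit$ktrans))
  expect_match(fit$reason, "degenerate")
  expect_error(build_regressors(vif, fit_window = 8:9), "at least 3")
  expect_error(build_regressors(vif, fit_window = 5:20), "bolus")
})

test_that("volume fitting is voxel-order independent and NA outside the mask", {
  ph <- generate_phantom(single_tissue_spec(grid = c(4, 4, 2)))
  t1m0 <- fit_vfa_t1(ph$vfa, ph$b1_map)
  conc <- signal_to_concentration(ph$dynamic, t1m0, ph$b1_map)
  vif <- clean_vif()
  mask <- array(TRUE, c(4, 4, 2)); mask[1, 1, 1] <- FALSE
  maps <- fit_volume(conc, vif, mask)
  expect_true(is.na(maps$ktrans[1, 1, 1]))
  expect_false(any(maps$ktrans[mask] == 0))
  # permuting voxels: fit a voxel standalone and compare to the volume fit
  reg <- build_regressors(vif)
  single <- patlak_fit_voxel(conc$concentration[2, 3, 1, ], reg)
  expect_equal(maps$ktrans[2, 3, 1], single$ktrans, tolerance = 1e-12)
  expect_equal(maps$vp[2, 3, 1], single$vp, tolerance = 1e-12)
})

test_that("voxels with missing frames fall back to their finite frames", {
  ph <- generate_phantom(single_tissue_spec(grid = c(2, 2, 1)))
  t1m0 <- fit_vfa_t1(ph$vfa, ph$b1_map)
  conc <- signal_to_concentration(ph$dynamic, t1m0, ph$b1_map)
  conc$concentration[1, 1, 1, 20:30] <- NA
  maps <- fit_volume(conc, clean_vif(), array(TRUE, c(2, 2, 1)))
  expect_equal(maps$ktrans[1, 1, 1], 3e-3, tolerance = 1e-6)
})

test_that("subject QC applies the declared physiological rules in order", {
  ph <- generate_phantom(single_tissue_spec(grid = c(4, 4, 2), vp = 0.03))
  t1m0 <- fit_vfa_t1(ph$vfa, ph$b1_map)
  conc <- signal_to_concentration(ph$dynamic, t1m0, ph$b1_map)
  maps <- fit_volume(conc, clean_vif(), array(TRUE, c(4, 4, 2)))
  maps <- subject_qc(maps)
  expect_equal(maps$qc$verdict, "pass")
  bad <- maps; bad$vp[] <- 2.0
  expect_equal(subject_qc(bad)$qc$verdict, "fail")
  expect_match(subject_qc(bad)$qc$reason, "vp>1 fraction")
  zero <- maps; zero$vp[] <- 0
  expect_equal(subject_qc(zero)$qc$verdict, "fail")
  expect_match(subject_qc(zero)$qc$reason, "median vp")
})

test_that("estimation error shrinks monotonically with SNR through the full chain", {
  vif <- clean_vif()
  ph0 <- generate_phantom(single_tissue_spec(grid = c(8, 8, 4)))
  t1m0 <- fit_vfa_t1(ph0$vfa, ph0$b1_map)
  med_err <- function(snr) {
    ph <- generate_phantom(single_tissue_spec(grid = c(8, 8, 4),
                                              noise_model = "rician",
                                              snr = snr, seed = 42))
    conc <- signal_to_concentration(ph$dynamic, t1m0, ph$b1_map, anchor = "m0")
    maps <- fit_volume(conc, vif, array(TRUE, c(8, 8, 4)))
    c(kt = median(abs(maps$ktrans - 3e-3) / 3e-3, na.rm = TRUE),
      vp = median(abs(maps$vp - 0.02) / 0.02, na.rm = TRUE))
  }
  e10 <- med_err(10); e20 <- med_err(20); e50 <- med_err(50)
  expect_true(all(e50 < e20) && all(e20 < e10))
})
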