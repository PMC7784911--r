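#' Dynamic contrast-enhanced series
#'
#' Container for the 4D dynamic signal, its time grid and the acquisition
#' parameters needed by the relaxometric conversion. Times are stored in
#' seconds from the start of the series; kinetic quantities downstream are
#' expressed in minutes.
#'
#' @param signal 4D numeric array (x, y, z, t).
#' @param times Frame times in seconds, strictly increasing, uniformly
#'   spaced to within 1%.
#' @param bolus_dynamic 1-based index of the injection frame (>= 2).
#' @param flip_angle Nominal flip angle of the dynamic acquisition, degrees.
#' @param tr Repetition time, ms.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(signal, times, bolus_dynamic, flip_angle, tr) {
  stopifnot(length(dim(signal)) == 4)
  if (dim(signal)[4] != length(times))
    stop("time grid length does not match the 4th array dimension")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  dts <- diff(times)
  if (length(dts) && (max(dts) - min(dts)) / mean(dts) > 0.01)
    stop("frame spacing must be uniform to within 1%")
  if (bolus_dynamic < 2) stop("bolus_dynamic must be >= 2")
  structure(list(signal = signal, times = times,
                 bolus_dynamic = as.integer(bolus_dynamic),
                 flip_angle = flip_angle, tr = tr),
            class = "dynamic_series")
}

#' Kinetic conversion settings
#'
#' @param r1 Longitudinal relaxivity of the contrast agent, 1/s per mM.
#'   Default 3.5, typical of gadoterate at 3 T; concentrations (and hence
#'   Ktrans and vp) scale inversely with this value, so it is recorded in
#'   all outputs.
#' @param hematocrit Haematocrit fraction in (0, 1); converts whole-blood to
#'   plasma concentration. Default 0.42.
#' @param baseline_window Pre-contrast frame indices used for the baseline
#'   signal; default all frames before the bolus dynamic.
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(r1 = 3.5, hematocrit = 0.42,
                            baseline_window = NULL) {
  if (r1 <= 0) stop("r1 must be positive")
  if (hematocrit <= 0 || hematocrit >= 1) stop("hematocrit must be in (0, 1)")
  structure(list(r1 = r1, hematocrit = hematocrit,
                 baseline_window = baseline_window),
            class = "kinetics_config")
}

#' Voxelwise pre-contrast baseline signal
#'
#' Mean of the dynamic signal over the pre-bolus frames.
#'
#' @param series A [dynamic_series()].
#' @param window Frame indices to average; default `1..bolus_dynamic - 1`.
#'   Must lie strictly before the bolus dynamic.
#' @return 3D array of baseline signal.
#' @export
baseline_signal <- function(series, window = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  if (is.null(window)) window <- seq_len(series$bolus_dynamic - 1)
  if (length(window) == 0) stop("baseline window is empty")
  if (any(window >= series$bolus_dynamic))
    stop("baseline window must lie strictly before the bolus dynamic")
  sub <- series$signal[, , , window, drop = FALSE]
  apply(sub, 1:3, mean)
}

#' Convert dynamic signal to contrast-agent concentration
#'
#' Inverts the spoiled-gradient-echo equation frame by frame. The effective
#' equilibrium signal of the dynamic acquisition is anchored per voxel so
#' that the model reproduces the measured baseline signal at
#' \eqn{R_1 = 1/T_{1,pre}}; each frame's signal is then solved for
#' \eqn{E_1}, giving \eqn{R_1(t)} and
#' \eqn{C(t) = (R_1(t) - R_{1,pre})/r_1}. Signals at or above the SPGR
#' saturation ceiling (or implying non-positive \eqn{R_1}) are flagged
#' non-invertible and returned as `NA`, with a per-volume count in the
#' result. Signals below baseline yield negative concentrations, which are
#' retained, not clipped.
#'
#' @param series A [dynamic_series()].
#' @param t1m0 A `t1m0_maps` object from [fit_vfa_t1()] on the same grid.
#' @param b1 3D transmit-field scale array or scalar.
#' @param cfg A [kinetics_config()].
#' @param anchor `"baseline"` (default) scales the signal model per voxel so
#'   it reproduces the measured pre-bolus signal — robust to a gain
#'   difference between the variable-flip-angle and dynamic acquisitions,
#'   at the cost that the noise of the few baseline frames propagates into
#'   every frame's concentration as a common-mode error. `"m0"` uses the
#'   fitted M0 map directly, which assumes one shared scanner gain and
#'   isolates the per-frame noise.
#' @return An object of class `concentration_series`: list with 4D array
#'   `concentration` (mM, `NA` where invalid/non-invertible), `times_min`,
#'   `bolus_time_min`, `bolus_dynamic`, `n_noninvertible`, and the
#'   conversion settings used.
#' @export
signal_to_concentration <- function(series, t1m0, b1 = 1, cfg = kinetics_config(),
                                    anchor = c("baseline", "m0")) {
  stopifnot(inherits(series, "dynamic_series"), inherits(t1m0, "t1m0_maps"),
            inherits(cfg, "kinetics_config"))
  anchor <- match.arg(anchor)
  dm <- dim(series$signal)[1:3]
  if (!identical(dim(t1m0$t1), dm)) stop("T1/M0 maps and series are on different grids")
  if (length(b1) == 1) b1 <- array(b1, dm)
  if (!identical(dim(b1), dm)) stop("b1 map and series are on different grids")

  window <- cfg$baseline_window
  if (is.null(window)) window <- seq_len(series$bolus_dynamic - 1)
  s0 <- baseline_signal(series, window)

  nv <- prod(dm); n_t <- dim(series$signal)[4]
  theta <- effective_flip(series$flip_angle, as.vector(b1)) * pi / 180
  tr_s <- series$tr / 1000
  t1pre <- as.vector(t1m0$t1)
  ok <- as.vector(t1m0$valid) & is.finite(as.vector(s0)) & as.vector(s0) > 0

  if (anchor == "baseline") {
    # unit-M0 SPGR shape at the dynamic flip/TR, per voxel
    shape <- rep(NA_real_, nv)
    shape[ok] <- spgr_signal(1, t1pre[ok], series$tr, series$flip_angle,
                             as.vector(b1)[ok])
    m0_dyn <- as.vector(s0) / shape         # NA where !ok
  } else {
    ok <- as.vector(t1m0$valid) & is.finite(as.vector(t1m0$m0))
    m0_dyn <- as.vector(t1m0$m0)
    m0_dyn[!ok] <- NA_real_
  }

  sig <- matrix(series$signal, nv, n_t)
  a <- m0_dyn * sin(theta)                  # saturation ceiling
  e1 <- (a - sig) / (a - sig * cos(theta))  # recycled per column
  invertible <- ok & is.finite(e1) & e1 > 0 & e1 < 1
  r1t <- matrix(NA_real_, nv, n_t)
  r1t[invertible] <- -log(e1[invertible]) / tr_s
  conc <- (r1t - 1 / t1pre) / cfg$r1        # mM; NA propagates

  structure(list(
    concentration = array(conc, c(dm, n_t)),
    times_min = series$times / 60,
    bolus_time_min = series$times[series$bolus_dynamic] / 60,
    bolus_dynamic = series$bolus_dynamic,
    n_noninvertible = sum(ok & !invertible[, seq_len(n_t)]),
    anchor = anchor, r1 = cfg$r1, hematocrit = cfg$hematocrit
  ), class = "concentration_series")
}

#' Extract the vascular input function from a venous region
#'
#' Averages the voxelwise blood concentration curves over the supplied mask
#' (conversion first, averaging second) and divides by \eqn{1 - Hct} to
#' obtain the plasma concentration driving the kinetic model.
#'
#' @param conc A `concentration_series` from [signal_to_concentration()].
#' @param sinus_mask Logical 3D array selecting the venous voxels.
#' @param cfg A [kinetics_config()] providing the haematocrit.
#' @return An object of class `vif_curve`: list with `cp` (plasma
#'   concentration, mM), `times_min`, `bolus_dynamic`, `n_roi_voxels` and
#'   `hematocrit_used`.
#' @export
extract_vif <- function(conc, sinus_mask, cfg = kinetics_config()) {
  stopifnot(inherits(conc, "concentration_series"))
  dm <- dim(conc$concentration)[1:3]
  if (!identical(dim(sinus_mask), dm)) stop("sinus mask and series are on different grids")
  n <- sum(sinus_mask)
  if (n == 0) stop("sinus mask is empty")
  n_t <- dim(conc$concentration)[4]
  m <- matrix(conc$concentration, prod(dm), n_t)[as.vector(sinus_mask), , drop = FALSE]
  frac_bad <- rowMeans(is.na(m))
  if (any(frac_bad > 0.5))
    stop(sum(frac_bad > 0.5),
         " sinus voxel(s) non-invertible in more than half of the frames")
  cb <- colMeans(m, na.rm = TRUE)
  structure(list(cp = cb / (1 - cfg$hematocrit),
                 times_min = conc$times_min,
                 bolus_dynamic = conc$bolus_dynamic,
                 n_roi_voxels = n,
                 hematocrit_used = cfg$hematocrit),
            class = "vif_curve")
}

#' Write a vascular input function to CSV with a JSON sidecar
#'
#' @param vif A `vif_curve`.
#' @param path CSV path (`time_min`, `cp_mM` columns); the sidecar takes the
#'   same path with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_vif <- function(vif, path) {
  stopifnot(inherits(vif, "vif_curve"))
  utils::write.csv(data.frame(time_min = vif$times_min, cp_mM = vif$cp),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(n_roi_voxels = vif$n_roi_voxels,
         hematocrit_used = vif$hematocrit_used,
         bolus_dynamic = vif$bolus_dynamic),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
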