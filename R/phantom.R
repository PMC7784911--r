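#' Default tissue table for the digital phantom
#'
#' One row per tissue label with pre-contrast T1 (s), equilibrium signal M0
#' (arbitrary units), Ktrans (1/min) and plasma volume fraction vp. Labels
#' 1..8 are the canonical analysis regions (substantia nigra, caudate,
#' putamen, pallidum, white-matter lesions, normal-appearing white matter,
#' frontal and posterior cortex); label 9 is venous blood carrying the pure
#' input-function signal. T1 values are typical at 3 T; Ktrans and vp sit in
#' the low-leakage range reported for intact and mildly disrupted
#' blood-brain barrier.
#'
#' @return A data frame with columns `label`, `name`, `t1`, `m0`, `ktrans`,
#'   `vp`.
#' @export
phantom_tissues <- function() {
  data.frame(
    label  = 1:9,
    name   = c("SN", "CA", "PU", "P", "WML", "NAWM", "FC", "PC", "blood"),
    t1     = c(1.20, 1.40, 1.30, 1.10, 1.30, 1.00, 1.45, 1.45, 1.65),
    m0     = c(1000, 1050, 1020, 980, 1040, 950, 1060, 1060, 1100),
    ktrans = c(3.5e-3, 3.0e-3, 3.0e-3, 2.5e-3, 4.0e-3, 2.0e-3, 3.5e-3, 3.5e-3, 0),
    vp     = c(0.012, 0.015, 0.012, 0.008, 0.007, 0.006, 0.018, 0.018, 1),
    stringsAsFactors = FALSE
  )
}

#' Specification of a digital DCE-MRI phantom
#'
#' Bundles acquisition geometry and timing, the tissue parameter table, the
#' input-function parameters and the noise model used by
#' [generate_phantom()]. Defaults reproduce the acquisition this package
#' models: 160 dynamics at 7.6 s temporal resolution with the bolus on the
#' 8th dynamic, pre-contrast images at flip angles 2, 5 and 10 degrees, and
#' 1.5 x 1.5 x 4 mm voxels.
#'
#' @param grid_shape Voxels per axis (length 3).
#' @param voxel_size Voxel edge lengths in mm (length 3).
#' @param n_dynamics Number of dynamic frames.
#' @param dt Temporal resolution in seconds.
#' @param bolus_dynamic 1-based index of the frame on which the bolus is
#'   injected; frames `1..bolus_dynamic - 1` are pre-contrast.
#' @param flip_angles Nominal flip angles of the pre-contrast variable-flip-
#'   angle stack, degrees.
#' @param dynamic_flip Nominal flip angle of the dynamic series, degrees.
#' @param tr Repetition time in ms (shared by VFA and dynamic series; the
#'   acquisition protocol does not pin this down publicly, so it is a
#'   configurable input everywhere).
#' @param tissues Tissue table as from [phantom_tissues()].
#' @param label_map Optional integer 3D array of tissue labels (0 =
#'   background/air). Default: [phantom_label_map()] on `grid_shape`.
#' @param vif_label Label carrying pure blood signal.
#' @param b1 Transmit-field scale: scalar or 3D array.
#' @param aif [aif_params()] driving the simulation.
#' @param r1 Contrast-agent longitudinal relaxivity, 1/s per mM.
#' @param hematocrit Haematocrit fraction used to convert the blood curve to
#'   plasma concentration in the tissue forward model.
#' @param noise_model One of "none", "gaussian", "rician".
#' @param snr Signal-to-noise ratio of the mean pre-contrast tissue signal;
#'   required when noise is enabled.
#' @param seed Integer seed making noisy phantoms reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(20, 20, 8),
                         voxel_size = c(1.5, 1.5, 4),
                         n_dynamics = 160,
                         dt = 7.6,
                         bolus_dynamic = 8,
                         flip_angles = c(2, 5, 10),
                         dynamic_flip = 10,
                         tr = 5,
                         tissues = phantom_tissues(),
                         label_map = NULL,
                         vif_label = 9,
                         b1 = 1,
                         aif = NULL,
                         r1 = 3.5,
                         hematocrit = 0.42,
                         noise_model = c("none", "gaussian", "rician"),
                         snr = NULL,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_dynamics < bolus_dynamic || bolus_dynamic < 2)
    stop("need n_dynamics >= bolus_dynamic >= 2")
  if (any(tissues$vp < 0 | tissues$vp > 1))
    stop("per-tissue vp must lie in [0, 1]")
  if (noise_model != "none" && (is.null(snr) || snr <= 0))
    stop("snr must be > 0 when noise is enabled")
  if (is.null(aif)) aif <- aif_params(onset_time = (bolus_dynamic - 1) * dt / 60)
  if (is.null(label_map)) label_map <- phantom_label_map(grid_shape)
  structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size,
    n_dynamics = n_dynamics, dt = dt, bolus_dynamic = bolus_dynamic,
    flip_angles = flip_angles, dynamic_flip = dynamic_flip, tr = tr,
    tissues = tissues, label_map = label_map, vif_label = vif_label,
    b1 = b1, aif = aif, r1 = r1, hematocrit = hematocrit,
    noise_model = noise_model, snr = snr, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Default phantom label geometry
#'
#' Partitions the grid into eight tissue slabs along x (labels 1..8) and
#' overwrites a 5 x 5 x 2 corner block with the blood label 9 (about the
#' 50-voxel size of a hand-drawn venous region). Columns beyond the eight
#' slabs fall to normal-appearing white matter (label 6).
#'
#' @param grid_shape Voxels per axis (length 3).
#' @return Integer 3D array of labels.
#' @export
phantom_label_map <- function(grid_shape = c(20, 20, 8)) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= c(8, 5, 2)))
  lab <- array(6L, dim = grid_shape)
  slab <- pmin(8L, as.integer(ceiling(seq_len(grid_shape[1]) / (grid_shape[1] / 8))))
  for (i in seq_len(grid_shape[1])) lab[i, , ] <- slab[i]
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  lab[(nx - 4):nx, (ny - 4):ny, (nz - 1):nz] <- 9L
  lab
}

#' Generate a digital DCE-MRI phantom
#'
#' Simulates, per tissue label, the uptake-model tissue concentration
#' \deqn{C_t(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(\tau)\,d\tau}
#' with \eqn{C_p = C_b / (1 - \mathrm{Hct})} derived from the population
#' blood curve, maps concentration to longitudinal relaxation rate via
#' \eqn{R_1(t) = 1/T_1 + r_1 C(t)}, and synthesises all signals through the
#' spoiled-gradient-echo forward model. The blood label carries the pure
#' whole-blood concentration. Optional Gaussian or Rician noise is added to
#' every VFA and dynamic frame with standard deviation equal to the mean
#' pre-contrast tissue signal divided by `snr`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_dataset`: list with `vfa`
#'   ([vfa_stack()]), `b1_map`, `dynamic` ([dynamic_series()]), truth arrays
#'   `truth_ktrans`, `truth_vp`, `truth_t1`, `truth_m0`, the `label_map`,
#'   tissue `rois` (named list of logical masks), and a `manifest` of
#'   acquisition metadata.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  lab <- spec$label_map
  if (!identical(dim(lab), as.integer(dm)) && !identical(dim(lab), dm))
    stop("label_map grid does not match grid_shape")
  used <- sort(unique(as.vector(lab)))
  used <- used[used != 0]
  missing_lab <- setdiff(used, spec$tissues$label)
  if (length(missing_lab))
    stop("label(s) in label_map absent from tissue table: ",
         paste(missing_lab, collapse = ", "))

  b1 <- if (length(spec$b1) == 1) array(spec$b1, dm) else spec$b1
  if (!identical(dim(b1), dim(lab))) stop("b1 grid does not match label_map")

  # truth maps from the tissue table
  idx <- match(as.vector(lab), spec$tissues$label)
  truth_t1 <- array(spec$tissues$t1[idx], dm)
  truth_m0 <- array(spec$tissues$m0[idx], dm)
  truth_kt <- array(spec$tissues$ktrans[idx], dm)
  truth_vp <- array(spec$tissues$vp[idx], dm)

  times_s <- (seq_len(spec$n_dynamics) - 1) * spec$dt
  t_min <- times_s / 60
  cb <- population_aif(t_min, spec$aif)
  cp <- cb / (1 - spec$hematocrit)
  cp_int <- as.vector(pracma::cumtrapz(t_min, cp))

  # per-label concentration curves, then per-label signal curves
  n_t <- spec$n_dynamics
  conc_by_label <- lapply(seq_len(nrow(spec$tissues)), function(i) {
    row <- spec$tissues[i, ]
    if (row$label == spec$vif_label) cb
    else row$vp * cp + row$ktrans * cp_int
  })
  names(conc_by_label) <- as.character(spec$tissues$label)

  sig4d <- array(0, c(dm, n_t))
  inbrain <- as.vector(lab) != 0
  b1v <- as.vector(b1)
  for (i in seq_len(nrow(spec$tissues))) {
    row <- spec$tissues[i, ]
    sel <- as.vector(lab) == row$label
    if (!any(sel)) next
    conc <- conc_by_label[[as.character(row$label)]]
    r1t <- 1 / row$t1 + spec$r1 * conc            # 1/s, length n_t
    for (k in seq_len(n_t)) {
      frame <- spgr_signal(row$m0, 1 / r1t[k], spec$tr, spec$dynamic_flip,
                           b1v[sel])
      sigk <- sig4d[, , , k, drop = FALSE]
      sigk[sel] <- frame
      sig4d[, , , k] <- sigk
    }
  }

  vfa_arrays <- lapply(spec$flip_angles, function(a) {
    v <- numeric(prod(dm))
    v[inbrain] <- spgr_signal(truth_m0[inbrain], truth_t1[inbrain],
                              spec$tr, a, b1v[inbrain])
    array(v, dm)
  })

  if (spec$noise_model != "none") {
    set.seed(spec$seed)
    baseline <- sig4d[, , , seq_len(spec$bolus_dynamic - 1), drop = FALSE]
    sigma <- mean(baseline[rep(inbrain, spec$bolus_dynamic - 1)]) / spec$snr
    add_noise <- function(x) {
      if (spec$noise_model == "gaussian") {
        x + stats::rnorm(length(x), 0, sigma)
      } else {
        sqrt((x + stats::rnorm(length(x), 0, sigma))^2 +
               stats::rnorm(length(x), 0, sigma)^2)
      }
    }
    sig4d <- array(add_noise(sig4d), dim = dim(sig4d))
    vfa_arrays <- lapply(vfa_arrays, function(a) array(add_noise(a), dim = dm))
  } else {
    sigma <- 0
  }

  rois <- lapply(seq_len(nrow(spec$tissues)), function(i)
    array(as.vector(lab) == spec$tissues$label[i], dm))
  names(rois) <- spec$tissues$name

  manifest <- list(
    n_dynamics = spec$n_dynamics, dt_s = spec$dt,
    total_duration_s = spec$n_dynamics * spec$dt,
    bolus_dynamic = spec$bolus_dynamic,
    flip_angles_deg = spec$flip_angles, dynamic_flip_deg = spec$dynamic_flip,
    tr_ms = spec$tr, voxel_size_mm = spec$voxel_size,
    r1 = spec$r1, hematocrit = spec$hematocrit,
    noise_model = spec$noise_model, snr = spec$snr, noise_sigma = sigma,
    seed = spec$seed
  )

  structure(list(
    vfa = vfa_stack(vfa_arrays, spec$flip_angles, spec$tr),
    b1_map = b1,
    dynamic = dynamic_series(sig4d, times_s, spec$bolus_dynamic,
                             spec$dynamic_flip, spec$tr),
    truth_ktrans = truth_kt, truth_vp = truth_vp,
    truth_t1 = truth_t1, truth_m0 = truth_m0,
    label_map = lab, rois = rois, manifest = manifest, spec = spec
  ), class = "phantom_dataset")
}

#' Write a phantom to disk as NIfTI volumes plus sidecars
#'
#' Writes the 4D dynamic series, one volume per flip angle, the B1 map, the
#' truth parameter maps and the label map as compressed NIfTI-1 files, the
#' acquisition manifest as JSON, and returns the file paths. The layout
#' matches what [run_subject()] consumes.
#'
#' @param phantom A `phantom_dataset` from [generate_phantom()].
#' @param dir Output directory (created if absent).
#' @return Named list of file paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$manifest$voxel_size_mm
  wr <- function(img, name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = vs), path)
    path
  }
  paths <- list(dynamic = wr(phantom$dynamic$signal, "dynamic"),
                b1 = wr(phantom$b1_map, "b1"),
                label_map = wr(phantom$label_map, "labels"),
                truth_ktrans = wr(phantom$truth_ktrans, "truth_ktrans"),
                truth_vp = wr(phantom$truth_vp, "truth_vp"),
                truth_t1 = wr(phantom$truth_t1, "truth_t1"))
  for (j in seq_along(phantom$vfa$flip_angles)) {
    nm <- paste0("vfa_", phantom$vfa$flip_angles[j], "deg")
    paths[[nm]] <- wr(phantom$vfa$signals[[j]], nm)
  }
  paths$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(phantom$manifest, paths$manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
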