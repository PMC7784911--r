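#' Spoiled-gradient-echo steady-state signal
#'
#' Signal of an ideally spoiled gradient-recalled echo (T1-FFE / SPGR / FLASH)
#' acquisition:
#' \deqn{S = M_0 \sin(b_1\alpha)\,\frac{1 - E_1}{1 - \cos(b_1\alpha)\,E_1},
#'       \qquad E_1 = e^{-TR/T_1}}
#' All arguments are vectorised and recycled against each other.
#'
#' @param m0 Equilibrium signal (arbitrary units).
#' @param t1 Longitudinal relaxation time in seconds; must be positive.
#' @param tr Repetition time in milliseconds; must be positive.
#' @param alpha Nominal flip angle in degrees.
#' @param b1 Transmit-field scale (actual/nominal flip-angle ratio; 1 = nominal).
#' @return Signal in the units of `m0`.
#' @export
spgr_signal <- function(m0, t1, tr, alpha, b1 = 1) {
  if (any(t1 <= 0)) stop("t1 must be positive")
  if (any(tr <= 0)) stop("tr must be positive")
  theta <- effective_flip(alpha, b1) * pi / 180
  e1 <- exp(-(tr / 1000) / t1)
  m0 * sin(theta) * (1 - e1) / (1 - cos(theta) * e1)
}

#' Effective flip angle after transmit-field correction
#'
#' @param alpha_nominal Nominal flip angle in degrees.
#' @param b1 Transmit-field scale; must be positive.
#' @return Actual flip angle in degrees, `alpha_nominal * b1`.
#' @export
effective_flip <- function(alpha_nominal, b1) {
  if (any(b1 <= 0)) stop("b1 must be positive")
  alpha_nominal * b1
}

#' Variable-flip-angle image stack
#'
#' Container for pre-contrast spoiled-gradient-echo images acquired at two or
#' more nominal flip angles with a common repetition time, the input of
#' [fit_vfa_t1()].
#'
#' @param signals List of 3D numeric arrays, one per flip angle, on a common
#'   voxel grid.
#' @param flip_angles Nominal flip angles in degrees, one per array.
#' @param tr Repetition time in milliseconds.
#' @return An object of class `vfa_stack`.
#' @export
vfa_stack <- function(signals, flip_angles, tr) {
  if (length(signals) != length(flip_angles))
    stop("one signal array per flip angle is required")
  if (length(unique(flip_angles)) < 2)
    stop("at least two distinct flip angles are required")
  dims <- lapply(signals, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all flip-angle volumes must share one voxel grid")
  if (tr <= 0) stop("tr must be positive")
  structure(list(signals = signals, flip_angles = flip_angles, tr = tr),
            class = "vfa_stack")
}

#' Voxelwise pre-contrast T1 and M0 from variable-flip-angle data
#'
#' Linearised two-parameter fit (DESPOT1): for each voxel the points
#' \eqn{y = S/\sin\theta} against \eqn{x = S/\tan\theta}, with \eqn{\theta}
#' the B1-corrected flip angle, lie on a line of slope \eqn{E_1 = e^{-TR/T_1}}
#' and intercept \eqn{M_0 (1 - E_1)}. Voxels whose fitted slope falls outside
#' (0, 1) — including all-zero voxels — are flagged invalid rather than
#' clamped; downstream kinetic fitting skips them.
#'
#' @param stack A [vfa_stack()].
#' @param b1 3D transmit-field scale array on the stack grid (or a scalar).
#' @param mask Optional logical 3D array; voxels outside are left `NA`/invalid.
#' @return An object of class `t1m0_maps`: list with 3D arrays `t1` (seconds),
#'   `m0` (signal units), logical `valid`, and the repetition time `tr` (ms).
#' @export
fit_vfa_t1 <- function(stack, b1 = 1, mask = NULL) {
  stopifnot(inherits(stack, "vfa_stack"))
  dm <- dim(stack$signals[[1]])
  if (length(b1) == 1) b1 <- array(b1, dm)
  if (!identical(dim(b1), dm)) stop("b1 map grid does not match the VFA stack")
  if (is.null(mask)) mask <- array(TRUE, dm)
  if (!identical(dim(mask), dm)) stop("mask grid does not match the VFA stack")

  n_ang <- length(stack$flip_angles)
  nv <- prod(dm)
  theta <- matrix(0, nv, n_ang)  # radians, B1-corrected, per voxel x angle
  s <- matrix(0, nv, n_ang)
  for (j in seq_len(n_ang)) {
    theta[, j] <- effective_flip(stack$flip_angles[j], as.vector(b1)) * pi / 180
    s[, j] <- as.vector(stack$signals[[j]])
  }
  y <- s / sin(theta)
  x <- s / tan(theta)
  # per-voxel simple linear regression, closed form
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  denom <- n_ang * sxx - sx^2
  slope <- (n_ang * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / n_ang

  valid <- as.vector(mask) & is.finite(slope) & slope > 0 & slope < 1
  t1 <- rep(NA_real_, nv)
  m0 <- rep(NA_real_, nv)
  tr_s <- stack$tr / 1000
  t1[valid] <- -tr_s / log(slope[valid])
  m0[valid] <- intercept[valid] / (1 - slope[valid])
  bad_m0 <- valid & (!is.finite(m0) | m0 <= 0)
  valid[bad_m0] <- FALSE; t1[bad_m0] <- NA_real_; m0[bad_m0] <- NA_real_

  structure(list(t1 = array(t1, dm), m0 = array(m0, dm),
                 valid = array(valid, dm), tr = stack$tr),
            class = "t1m0_maps")
}
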