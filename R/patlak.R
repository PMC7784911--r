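#' Build the Patlak design from a vascular input function
#'
#' The uptake (Patlak) model is linear in its two regressors: the plasma
#' concentration \eqn{C_p(t)} and its running integral
#' \eqn{\int_0^t C_p\,d\tau}. The integral is computed by cumulative
#' trapezoid with \eqn{C_p} set to zero before the bolus dynamic, so
#' baseline noise does not accumulate.
#'
#' @param vif A `vif_curve` from [extract_vif()].
#' @param fit_window Frame indices used in the fit; default bolus dynamic to
#'   the end of the series. Must contain at least 3 frames and start at or
#'   after the bolus dynamic.
#' @return An object of class `patlak_regressors`: list with `times` (min),
#'   `cp` (mM), `cp_integral` (mM.min) over the full series, and the
#'   `fit_window` indices.
#' @export
build_regressors <- function(vif, fit_window = NULL) {
  stopifnot(inherits(vif, "vif_curve"))
  n_t <- length(vif$cp)
  if (is.null(fit_window)) fit_window <- seq(vif$bolus_dynamic, n_t)
  if (length(fit_window) < 3) stop("fit window must contain at least 3 frames")
  if (min(fit_window) < vif$bolus_dynamic)
    stop("fit window must start at or after the bolus dynamic")
  if (max(fit_window) > n_t) stop("fit window exceeds the series length")
  cp <- vif$cp
  cp[seq_len(vif$bolus_dynamic - 1)] <- 0
  cp_int <- as.vector(pracma::cumtrapz(vif$times_min, cp))
  structure(list(times = vif$times_min, cp = vif$cp, cp_integral = cp_int,
                 fit_window = as.integer(fit_window)),
            class = "patlak_regressors")
}

# Shared two-regressor no-intercept least squares:
#   C_t(t) = vp * C_p(t) + Ktrans * integral(C_p)
# ct: matrix (frames-in-window x voxels). Returns list(vp, ktrans, r2).
.patlak_ols <- function(ct, reg) {
  w <- reg$fit_window
  x1 <- reg$cp[w]; x2 <- reg$cp_integral[w]
  xtx <- matrix(c(sum(x1 * x1), sum(x1 * x2), sum(x1 * x2), sum(x2 * x2)), 2)
  det <- xtx[1, 1] * xtx[2, 2] - xtx[1, 2]^2
  if (!is.finite(det) || det <= 0 ||
      det < 1e-12 * max(xtx[1, 1] * xtx[2, 2], .Machine$double.eps))
    return(NULL)  # degenerate design (e.g. cp identically zero)
  xty <- rbind(colSums(x1 * ct), colSums(x2 * ct))
  beta <- solve(xtx, xty)
  fitted <- cbind(x1, x2) %*% beta
  ssr <- colSums((ct - fitted)^2)
  sst <- colSums(sweep(ct, 2, colMeans(ct))^2)
  r2 <- ifelse(sst > 0, 1 - ssr / sst, ifelse(ssr == 0, 1, -Inf))
  list(vp = beta[1, ], ktrans = beta[2, ], r2 = r2)
}

#' Fit the Patlak model to one concentration curve
#'
#' Ordinary least squares of the uptake model
#' \eqn{C_t(t) = v_p C_p(t) + K^{trans}\int_0^t C_p\,d\tau}
#' over the fit window, with no intercept. Estimates are not clipped;
#' physiological screening happens later in [subject_qc()].
#'
#' @param ct Tissue concentration curve (mM) over the full series.
#' @param reg A `patlak_regressors` object.
#' @return An object of class `patlak_result`: list with `ktrans` (1/min),
#'   `vp` (fraction), `r_squared` (against the window mean) and `n_points`.
#'   `NULL` fields with a `reason` when the design is degenerate.
#' @export
patlak_fit_voxel <- function(ct, reg) {
  stopifnot(inherits(reg, "patlak_regressors"))
  if (length(ct) != length(reg$cp))
    stop("curve length does not match the regressors")
  w <- reg$fit_window
  ctw <- ct[w]
  keep <- is.finite(ctw)
  if (sum(keep) < 3)
    return(structure(list(ktrans = NA_real_, vp = NA_real_,
                          r_squared = NA_real_, n_points = sum(keep),
                          reason = "fewer than 3 finite points"),
                     class = "patlak_result"))
  reg2 <- reg; reg2$fit_window <- w[keep]
  sol <- .patlak_ols(matrix(ctw[keep], ncol = 1), reg2)
  if (is.null(sol))
    return(structure(list(ktrans = NA_real_, vp = NA_real_,
                          r_squared = NA_real_, n_points = sum(keep),
                          reason = "degenerate design (cp ~ 0)"),
                     class = "patlak_result"))
  structure(list(ktrans = sol$ktrans, vp = sol$vp, r_squared = sol$r2,
                 n_points = sum(keep), reason = NULL),
            class = "patlak_result")
}

#' Voxelwise Patlak fit over a volume
#'
#' Applies the uptake-model least squares to every masked voxel of a
#' concentration series. Voxels with missing frames (non-invertible signal)
#' are fitted on their finite frames when at least three remain; otherwise
#' they are recorded as unfitted with a reason count. Voxels outside the
#' mask carry `NA`, never 0.
#'
#' @param conc A `concentration_series`.
#' @param vif A `vif_curve` on the same time grid.
#' @param mask Logical 3D array of voxels to fit.
#' @param fit_window Frame indices; default bolus dynamic to series end.
#' @return An object of class `pk_maps`: list with 3D arrays `ktrans`, `vp`,
#'   `r_squared`, logical `fitted`, `n_unfitted` reason table, the mask, and
#'   a `qc` slot (filled by [subject_qc()]).
#' @export
fit_volume <- function(conc, vif, mask, fit_window = NULL) {
  stopifnot(inherits(conc, "concentration_series"), inherits(vif, "vif_curve"))
  dm <- dim(conc$concentration)[1:3]
  if (!identical(dim(mask), dm)) stop("mask and series are on different grids")
  if (sum(mask) == 0) stop("mask is empty")
  if (length(vif$cp) != dim(conc$concentration)[4])
    stop("input function and series have different lengths")
  reg <- build_regressors(vif, fit_window)
  w <- reg$fit_window

  nv <- prod(dm)
  cmat <- matrix(conc$concentration, nv, dim(conc$concentration)[4])
  sel <- which(as.vector(mask))
  ctw <- t(cmat[sel, w, drop = FALSE])          # frames x voxels
  complete <- colSums(!is.finite(ctw)) == 0

  kt <- vp <- r2 <- rep(NA_real_, length(sel))
  reasons <- c(incomplete_frames = 0L, degenerate_design = 0L)

  if (any(complete)) {
    sol <- .patlak_ols(ctw[, complete, drop = FALSE], reg)
    if (is.null(sol)) {
      reasons["degenerate_design"] <- sum(complete)
    } else {
      kt[complete] <- sol$ktrans; vp[complete] <- sol$vp; r2[complete] <- sol$r2
    }
  }
  for (j in which(!complete)) {
    res <- patlak_fit_voxel(cmat[sel[j], ], reg)
    if (is.na(res$ktrans)) {
      reasons["incomplete_frames"] <- reasons["incomplete_frames"] + 1L
    } else {
      kt[j] <- res$ktrans; vp[j] <- res$vp; r2[j] <- res$r_squared
    }
  }

  to_map <- function(v) { out <- rep(NA_real_, nv); out[sel] <- v; array(out, dm) }
  fitted <- array(FALSE, dm); fitted[sel] <- !is.na(kt)
  structure(list(ktrans = to_map(kt), vp = to_map(vp), r_squared = to_map(r2),
                 fitted = fitted, mask = mask, n_unfitted = reasons,
                 fit_window = w, qc = NULL),
            class = "pk_maps")
}

#' Subject-level physiological quality control
#'
#' Flags subjects whose plasma-volume map is non-physiological: the default
#' rule fails a subject when the median vp over the mask is not in
#' `(0, 0.1]` or when more than 10% of masked voxels have vp > 1. The rule
#' and thresholds are declared in the verdict and are overridable; the study
#' this package models excluded such subjects but did not publish its exact
#' rule.
#'
#' @param maps A `pk_maps` object.
#' @param mask Logical 3D array; default the fitting mask.
#' @param median_vp_range Admissible `(low, high]` range for the median vp.
#' @param max_frac_vp_gt1 Maximum tolerated fraction of voxels with vp > 1.
#' @return The `pk_maps` with its `qc` slot set: list with `verdict`
#'   ("pass"/"fail"), `reason`, and summary statistics.
#' @export
subject_qc <- function(maps, mask = NULL, median_vp_range = c(0, 0.1),
                       max_frac_vp_gt1 = 0.1) {
  stopifnot(inherits(maps, "pk_maps"))
  if (is.null(mask)) mask <- maps$mask
  vpv <- maps$vp[mask]
  vpv <- vpv[is.finite(vpv)]
  med <- stats::median(vpv)
  frac_gt1 <- mean(vpv > 1)
  verdict <- "pass"; reason <- "median vp and vp>1 fraction within limits"
  if (!length(vpv)) {
    verdict <- "fail"; reason <- "no finite vp values in mask"
  } else if (frac_gt1 > max_frac_vp_gt1) {
    verdict <- "fail"
    reason <- sprintf("vp>1 fraction %.3f exceeds %.3f", frac_gt1, max_frac_vp_gt1)
  } else if (!(med > median_vp_range[1] && med <= median_vp_range[2])) {
    verdict <- "fail"
    reason <- if (med <= median_vp_range[1])
      sprintf("median vp ≤ %g", median_vp_range[1])
    else
      sprintf("median vp %.4f outside (%g, %g]", med,
              median_vp_range[1], median_vp_range[2])
  }
  maps$qc <- list(verdict = verdict, reason = reason,
                  median_vp = med, frac_vp_gt1 = frac_gt1,
                  median_vp_range = median_vp_range,
                  max_frac_vp_gt1 = max_frac_vp_gt1,
                  n_voxels = length(vpv))
  maps
}
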