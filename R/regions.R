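#' Binarise a lesion probability map
#'
#' Voxels whose lesion probability is greater than or equal to the threshold
#' are included (boundary-inclusive by convention, documented because
#' segmentation toolboxes differ). The default threshold of 0.3 is the value
#' validated against semi-automated lesion delineation in the study this
#' package models.
#'
#' @param lesion 3D array of lesion probabilities in `[0, 1]` (a pre-binarised
#'   0/1 mask is also accepted).
#' @param threshold Inclusion threshold in (0, 1); default 0.3.
#' @return Logical 3D array.
#' @export
lesion_binarize <- function(lesion, threshold = 0.3) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (any(lesion < 0 | lesion > 1, na.rm = TRUE))
    stop("lesion probabilities must lie in [0, 1]")
  out <- !is.na(lesion) & lesion >= threshold
  array(out, dim(lesion))
}

#' White-matter-lesion volume and its cube root
#'
#' Lesion volumes are strongly right-skewed across subjects, so the cube
#' root is the conventional scale for group statistics.
#'
#' @param mask Logical 3D lesion mask.
#' @param voxel_size Voxel edge lengths in mm (length 3), all positive.
#' @return List with `volume` (mm^3) and `cube_root` (mm).
#' @export
wml_volume <- function(mask, voxel_size) {
  stopifnot(length(voxel_size) == 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive on all axes")
  vol <- sum(mask, na.rm = TRUE) * prod(voxel_size)
  list(volume = vol, cube_root = vol^(1 / 3))
}

#' Remove lesion voxels from all non-lesion regions of interest
#'
#' Regional means must not mix lesional and non-lesional tissue, so every
#' ROI except the lesion mask itself has the lesion voxels subtracted. The
#' operation is idempotent. An ROI emptied entirely is retained as an empty
#' mask with a warning.
#'
#' @param rois Named list of logical 3D arrays on one grid; an entry named
#'   `"WML"` (if present) is left untouched.
#' @param wml_mask Logical 3D lesion mask on the same grid.
#' @return The cleaned ROI list, with an attribute `removed` giving the
#'   per-ROI count of voxels removed.
#' @export
clean_rois <- function(rois, wml_mask) {
  stopifnot(is.list(rois), length(rois) > 0)
  dm <- dim(wml_mask)
  removed <- integer(length(rois)); names(removed) <- names(rois)
  for (nm in names(rois)) {
    if (!identical(dim(rois[[nm]]), dm)) stop("ROI '", nm, "' is on a different grid")
    if (identical(nm, "WML")) next
    overlap <- rois[[nm]] & wml_mask
    removed[nm] <- sum(overlap)
    rois[[nm]] <- rois[[nm]] & !wml_mask
    if (removed[nm] > 0 && !any(rois[[nm]]))
      warning("ROI '", nm, "' was emptied entirely by lesion removal")
  }
  attr(rois, "removed") <- removed
  rois
}

#' Per-region mean parameter values
#'
#' Means of Ktrans and vp over each region, taken over fitted (non-missing)
#' voxels only; missing voxels are excluded and reported through the valid
#' voxel count, never imputed. A region with no valid voxel yields `NA` with
#' a warning.
#'
#' @param maps A `pk_maps` object.
#' @param rois Named list of logical 3D arrays on the map grid.
#' @return A tibble in long format: columns `region`, `metric` ("ktrans" or
#'   "vp"), `value`, `n_voxels`.
#' @export
regional_means <- function(maps, rois) {
  stopifnot(inherits(maps, "pk_maps"), is.list(rois))
  dm <- dim(maps$ktrans)
  rows <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    if (!identical(dim(roi), dm)) stop("ROI '", nm, "' is on a different grid")
    out <- lapply(c(ktrans = "ktrans", vp = "vp"), function(metric) {
      v <- maps[[metric]][roi]
      v <- v[is.finite(v)]
      if (length(v) == 0) {
        warning("region '", nm, "' has no valid voxel for ", metric)
        tibble::tibble(region = nm, metric = metric,
                       value = NA_real_, n_voxels = 0L)
      } else {
        tibble::tibble(region = nm, metric = metric,
                       value = mean(v), n_voxels = length(v))
      }
    })
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}
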