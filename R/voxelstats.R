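#' Separable 3D Gaussian smoothing
#'
#' Convolves a volume with a normalised separable Gaussian kernel of the
#' given full width at half maximum, \eqn{\sigma = FWHM/(2\sqrt{2\ln 2})}
#' per axis in voxel units. At the volume boundary the kernel is
#' renormalised over its in-volume support (normalised convolution), so a
#' constant field is exactly preserved everywhere and total mass is
#' preserved for support away from the edges; `fwhm = 0` is the identity.
#'
#' @param field 3D numeric array.
#' @param fwhm Full width at half maximum in mm; scalar or per-axis.
#' @param voxel_size Voxel edge lengths in mm (length 3).
#' @return Smoothed 3D array.
#' @export
gaussian_smooth <- function(field, fwhm, voxel_size = c(1.5, 1.5, 4)) {
  stopifnot(length(dim(field)) == 3, all(fwhm >= 0))
  fwhm <- rep_len(fwhm, 3)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  out <- field
  dm <- dim(field)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s == 0) next
    r <- max(1L, ceiling(3.5 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    acc <- array(0, dm)
    wsum <- numeric(dm[ax])  # in-volume kernel mass per position along axis
    for (j in -r:r) {
      w <- k[j + r + 1]
      n <- dm[ax]
      src <- seq_len(n) - j
      valid <- src >= 1 & src <= n
      if (!any(valid)) next
      dst_idx <- which(valid)
      src_idx <- src[valid]
      wsum[dst_idx] <- wsum[dst_idx] + w
      if (ax == 1) acc[dst_idx, , ] <- acc[dst_idx, , ] + w * out[src_idx, , ]
      else if (ax == 2) acc[, dst_idx, ] <- acc[, dst_idx, ] + w * out[, src_idx, ]
      else acc[, , dst_idx] <- acc[, , dst_idx] + w * out[, , src_idx]
    }
    out <- sweep(acc, ax, wsum, "/")
  }
  out
}

#' Voxelwise two-sample Welch t-test between groups of maps
#'
#' Unequal-variance (Welch) t statistic and Welch–Satterthwaite degrees of
#' freedom per voxel. Voxels missing in some subjects use the per-voxel
#' available n; voxels with fewer than two observations per group, or zero
#' variance in both groups, return `NA`.
#'
#' @param maps_A,maps_B Lists of 3D arrays (one per subject) on one grid.
#' @return List with 3D arrays `t` and `df`, plus `n_A`, `n_B` arrays of the
#'   per-voxel sample sizes.
#' @export
voxelwise_ttest <- function(maps_A, maps_B) {
  stopifnot(length(maps_A) >= 2, length(maps_B) >= 2)
  dm <- dim(maps_A[[1]])
  A <- matrix(unlist(lapply(maps_A, as.vector)), nrow = prod(dm))
  B <- matrix(unlist(lapply(maps_B, as.vector)), nrow = prod(dm))
  stat <- .welch_rows(A, B)
  list(t = array(stat$t, dm), df = array(stat$df, dm),
       n_A = array(stat$nA, dm), n_B = array(stat$nB, dm))
}

# Row-wise Welch t over matrices (voxels x subjects), NA-aware.
.welch_rows <- function(A, B) {
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  vA <- (rowSums(A^2, na.rm = TRUE) - nA * mA^2) / pmax(nA - 1, 1)
  vB <- (rowSums(B^2, na.rm = TRUE) - nB * mB^2) / pmax(nB - 1, 1)
  seA <- vA / nA; seB <- vB / nB
  se2 <- seA + seB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (seA^2 / (nA - 1) + seB^2 / (nB - 1))
  bad <- nA < 2 | nB < 2 | se2 <= 0
  t[bad] <- NA_real_; df[bad] <- NA_real_
  list(t = t, df = df, nA = nA, nB = nB)
}

# 26-connectivity component labelling restricted to a set of voxel indices.
# Returns an integer vector of component ids parallel to `idx`.
.label_components26 <- function(idx, dm) {
  n <- length(idx)
  if (n == 0) return(integer(0))
  coord <- arrayInd(idx, dm)
  key <- (coord[, 3] - 1) * (dm[1] * dm[2]) + (coord[, 2] - 1) * dm[1] + coord[, 1]
  pos <- integer(prod(dm)); pos[key] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[o, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nbkey <- (nb[ok, 3] - 1) * (dm[1] * dm[2]) + (nb[ok, 2] - 1) * dm[1] + nb[ok, 1]
    j <- pos[nbkey]
    here <- which(ok)[j > 0]
    j <- j[j > 0]
    for (m in seq_along(here)) {
      ra <- find(here[m]); rb <- find(j[m])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Cluster-extent thresholding of a t map
#'
#' Applies a one-sided voxel-level threshold (`t` exceeding the critical
#' value of the per-voxel degrees of freedom at `voxel_p`), labels the
#' supra-threshold voxels by 26-neighbour connectivity (faces, edges and
#' corners all connect — so two blobs touching only at a corner form one
#' cluster), and discards components smaller than `min_extent` voxels.
#' The test direction is `A > B` for a map from [voxelwise_ttest()]; negate
#' the map for the opposite direction.
#'
#' @param tmap 3D t-statistic array (`NA` allowed).
#' @param df 3D degrees-of-freedom array, or a scalar.
#' @param voxel_p One-sided voxel-level threshold; default 0.001.
#' @param min_extent Minimum cluster size in voxels; default 50.
#' @return List with `clusters`: tibble (`cluster`, `n_voxels`, `peak_t`,
#'   `peak_x`, `peak_y`, `peak_z`), and `label_map`: integer 3D array
#'   (0 = background), ordered by decreasing extent.
#' @export
cluster_threshold <- function(tmap, df, voxel_p = 0.001, min_extent = 50) {
  stopifnot(voxel_p > 0, min_extent > 0)
  dm <- dim(tmap)
  if (length(df) == 1) df <- array(df, dm)
  crit <- stats::qt(1 - voxel_p, df)
  supra <- which(!is.na(tmap) & !is.na(crit) & tmap > crit)
  lab_map <- array(0L, dm)
  empty <- tibble::tibble(cluster = integer(), n_voxels = integer(),
                          peak_t = numeric(), peak_x = integer(),
                          peak_y = integer(), peak_z = integer())
  if (length(supra) == 0) return(list(clusters = empty, label_map = lab_map))
  comp <- .label_components26(supra, dm)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_extent)
  if (length(keep) == 0) return(list(clusters = empty, label_map = lab_map))
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  rows <- lapply(seq_along(ord), function(i) {
    vox <- supra[comp == ord[i]]
    lab_map[vox] <<- i
    peak <- vox[which.max(tmap[vox])]
    pc <- arrayInd(peak, dm)
    tibble::tibble(cluster = i, n_voxels = length(vox),
                   peak_t = tmap[peak],
                   peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  })
  list(clusters = dplyr::bind_rows(rows), label_map = lab_map)
}

# Maximum supra-threshold cluster extent for each column of a t matrix
# (voxels x permutations), with matching df matrix. Cheap because under the
# null very few voxels exceed the per-voxel critical value.
.max_extents <- function(tm, dfm, dm, voxel_p, min_df) {
  tmin <- stats::qt(1 - voxel_p, max(min_df, 1.001))  # loosest possible crit
  out <- numeric(ncol(tm))
  cand <- which(!is.na(tm) & tm > tmin, arr.ind = TRUE)
  if (nrow(cand)) {
    really <- tm[cand] > stats::qt(1 - voxel_p, dfm[cand])
    cand <- cand[really, , drop = FALSE]
  }
  if (nrow(cand) == 0) return(out)
  by_col <- split(cand[, 1], cand[, 2])
  for (cl in names(by_col)) {
    comp <- .label_components26(by_col[[cl]], dm)
    out[as.integer(cl)] <- max(tabulate(comp))
  }
  out
}

#' Permutation-based cluster-level family-wise-error correction
#'
#' Builds the null distribution of the maximum supra-threshold cluster
#' extent by permuting group labels (keeping group sizes), then assigns
#' each observed cluster the corrected p-value
#' \deqn{p = \frac{1 + \#\{\text{perm max extent} \ge \text{observed extent}\}}{n_{perm} + 1},}
#' which is never below \eqn{1/(n_{perm}+1)}. When fewer distinct
#' permutations exist than requested, all are enumerated and the result is
#' flagged exact. The test direction is one-sided, `A > B`.
#'
#' @param maps_A,maps_B Lists of 3D arrays, one per subject.
#' @param voxel_p One-sided voxel-level threshold; default 0.001.
#' @param min_extent Minimum reported cluster size; default 50.
#' @param n_perm Number of permutations (>= 100); default 199.
#' @param seed Integer seed for the permutation draw.
#' @return List with `clusters` (the [cluster_threshold()] tibble plus a
#'   `p_fwe` column), `label_map`, `perm_max_extent` (the null draws),
#'   `n_perm_used`, and `exact` (logical).
#' @export
permutation_cluster_fwe <- function(maps_A, maps_B, voxel_p = 0.001,
                                    min_extent = 50, n_perm = 199,
                                    seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  nA <- length(maps_A); nB <- length(maps_B)
  dm <- dim(maps_A[[1]])
  X <- matrix(unlist(lapply(c(maps_A, maps_B), as.vector)), nrow = prod(dm))
  n <- nA + nB

  total <- choose(n, nA)
  exact <- total <= n_perm
  if (exact) {
    sets <- utils::combn(n, nA, simplify = FALSE)
    perms <- Filter(function(s) !identical(s, seq_len(nA)), sets)
  } else {
    set.seed(seed)
    perms <- replicate(n_perm, sample(n, nA), simplify = FALSE)
  }
  n_used <- length(perms)

  obs <- .welch_rows(X[, seq_len(nA), drop = FALSE],
                     X[, nA + seq_len(nB), drop = FALSE])
  observed <- cluster_threshold(array(obs$t, dm), array(obs$df, dm),
                                voxel_p = voxel_p, min_extent = min_extent)

  min_df <- n - 2  # upper bound on Welch df => loosest critical value
  tm <- matrix(NA_real_, prod(dm), n_used)
  dfm <- matrix(NA_real_, prod(dm), n_used)
  for (k in seq_len(n_used)) {
    ia <- perms[[k]]
    st <- .welch_rows(X[, ia, drop = FALSE], X[, -ia, drop = FALSE])
    tm[, k] <- st$t; dfm[, k] <- st$df
  }
  perm_max <- .max_extents(tm, dfm, dm, voxel_p, min_df)

  cl <- observed$clusters
  if (nrow(cl)) {
    cl$p_fwe <- vapply(cl$n_voxels, function(ext)
      (1 + sum(perm_max >= ext)) / (n_used + 1), numeric(1))
  } else {
    cl$p_fwe <- numeric(0)
  }
  list(clusters = cl, label_map = observed$label_map,
       perm_max_extent = perm_max, n_perm_used = n_used, exact = exact)
}
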