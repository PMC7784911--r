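#' Canonical analysis regions
#' @return Character vector of the eight regional ROI names.
#' @export
canonical_regions <- function() c("SN", "CA", "PU", "P", "WML", "NAWM", "FC", "PC")

.default_mean_ktrans <- function(regions) {
  # 1/min; rows CN, CP, PD. Leakage mildly elevated in the disease group in
  # substantia nigra, white matter (lesional and normal-appearing) and
  # posterior cortex, the regional pattern this package's statistics are
  # designed to detect.
  base <- c(SN = 3.0e-3, CA = 2.5e-3, PU = 2.5e-3, P = 2.0e-3,
            WML = 3.5e-3, NAWM = 1.8e-3, FC = 3.2e-3, PC = 3.0e-3)
  m <- rbind(CN = base,
             CP = base * c(1.10, 1.08, 1.05, 1.05, 1.15, 1.15, 1.05, 1.10),
             PD = base * c(1.27, 1.08, 1.08, 1.05, 1.26, 1.28, 1.06, 1.27))
  m[, regions, drop = FALSE]
}

.default_mean_vp <- function(regions) {
  base <- c(SN = 0.010, CA = 0.015, PU = 0.014, P = 0.010,
            WML = 0.007, NAWM = 0.006, FC = 0.020, PC = 0.018)
  m <- rbind(CN = base, CP = base * 0.85, PD = base)
  m[, regions, drop = FALSE]
}

#' Design of a synthetic three-group cohort
#'
#' Encodes the statistical structure the group analysis assumes: per-group,
#' per-region mean Ktrans and vp with a subject-level random intercept and
#' within-subject (regional) noise, plus demographic and clinical covariates
#' whose group-level distributions mirror a Parkinson's cohort with healthy
#' (CN) and cerebrovascular-disease (CP) controls. Default group sizes are
#' the analysable cohort of the study this package models (31 CN, 15 CP,
#' 49 PD).
#'
#' @param group_sizes Named counts for CN, CP, PD.
#' @param regions Region names; default [canonical_regions()].
#' @param mean_ktrans,mean_vp Group-by-region mean matrices (rownames CN,
#'   CP, PD). Defaults encode regionally varying means with mild disease
#'   elevation of Ktrans.
#' @param between_subject_sd,within_subject_sd Named vectors with entries
#'   `ktrans` and `vp` giving the SD of the subject random intercept and of
#'   region-level noise, in the metric's own units.
#' @param seed Integer seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(CN = 31, CP = 15, PD = 49),
                          regions = canonical_regions(),
                          mean_ktrans = .default_mean_ktrans(regions),
                          mean_vp = .default_mean_vp(regions),
                          between_subject_sd = c(ktrans = 0.8e-3, vp = 0.004),
                          within_subject_sd = c(ktrans = 0.5e-3, vp = 0.003),
                          seed = 1L) {
  if (length(regions) == 0) stop("region list is empty")
  stopifnot(all(c("CN", "CP", "PD") %in% names(group_sizes)),
            identical(sort(rownames(mean_ktrans)), c("CN", "CP", "PD")),
            identical(colnames(mean_ktrans), regions),
            identical(colnames(mean_vp), regions))
  if (any(between_subject_sd < 0) || any(within_subject_sd < 0))
    stop("SDs must be non-negative")
  if (any(group_sizes < 2)) stop("each group needs at least 2 subjects")
  structure(list(group_sizes = group_sizes, regions = regions,
                 mean_ktrans = mean_ktrans, mean_vp = mean_vp,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# Group-level covariate distributions (age in years; female fraction; cube
# root of lesion volume in mm with its spread; cognitive score; and, for the
# disease group, medication dose in mg and severity score).
.covariate_presets <- function() {
  list(
    CN = list(age = c(66.4, 7.5), p_female = 16 / 31, wml_cr = c(1.26, 0.83),
              moca = c(27.9, 2.3), ledd = NULL, updrs = NULL),
    CP = list(age = c(69.1, 7.5), p_female = 4 / 15, wml_cr = c(2.11, 0.72),
              moca = c(26.1, 2.9), ledd = NULL, updrs = NULL),
    PD = list(age = c(68.9, 7.5), p_female = 12 / 49, wml_cr = c(1.80, 0.95),
              moca = c(25.2, 3.9), ledd = c(583.5, 399.6), updrs = c(29.2, 12.7))
  )
}

#' Simulate a cohort table
#'
#' Draws one subject table and one long-format value table (one row per
#' subject x region x metric) from a [cohort_design()]. For each subject a
#' random intercept (shared across regions, per metric) and independent
#' region-level noise are added to the design mean. Covariates are drawn
#' from the group presets; LEDD and UPDRS exist only for the PD group.
#' Deterministic under the design seed.
#'
#' @param design A [cohort_design()].
#' @return A tibble of class `cohort_table` with columns `subject`, `group`,
#'   `gender`, `age`, `wml_cube_root`, `wml_volume`, `moca`, `ledd`,
#'   `updrs`, `region`, `metric`, `value`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  presets <- .covariate_presets()
  groups <- c("CN", "CP", "PD")
  subj_rows <- list()
  val_rows <- list()
  sid <- 0L
  for (g in groups) {
    n <- design$group_sizes[[g]]
    pre <- presets[[g]]
    for (i in seq_len(n)) {
      sid <- sid + 1L
      id <- sprintf("S%03d", sid)
      wml_cr <- max(0.1, stats::rnorm(1, pre$wml_cr[1], pre$wml_cr[2]))
      subj <- tibble::tibble(
        subject = id, group = g,
        gender = ifelse(stats::runif(1) < pre$p_female, "F", "M"),
        age = round(min(90, max(50, stats::rnorm(1, pre$age[1], pre$age[2])))),
        wml_cube_root = wml_cr, wml_volume = wml_cr^3,
        moca = round(min(30, max(5, stats::rnorm(1, pre$moca[1], pre$moca[2])))),
        ledd = if (is.null(pre$ledd)) NA_real_ else
          max(0, stats::rnorm(1, pre$ledd[1], pre$ledd[2])),
        updrs = if (is.null(pre$updrs)) NA_real_ else
          max(1, round(stats::rnorm(1, pre$updrs[1], pre$updrs[2])))
      )
      subj_rows[[sid]] <- subj
      for (metric in c("ktrans", "vp")) {
        mu <- if (metric == "ktrans") design$mean_ktrans[g, ] else design$mean_vp[g, ]
        b <- stats::rnorm(1, 0, design$between_subject_sd[[metric]])
        e <- stats::rnorm(length(design$regions), 0,
                          design$within_subject_sd[[metric]])
        val_rows[[length(val_rows) + 1L]] <- tibble::tibble(
          subject = id, region = design$regions, metric = metric,
          value = as.numeric(mu + b + e))
      }
    }
  }
  subjects <- dplyr::bind_rows(subj_rows)
  values <- dplyr::bind_rows(val_rows)
  out <- dplyr::left_join(subjects, values, by = "subject")
  class(out) <- c("cohort_table", class(out))
  out
}

#' Subject-level rows of a cohort table
#'
#' @param cohort A `cohort_table` (long format).
#' @return A tibble with one row per subject and the subject-level columns.
#' @export
cohort_subjects <- function(cohort) {
  cols <- intersect(c("subject", "group", "gender", "age", "wml_cube_root",
                      "wml_volume", "moca", "ledd", "updrs"), names(cohort))
  dplyr::distinct(dplyr::select(cohort, dplyr::all_of(cols)))
}
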