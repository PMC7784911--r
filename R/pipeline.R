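#' Pipeline configuration
#'
#' Collects every tunable of the per-subject and group analyses in one
#' place so that runs are reproducible from config + inputs + seed. There
#' are no hidden defaults in the science path: the relaxivity, haematocrit,
#' fit window, QC thresholds and statistical design used are all recorded
#' in the output sidecars.
#'
#' @param r1,hematocrit See [kinetics_config()].
#' @param baseline_window Pre-contrast frames for the baseline; `NULL` means
#'   all frames before the bolus.
#' @param fit_window Patlak fit frames; `NULL` means bolus to series end.
#' @param qc_median_vp_range,qc_max_frac_vp_gt1 See [subject_qc()].
#' @param voxel_p,min_extent,n_perm Voxelwise comparison settings.
#' @param smooth_fwhm Smoothing kernel FWHM in mm applied to parameter maps
#'   before voxelwise comparison (0 disables).
#' @param seed Integer seed recorded in all outputs.
#' @param out_dir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(r1 = 3.5, hematocrit = 0.42,
                            baseline_window = NULL, fit_window = NULL,
                            qc_median_vp_range = c(0, 0.1),
                            qc_max_frac_vp_gt1 = 0.1,
                            voxel_p = 0.001, min_extent = 50, n_perm = 199,
                            smooth_fwhm = 8, seed = 1L, out_dir = ".") {
  structure(list(r1 = r1, hematocrit = hematocrit,
                 baseline_window = baseline_window, fit_window = fit_window,
                 qc_median_vp_range = qc_median_vp_range,
                 qc_max_frac_vp_gt1 = qc_max_frac_vp_gt1,
                 voxel_p = voxel_p, min_extent = min_extent, n_perm = n_perm,
                 smooth_fwhm = smooth_fwhm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Per-subject input record
#'
#' @param subject Subject id.
#' @param group Group label (CN, CP or PD).
#' @param dynamic,b1,mask Paths to the 4D dynamic series, B1 map and brain
#'   mask (NIfTI).
#' @param vfa Named list or vector of per-flip-angle NIfTI paths, names like
#'   `"2"`, `"5"`, `"10"` (degrees).
#' @param sinus_mask Path to the venous (input-function) mask.
#' @param meta Path to a JSON sidecar with `dt_s`, `bolus_dynamic`, `tr_ms`,
#'   `dynamic_flip_deg`.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject, group, dynamic, vfa, b1, mask,
                           sinus_mask, meta) {
  structure(list(subject = subject, group = group, dynamic = dynamic,
                 vfa = vfa, b1 = b1, mask = mask, sinus_mask = sinus_mask,
                 meta = meta),
            class = "subject_record")
}

.validate_record <- function(record) {
  paths <- c(dynamic = record$dynamic, b1 = record$b1, mask = record$mask,
             sinus_mask = record$sinus_mask, meta = record$meta,
             stats::setNames(unlist(record$vfa),
                             paste0("vfa_", names(record$vfa))))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", names(missing), missing), collapse = "; "))
  invisible(TRUE)
}

.read_vol <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Run the full per-subject pipeline
#'
#' Validates the inputs, fits the pre-contrast T1/M0 maps from the
#' variable-flip-angle stack, converts the dynamic series to concentration,
#' extracts the input function from the venous mask, fits the Patlak model
#' voxelwise, applies subject QC, and writes every intermediate with a JSON
#' provenance sidecar (inputs, settings, seed). A failed QC still writes
#' all outputs; the verdict is in the return value and sidecar.
#'
#' @param config A [pipeline_config()].
#' @param record A [subject_record()].
#' @return List with `t1m0`, `conc`, `vif`, `maps` (QC-stamped `pk_maps`),
#'   `regional` (if ROI labels are available) and `paths` of written files.
#' @export
run_subject <- function(config, record) {
  stopifnot(inherits(config, "pipeline_config"), inherits(record, "subject_record"))
  .validate_record(record)
  meta <- jsonlite::read_json(record$meta, simplifyVector = TRUE)
  for (k in c("dt_s", "bolus_dynamic", "tr_ms", "dynamic_flip_deg"))
    if (is.null(meta[[k]])) stop("metadata sidecar lacks field '", k, "'")

  dyn4d <- .read_vol(record$dynamic)
  b1 <- .read_vol(record$b1)
  mask <- .read_vol(record$mask) > 0
  sinus <- .read_vol(record$sinus_mask) > 0
  dims <- list(dynamic = dim(dyn4d)[1:3], b1 = dim(b1), mask = dim(mask),
               sinus_mask = dim(sinus))
  for (nm in names(dims)[-1])
    if (!identical(dims[[nm]], dims$dynamic))
      stop("grid mismatch between dynamic and ", nm)

  vfa_sig <- lapply(record$vfa, .read_vol)
  angles <- as.numeric(names(record$vfa))
  stack <- vfa_stack(vfa_sig, angles, meta$tr_ms)

  times <- (seq_len(dim(dyn4d)[4]) - 1) * meta$dt_s
  series <- dynamic_series(dyn4d, times, meta$bolus_dynamic,
                           meta$dynamic_flip_deg, meta$tr_ms)
  cfg <- kinetics_config(config$r1, config$hematocrit, config$baseline_window)

  t1m0 <- fit_vfa_t1(stack, b1, mask | sinus)
  conc <- signal_to_concentration(series, t1m0, b1, cfg)
  vif <- extract_vif(conc, sinus, cfg)
  maps <- fit_volume(conc, vif, mask, config$fit_window)
  maps <- subject_qc(maps, median_vp_range = config$qc_median_vp_range,
                     max_frac_vp_gt1 = config$qc_max_frac_vp_gt1)

  out <- file.path(config$out_dir, record$subject)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wr <- function(img, name) {
    p <- file.path(out, paste0(name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(img), p)
    p
  }
  na0 <- function(a) { a[!is.finite(a)] <- 0; a }  # NIfTI has no NA; mask says which are valid
  paths <- list(
    t1 = wr(na0(t1m0$t1), "t1"), m0 = wr(na0(t1m0$m0), "m0"),
    t1_valid = wr(t1m0$valid * 1, "t1_valid"),
    ktrans = wr(na0(maps$ktrans), "ktrans"), vp = wr(na0(maps$vp), "vp"),
    r_squared = wr(na0(maps$r_squared), "r_squared"),
    fitted = wr(maps$fitted * 1, "fitted"),
    vif = write_vif(vif, file.path(out, "vif.csv"))
  )
  prov <- list(subject = record$subject, group = record$group,
               inputs = record[c("dynamic", "vfa", "b1", "mask",
                                 "sinus_mask", "meta")],
               settings = unclass(config)[c("r1", "hematocrit",
                                            "baseline_window", "fit_window",
                                            "qc_median_vp_range",
                                            "qc_max_frac_vp_gt1")],
               seed = config$seed,
               fit_window_used = maps$fit_window,
               n_noninvertible = conc$n_noninvertible,
               n_unfitted = as.list(maps$n_unfitted),
               qc = maps$qc)
  paths$provenance <- file.path(out, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  list(t1m0 = t1m0, conc = conc, vif = vif, maps = maps, paths = paths)
}

#' Run the group-level statistical battery on a cohort table
#'
#' Applies the QC exclusions first, then computes the demographic
#' comparison table, the repeated-measures mixed ANOVA for each metric
#' (without and with the age/gender/lesion-volume covariates), Bonferroni
#' post hoc pairwise tests, and the clinical mixed-model correlations in
#' the PD subset. Tables are written as CSV to `config$out_dir` together
#' with the exclusion report.
#'
#' @param config A [pipeline_config()].
#' @param manifest Subject manifest with QC flag columns (see
#'   [apply_exclusions()]).
#' @param cohort A `cohort_table` of regional values for (at least) the
#'   retained subjects.
#' @return List with `report`, `demographics`, per-metric `anova`,
#'   `anova_cov`, `posthoc`, `clinical`, and `paths` of written CSVs.
#' @export
run_group <- function(config, manifest, cohort) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(manifest) == 0) stop("manifest is empty")
  excl <- apply_exclusions(manifest, cohort)
  groups_left <- unique(excl$manifest$group)
  if (length(groups_left) < 2)
    stop("fewer than 2 groups remain after exclusions; report: ",
         jsonlite::toJSON(excl$report[c("n_recruited", "n_excluded",
                                        "n_analysable")], auto_unbox = TRUE))
  cohort <- excl$cohort
  subjects <- cohort_subjects(cohort)
  demo <- demographic_tests(subjects)
  res <- list(report = excl$report, demographics = demo)
  for (metric in intersect(c("ktrans", "vp"), unique(cohort$metric))) {
    res$anova[[metric]] <- rm_anova(cohort, metric)
    res$anova_cov[[metric]] <- rm_anova(cohort, metric,
                                        covariates = c("age", "gender",
                                                       "wml_cube_root"))
    res$posthoc[[metric]] <- posthoc_pairwise(cohort, metric)
    if ("PD" %in% groups_left && all(c("moca", "ledd", "updrs") %in% names(cohort)))
      res$clinical[[metric]] <- clinical_lmm(cohort, metric)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wrt <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths$demographics <- wrt(demo, "demographics")
  for (metric in names(res$anova)) {
    paths[[paste0("anova_", metric)]] <- wrt(res$anova[[metric]]$table,
                                             paste0("anova_", metric))
    paths[[paste0("posthoc_", metric)]] <- wrt(res$posthoc[[metric]]$overall,
                                               paste0("posthoc_", metric))
  }
  paths$exclusions <- file.path(config$out_dir, "exclusion_report.json")
  jsonlite::write_json(
    list(per_reason_group = excl$report$per_reason_group,
         n_recruited = excl$report$n_recruited,
         n_excluded = excl$report$n_excluded,
         n_analysable = excl$report$n_analysable,
         analysable_by_group = as.list(excl$report$analysable_by_group),
         seed = config$seed),
    paths$exclusions, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$paths <- paths
  res
}
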