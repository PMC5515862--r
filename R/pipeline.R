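#' Texture and intensity features for one patient
#'
#' For each analyzed tissue and timepoint, quantizes the masked region and
#' computes the orientation-averaged texture vector plus first-order
#' intensity statistics. The normalization range is the min/max over the
#' union of all analyzed masks, computed per volume (pre and post
#' separately) by default, or jointly with
#' `range_scope = "shared_pre_post"`.
#'
#' @param pre,post 3D intensity arrays on a common grid.
#' @param masks Named list of logical masks (disjoint; see
#'   [resolve_mask_overlaps()]).
#' @param patient_id Identifier written into every row.
#' @param n_levels Vector of gray-level counts (subset of 8/16/32/64).
#' @param range_scope `"per_volume"` (default) or `"shared_pre_post"`.
#' @param tissues Optional subset of tissues to analyze.
#' @return data.frame, one row per (tissue, timepoint, n_levels):
#'   identifiers, the six descriptors, `orientations_used`, `total_pairs`,
#'   `correlation_defined`, `mean_intensity`, `var_intensity`, `vmr`.
#' @export
patient_features <- function(pre, post, masks, patient_id = NA_character_,
                             n_levels = 16, range_scope = "per_volume",
                             tissues = NULL) {
  range_scope <- match.arg(range_scope, c("per_volume", "shared_pre_post"))
  masks <- Filter(function(m) sum(m) >= 2, masks)
  if (length(masks) == 0)
    stop("no analyzable tissue mask (>= 2 voxels) present", call. = FALSE)
  # the scaling range always spans the union of every analyzed tissue mask
  # of the volume, even when features are only reported for a subset
  rng_pre <- intensity_range(pre, masks)
  rng_post <- intensity_range(post, masks)
  if (!is.null(tissues)) masks <- masks[intersect(tissues, names(masks))]
  if (length(masks) == 0)
    stop("no requested tissue mask present", call. = FALSE)
  if (range_scope == "shared_pre_post") {
    rng <- c(min(rng_pre[1], rng_post[1]), max(rng_pre[2], rng_post[2]))
    rng_pre <- rng_post <- rng
  }
  vols <- list(pre = pre, post = post)
  rngs <- list(pre = rng_pre, post = rng_post)
  rows <- list()
  for (tis in names(masks)) {
    for (tp in c("pre", "post")) {
      st <- region_stats(vols[[tp]][masks[[tis]]])
      for (N in n_levels) {
        qr <- quantize_region(vols[[tp]], masks[[tis]], rngs[[tp]], N)
        tv <- texture_vector(qr)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(patient_id = patient_id, tissue = tis, timepoint = tp,
                     n_levels = as.integer(N)),
          tv,
          data.frame(mean_intensity = st$mean, var_intensity = st$variance,
                     vmr = st$vmr))
      }
    }
  }
  do.call(rbind, rows)
}

#' Feature table for an in-memory phantom cohort
#'
#' Applies [patient_features()] to every patient of a generated cohort in
#' patient-id order.
#'
#' @param cohort Result of [generate_cohort()] (or a bare list of
#'   `phantom_patient` objects).
#' @param ... Passed to [patient_features()].
#' @return Combined feature data.frame.
#' @export
cohort_features <- function(cohort, ...) {
  patients <- if (!is.null(cohort$patients)) cohort$patients else cohort
  do.call(rbind, lapply(patients, function(p) {
    patient_features(p$pre, p$post, p$masks, patient_id = p$patient_id, ...)
  }))
}

#' Per-patient, per-tissue DVMR table
#'
#' @param features Feature table (any one `n_levels`; VMR is computed on
#'   raw intensities and identical across level counts).
#' @return data.frame with patient_id, tissue, dvmr.
#' @export
dvmr_table <- function(features) {
  f <- features[features$n_levels == features$n_levels[1], , drop = FALSE]
  pre <- f[f$timepoint == "pre", c("patient_id", "tissue", "vmr")]
  post <- f[f$timepoint == "post", c("patient_id", "tissue", "vmr")]
  m <- merge(pre, post, by = c("patient_id", "tissue"),
             suffixes = c("_pre", "_post"))
  data.frame(patient_id = m$patient_id, tissue = m$tissue,
             dvmr = m$vmr_post - m$vmr_pre)
}

discover_patients <- function(input_dir, covariates) {
  ids <- sort(covariates$patient_id)
  lapply(ids, function(id) {
    list(id = id,
         pre = file.path(input_dir, paste0(id, "_pre.nii.gz")),
         post = file.path(input_dir, paste0(id, "_post.nii.gz")),
         masks = setNames(file.path(input_dir,
                                    paste0(id, "_mask_", TISSUES, ".nii.gz")),
                          TISSUES))
  })
}

#' Extract the feature table from a cohort on disk
#'
#' Reads `<id>_pre.nii.gz` / `<id>_post.nii.gz` / `<id>_mask_<tissue>.nii.gz`
#' for every patient listed in the covariate CSV (patients processed in
#' sorted id order so output is order-stable), computes features, and
#' optionally writes them as CSV with all floating-point values at 12
#' significant digits (making reruns byte-identical). A patient whose
#' files are unreadable is skipped with a warning and never corrupts the
#' other rows.
#'
#' @param input_dir Directory holding the volumes, masks and
#'   `covariates.csv` (the layout written by [generate_cohort()]).
#' @param n_levels Vector of gray-level counts.
#' @param range_scope Passed to [patient_features()].
#' @param tissues Optional subset of tissues.
#' @param out_csv Optional output CSV path.
#' @return The feature data.frame, invisibly when `out_csv` is given.
#' @export
extract_features <- function(input_dir, n_levels = 16,
                             range_scope = "per_volume", tissues = NULL,
                             out_csv = NULL) {
  cov_path <- file.path(input_dir, "covariates.csv")
  if (!file.exists(cov_path))
    stop("input error: no covariates.csv in ", input_dir, call. = FALSE)
  covariates <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
  entries <- discover_patients(input_dir, covariates)
  rows <- list()
  for (e in entries) {
    feat <- tryCatch({
      vp <- load_volume_pair(e$pre, e$post, patient_id = e$id)
      masks <- load_masks(e$masks[file.exists(e$masks)], vp)
      patient_features(vp$pre, vp$post, masks, patient_id = e$id,
                       n_levels = n_levels, range_scope = range_scope,
                       tissues = tissues)
    }, error = function(err) {
      warning("skipping patient ", e$id, ": ", conditionMessage(err))
      NULL
    })
    if (!is.null(feat)) rows[[length(rows) + 1L]] <- feat
  }
  if (length(rows) == 0) stop("input error: zero resolvable patients",
                              call. = FALSE)
  features <- do.call(rbind, rows)
  if (!is.null(out_csv)) {
    write_feature_csv(features, out_csv)
    return(invisible(features))
  }
  features
}

write_feature_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full texture study on a cohort
#'
#' Orchestrates the whole analysis on a cohort directory (optionally
#' simulating it first from a [phantom_spec()]): feature extraction, the
#' CSF pre/post mixed-model table, the ANCOVA table per tissue and
#' descriptor, the nonparametric group-test battery for each grouping
#' variable, and the per-patient DVMR table. All tables are written as
#' CSV into `out_dir` together with a plain-text run manifest recording
#' the seed, configuration and package version.
#'
#' @param input_dir Cohort directory (created by [generate_cohort()] or
#'   following the same layout). Ignored when `spec` is given, in which
#'   case the cohort is simulated into `file.path(out_dir, "phantom")`.
#' @param out_dir Output directory.
#' @param spec Optional [phantom_spec()] to simulate first.
#' @param n_levels Gray-level counts for feature extraction.
#' @param range_scope Quantization range scope.
#' @param groupings Grouping variables for the test battery.
#' @param mixed_tissue Tissue for the pre/post mixed model (CSF, per the
#'   leakage hypothesis).
#' @return Invisibly, a list with `features`, `mixed_model`, `ancova`,
#'   `battery`, `dvmr`.
#' @export
run_full_study <- function(input_dir = NULL, out_dir, spec = NULL,
                           n_levels = 16, range_scope = "per_volume",
                           groupings = c("hypertension", "stroke_subtype",
                                         "bg_pvs", "svd_score"),
                           mixed_tissue = "CSF") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(spec)) {
    input_dir <- file.path(out_dir, "phantom")
    stage("simulate", generate_cohort(spec, dir = input_dir))
  }
  if (is.null(input_dir)) stop("input error: neither input_dir nor spec given",
                               call. = FALSE)
  features <- stage("extract", extract_features(
    input_dir, n_levels = n_levels, range_scope = range_scope,
    out_csv = file.path(out_dir, "features.csv")))
  covariates <- utils::read.csv(file.path(input_dir, "covariates.csv"),
                                stringsAsFactors = FALSE)
  f1 <- features[features$n_levels == n_levels[1], , drop = FALSE]

  mixed_rows <- stage("mixed_model", do.call(rbind, lapply(DESCRIPTORS, function(d) {
    r <- mixed_pre_post(f1, covariates, mixed_tissue, d)
    cbind(data.frame(tissue = mixed_tissue, descriptor = d),
          r$fixed_effects,
          data.frame(random_intercept_var = r$random_intercept_var,
                     residual_var = r$residual_var))
  })))
  ancova_rows <- stage("ancova", do.call(rbind, unlist(recursive = FALSE,
    lapply(unique(f1$tissue), function(tis) lapply(DESCRIPTORS, function(d) {
      r <- ancova_post_on_pre(f1, covariates, tis, d)
      cbind(data.frame(tissue = tis, descriptor = d), r$coefficients)
    })))))
  battery <- stage("battery", do.call(rbind, lapply(groupings, function(g) {
    run_comparison_battery(f1, covariates, g, p_adjusted = TRUE)
  })))
  dvmr_df <- stage("dvmr", dvmr_table(features))

  write_feature_csv(mixed_rows, file.path(out_dir, "mixed_model_csf.csv"))
  write_feature_csv(ancova_rows, file.path(out_dir, "ancova.csv"))
  write_feature_csv(battery, file.path(out_dir, "group_tests.csv"))
  write_feature_csv(dvmr_df, file.path(out_dir, "dvmr.csv"))
  manifest <- c(
    paste0("flairtex version: ", as.character(utils::packageVersion("flairtex"))),
    paste0("R version: ", R.version.string),
    paste0("input_dir: ", normalizePath(input_dir)),
    paste0("n_levels: ", paste(n_levels, collapse = ",")),
    paste0("range_scope: ", range_scope),
    paste0("groupings: ", paste(groupings, collapse = ",")),
    paste0("seed: ", if (!is.null(spec) && !is.null(spec$seed)) spec$seed else "NA"),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  invisible(list(features = features, mixed_model = mixed_rows,
                 ancova = ancova_rows, battery = battery, dvmr = dvmr_df))
}
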