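#' Default covariate model for the phantom cohort
#'
#' Marginal distributions emulating a mild-stroke SVD cohort of ~200
#' patients: age normal (65.6, 11.3) years, 74% hypertensive, 45.6% lacunar
#' stroke, total Fazekas score 0-6 and basal ganglia perivascular space
#' (PVS) and SVD summary scores with empirically typical category
#' frequencies. Centrum semiovale PVS, mean arterial pressure and diabetes
#' prevalence are not tabulated for such cohorts in comparable detail, so
#' plausible values are used. Covariates are sampled independently by
#' default; see `latent_severity` in [phantom_spec()] to induce
#' correlation.
#'
#' @return A named list of distribution parameter lists.
#' @export
default_covariate_model <- function() {
  list(
    age           = list(mean = 65.6, sd = 11.3),
    hypertension  = list(prob = 151 / 204),
    stroke_subtype = list(prob_lacunar = 93 / 204),
    fazekas       = list(probs = c(7, 16, 76, 23, 30, 20, 32) / 204),
    bg_pvs        = list(probs = c(4, 103, 55, 26, 16) / 204),
    cs_pvs        = list(probs = c(0.10, 0.35, 0.30, 0.15, 0.10)),
    svd_score     = list(probs = c(69, 49, 47, 26, 13) / 204),
    map_mmHg      = list(mean = 100, sd = 13),
    diabetes      = list(prob = 0.15)
  )
}

check_probs <- function(p, name, len = NULL) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("configuration error: invalid probabilities for ", name, call. = FALSE)
  if (!is.null(len) && length(p) != len)
    stop("configuration error: ", name, " needs ", len, " probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("configuration error: probabilities for ", name, " must sum to 1", call. = FALSE)
  invisible(p)
}

#' Specification of a synthetic phantom cohort
#'
#' Describes the generative model for a cohort of paired pre/post-contrast
#' volumes with tissue masks and clinical covariates. Ground-truth effects
#' are injected through two channels: (i) texture smoothness - white noise
#' smoothed in-plane with a Gaussian kernel whose sd is affine in the SVD
#' score and age, so higher disease burden yields spatially smoother (more
#' "homogeneous") texture; and (ii) post-contrast leakage - intensity
#' increments added inside tissue masks, with the CSF increment
#' proportional to the Fazekas score (gadolinium leaking into CSF with
#' worsening white matter disease).
#'
#' The leakage increment is spatially modulated by a smooth positive
#' random field with unit mean (`leakage_heterogeneity` is the log-scale
#' sd of that field; 0 gives a spatially constant increment), because
#' contrast agent accumulates unevenly and a perfectly uniform offset
#' would be invisible to co-occurrence texture.
#'
#' @param n_patients Number of patients (>= 1).
#' @param volume_shape Integer vector (rows, cols, slices), each >= c(32, 32, 8).
#' @param tissue_means Named baseline intensities for CSF, DGM, NAWM, WMH,
#'   stroke (arbitrary FLAIR-like units; CSF dark, WMH bright).
#' @param noise_sd Standard deviation of the white intensity noise.
#' @param smoothness_base Baseline Gaussian smoothing kernel sd (voxels).
#' @param smoothness_slope_svd Added kernel sd per unit SVD score (0-4).
#' @param smoothness_slope_age Added kernel sd per decade of age above 65.
#' @param leakage_csf_per_fazekas Post-contrast CSF mean increment per unit
#'   Fazekas score (intensity units).
#' @param leakage_tissue Named post-contrast increments for NAWM and WMH.
#' @param leakage_heterogeneity Log-sd of the unit-mean lognormal spatial
#'   modulation applied to leakage increments.
#' @param latent_severity Weight in `[0, 1]` coupling ordinal scores to a
#'   shared latent severity; 0 (default) samples covariates independently.
#' @param covariate_model As returned by [default_covariate_model()].
#' @param seed Integer seed recorded in the spec; [generate_cohort()] sets
#'   it, making cohorts bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 204,
                         volume_shape = c(32L, 32L, 8L),
                         tissue_means = c(CSF = 20, DGM = 90, NAWM = 100,
                                          WMH = 140, stroke = 125),
                         noise_sd = 10,
                         smoothness_base = 0.5,
                         smoothness_slope_svd = 0.003,
                         smoothness_slope_age = 0,
                         leakage_csf_per_fazekas = 2,
                         leakage_tissue = c(NAWM = 1, WMH = 3),
                         leakage_heterogeneity = 0.5,
                         latent_severity = 0,
                         covariate_model = default_covariate_model(),
                         seed = NULL) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("configuration error: n_patients must be >= 1", call. = FALSE)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < c(32L, 32L, 8L)))
    stop("configuration error: volume_shape must be at least 32 x 32 x 8",
         call. = FALSE)
  if (!all(TISSUES %in% names(tissue_means)))
    stop("configuration error: tissue_means must name ",
         paste(TISSUES, collapse = ", "), call. = FALSE)
  for (p in c(noise_sd, smoothness_base, smoothness_slope_svd,
              smoothness_slope_age, leakage_heterogeneity))
    if (!is.finite(p) || p < 0)
      stop("configuration error: noise/smoothness/heterogeneity parameters must be >= 0",
           call. = FALSE)
  if (latent_severity < 0 || latent_severity > 1)
    stop("configuration error: latent_severity must lie in [0, 1]", call. = FALSE)
  cm <- covariate_model
  if (!is.finite(cm$age$sd) || cm$age$sd <= 0 ||
      !is.finite(cm$map_mmHg$sd) || cm$map_mmHg$sd <= 0)
    stop("configuration error: age/MAP sd must be positive", call. = FALSE)
  for (nm in c("hypertension", "diabetes"))
    if (cm[[nm]]$prob < 0 || cm[[nm]]$prob > 1)
      stop("configuration error: ", nm, " probability outside [0, 1]", call. = FALSE)
  if (cm$stroke_subtype$prob_lacunar < 0 || cm$stroke_subtype$prob_lacunar > 1)
    stop("configuration error: stroke subtype probability outside [0, 1]", call. = FALSE)
  check_probs(cm$fazekas$probs, "fazekas", 7)
  check_probs(cm$bg_pvs$probs, "bg_pvs", 5)
  check_probs(cm$cs_pvs$probs, "cs_pvs")
  check_probs(cm$svd_score$probs, "svd_score", 5)

  structure(list(
    n_patients = as.integer(n_patients),
    volume_shape = volume_shape,
    tissue_means = tissue_means[TISSUES],
    noise_sd = noise_sd,
    smoothness_base = smoothness_base,
    smoothness_slope_svd = smoothness_slope_svd,
    smoothness_slope_age = smoothness_slope_age,
    leakage_csf_per_fazekas = leakage_csf_per_fazekas,
    leakage_tissue = leakage_tissue,
    leakage_heterogeneity = leakage_heterogeneity,
    latent_severity = latent_severity,
    covariate_model = cm,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "phantom_spec")
}

sample_categorical <- function(n, probs, latent = NULL, weight = 0) {
  k <- length(probs)
  if (weight <= 0 || is.null(latent)) {
    sample(0:(k - 1), n, replace = TRUE, prob = probs)
  } else {
    # quantile coupling: a shared severity percentile is blended with an
    # independent uniform, then inverted through the categorical CDF
    u <- weight * latent + (1 - weight) * stats::runif(n)
    as.integer(cut(u, breaks = c(0, cumsum(probs)), labels = FALSE,
                   include.lowest = TRUE)) - 1L
  }
}

#' Sample clinical covariates for a phantom cohort
#'
#' Draws `n` covariate rows from the distributions in `spec$covariate_model`
#' using the current RNG state. Ordinal scores stay within their declared
#' supports (Fazekas 0-6, PVS 0-4, SVD 0-4).
#'
#' @param spec A [phantom_spec()].
#' @param n Number of patients; defaults to `spec$n_patients`.
#' @return A data.frame with one row per patient.
#' @export
sample_covariates <- function(spec, n = spec$n_patients) {
  stopifnot(inherits(spec, "phantom_spec"))
  cm <- spec$covariate_model
  w <- spec$latent_severity
  latent <- if (w > 0) stats::runif(n) else NULL
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = cm$age$mean + cm$age$sd * (if (w > 0) stats::qnorm(w * latent + (1 - w) * stats::runif(n)) else stats::rnorm(n)),
    hypertension = stats::rbinom(n, 1L, cm$hypertension$prob),
    stroke_subtype = ifelse(stats::rbinom(n, 1L, cm$stroke_subtype$prob_lacunar) == 1L,
                            "lacunar", "cortical"),
    fazekas = sample_categorical(n, cm$fazekas$probs, latent, w),
    bg_pvs = sample_categorical(n, cm$bg_pvs$probs, latent, w),
    cs_pvs = sample_categorical(n, cm$cs_pvs$probs, latent, w),
    svd_score = sample_categorical(n, cm$svd_score$probs, latent, w),
    map_mmHg = stats::rnorm(n, cm$map_mmHg$mean, cm$map_mmHg$sd),
    diabetes = stats::rbinom(n, 1L, cm$diabetes$prob),
    stringsAsFactors = FALSE
  )
}

#' Effective smoothing kernel sd for one patient
#'
#' Affine in SVD score and age: `base + slope_svd * svd + slope_age *
#' (age - 65) / 10`, floored at 0.
#'
#' @param spec A [phantom_spec()].
#' @param svd_score,age Patient covariates.
#' @return Kernel sd in voxels.
#' @export
smoothing_sd <- function(spec, svd_score, age) {
  max(0, spec$smoothness_base +
        spec$smoothness_slope_svd * svd_score +
        spec$smoothness_slope_age * (age - 65) / 10)
}

ball_mask <- function(I, J, K, ctr, r, z_flatten = 2) {
  (I - ctr[1])^2 + (J - ctr[2])^2 + ((K - ctr[3]) * z_flatten)^2 <= r^2
}

#' Place the five tissue masks for one phantom patient
#'
#' Deterministic geometry given covariates and the RNG state: a central
#' ellipsoid of CSF (ventricles), an ellipsoidal shell of deep gray matter
#' around it, a large white matter shell (NAWM), one index stroke lesion
#' blob and `1 + 2 * fazekas` WMH patches carved out of the NAWM, so WMH
#' load grows with the Fazekas score. All masks are pairwise disjoint and
#' nonempty by construction.
#'
#' @param spec A [phantom_spec()].
#' @param covariates One covariate row.
#' @return Named list of logical 3D arrays (NAWM, DGM, WMH, CSF, stroke).
#' @export
place_masks <- function(spec, covariates) {
  d <- spec$volume_shape
  ctr <- (d + 1) / 2
  I <- slice.index(array(0L, d), 1)
  J <- slice.index(array(0L, d), 2)
  K <- slice.index(array(0L, d), 3)
  ell <- function(a, b, c) {
    ((I - ctr[1]) / a)^2 + ((J - ctr[2]) / b)^2 + ((K - ctr[3]) / c)^2 <= 1
  }
  csf <- ell(0.16 * d[1], 0.16 * d[2], 0.32 * d[3])
  dgm_outer <- ell(0.25 * d[1], 0.25 * d[2], 0.44 * d[3])
  brain <- ell(0.44 * d[1], 0.44 * d[2], 0.50 * d[3])
  dgm <- dgm_outer & !csf
  nawm <- brain & !dgm_outer

  carve <- function(nawm, r) {
    cand <- which(nawm)
    ctr_vox <- arrayInd(cand[sample.int(length(cand), 1L)], d)
    ball <- ball_mask(I, J, K, as.numeric(ctr_vox), r) & nawm
    ball
  }
  stroke <- carve(nawm, 2.5)
  nawm <- nawm & !stroke
  wmh <- array(FALSE, d)
  n_patch <- 1L + 2L * covariates$fazekas
  r_patch <- 1.5 + 0.1 * covariates$fazekas
  for (i in seq_len(n_patch)) {
    patch <- carve(nawm & !wmh, r_patch)
    wmh <- wmh | patch
  }
  nawm <- nawm & !wmh
  if (!all(vapply(list(nawm, dgm, wmh, csf, stroke), any, logical(1))))
    stop("generation error: could not place all masks disjointly", call. = FALSE)
  list(NAWM = nawm, DGM = dgm, WMH = wmh, CSF = csf, stroke = stroke)
}

#' Generate one phantom patient
#'
#' Pre-contrast volume = tissue baseline means + in-plane Gaussian-smoothed
#' white noise (kernel sd from [smoothing_sd()]); post-contrast volume =
#' pre + leakage increments (CSF increment mean = `leakage_csf_per_fazekas
#' * fazekas`, NAWM/WMH increments from `leakage_tissue`), each modulated
#' by a smooth unit-mean lognormal field when `leakage_heterogeneity > 0`.
#' Uses the current RNG state; draw order is fixed so identical seeds give
#' identical patients.
#'
#' @param spec A [phantom_spec()].
#' @param covariates One row as produced by [sample_covariates()].
#' @return An object of class `phantom_patient` with elements `patient_id`,
#'   `covariates`, `pre`, `post`, `masks`.
#' @export
generate_patient <- function(spec, covariates) {
  stopifnot(inherits(spec, "phantom_spec"), nrow(covariates) == 1)
  d <- spec$volume_shape
  masks <- place_masks(spec, covariates)
  ksd <- smoothing_sd(spec, covariates$svd_score, covariates$age)

  noise <- smooth_volume_inplane(array(stats::rnorm(prod(d), 0, spec$noise_sd), d), ksd)
  base <- array(0, d)
  for (t in TISSUES) base[masks[[t]]] <- spec$tissue_means[[t]]
  pre <- base + noise

  # leakage modulation field: smoothed, rescaled to unit marginal sd, then
  # exponentiated to a positive unit-mean field; drawn unconditionally so
  # the RNG stream does not depend on the leakage parameters
  z <- smooth_volume_inplane(array(stats::rnorm(prod(d)), d), 1)
  z <- z / stats::sd(z)
  h <- spec$leakage_heterogeneity
  mod <- exp(h * z - h^2 / 2)

  post <- pre
  inc_csf <- spec$leakage_csf_per_fazekas * covariates$fazekas
  if (inc_csf != 0) post[masks$CSF] <- post[masks$CSF] + inc_csf * mod[masks$CSF]
  for (t in names(spec$leakage_tissue)) {
    inc <- spec$leakage_tissue[[t]]
    if (inc != 0) post[masks[[t]]] <- post[masks[[t]]] + inc * mod[masks[[t]]]
  }

  structure(list(
    patient_id = covariates$patient_id,
    covariates = covariates,
    pre = pre,
    post = post,
    masks = masks
  ), class = "phantom_patient")
}

#' Generate a phantom cohort
#'
#' Seeds the RNG from `spec$seed` (when set), samples covariates, and
#' generates every patient in patient-id order. With `dir` given, writes
#' `<id>_pre.nii.gz`, `<id>_post.nii.gz`, `<id>_mask_<tissue>.nii.gz`,
#' `covariates.csv` and `phantom_spec.yaml` into it.
#'
#' @param spec A [phantom_spec()].
#' @param dir Optional output directory (created if missing).
#' @return Invisibly, a list with `patients` (list of `phantom_patient`),
#'   `covariates` (data.frame) and `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  covs <- sample_covariates(spec)
  patients <- lapply(seq_len(spec$n_patients), function(i) {
    generate_patient(spec, covs[i, , drop = FALSE])
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(covs, file.path(dir, "covariates.csv"), row.names = FALSE)
    spec_out <- spec
    spec_out$tissue_means <- as.list(spec_out$tissue_means)
    spec_out$leakage_tissue <- as.list(spec_out$leakage_tissue)
    yaml::write_yaml(unclass(spec_out), file.path(dir, "phantom_spec.yaml"))
    for (p in patients) {
      RNifti::writeNifti(p$pre, file.path(dir, paste0(p$patient_id, "_pre.nii.gz")))
      RNifti::writeNifti(p$post, file.path(dir, paste0(p$patient_id, "_post.nii.gz")))
      for (t in TISSUES) {
        RNifti::writeNifti(array(as.integer(p$masks[[t]]), dim(p$masks[[t]])),
                           file.path(dir, paste0(p$patient_id, "_mask_", t, ".nii.gz")))
      }
    }
  }
  invisible(list(patients = patients, covariates = covs, spec = spec))
}
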