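DESCRIPTORS <- c("contrast", "glcm_variance", "entropy",
                 "correlation", "homogeneity", "energy")

#' Class of a texture descriptor
#'
#' Descriptors expressing textural uniformity (correlation, homogeneity,
#' energy) form the homogeneity class; those expressing disorder
#' (contrast, GLCM variance, entropy) the variability class.
#'
#' @param descriptor Character vector of descriptor names.
#' @return Character vector, `"homogeneity"` or `"variability"`.
#' @export
descriptor_class <- function(descriptor) {
  ifelse(descriptor %in% c("correlation", "homogeneity", "energy"),
         "homogeneity", "variability")
}

group_test_result <- function(statistic, df, p, values, groups, test,
                              flags = character(0)) {
  med <- c(tapply(values, groups, stats::median))
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p),
                 group_medians = med,
                 n_per_group = as.integer(table(groups)),
                 test = test, flags = flags),
            class = "group_test")
}

check_groups <- function(values, groups, min_groups = 2) {
  stopifnot(length(values) == length(groups))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < min_groups)
    stop("need at least ", min_groups, " nonempty groups", call. = FALSE)
  groups
}

#' Kruskal-Wallis rank test across patient groups
#'
#' Tests whether the distribution of a descriptor is the same across
#' groups, using the tie-corrected chi-square approximation with k - 1
#' degrees of freedom. Invariant under strictly monotone transforms of the
#' values. All values identical is reported as H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (>= 2 groups).
#' @return A `group_test` result: `statistic`, `df`, `p_value`,
#'   `group_medians`, `n_per_group`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- check_groups(values, groups)
  if (length(unique(values)) == 1L)
    return(group_test_result(0, nlevels(groups) - 1L, 1, values, groups,
                             "kruskal_wallis", "all_values_identical"))
  kt <- stats::kruskal.test(values, groups)
  group_test_result(kt$statistic, kt$parameter, kt$p.value, values, groups,
                    "kruskal_wallis")
}

#' Mood's median test across patient groups
#'
#' Classifies every observation as above versus not-above the grand median
#' of the pooled values (ties count as not-above) and applies a Pearson
#' chi-square test without continuity correction to the resulting 2 x k
#' table. Degenerate splits (all observations on one side) yield
#' statistic 0, p = 1 with a flag; expected cell counts below 1 set a
#' `low_expected_count` flag.
#'
#' @param values Numeric vector (pooled n >= 4).
#' @param groups Grouping vector (>= 2 groups).
#' @return A `group_test` result.
#' @export
mood_median <- function(values, groups) {
  groups <- check_groups(values, groups)
  if (length(values) < 4)
    stop("Mood's median test needs pooled n >= 4", call. = FALSE)
  gm <- stats::median(values)
  above <- factor(values > gm, levels = c(FALSE, TRUE))
  tab <- table(groups, above)
  if (any(colSums(tab) == 0))
    return(group_test_result(0, nlevels(groups) - 1L, 1, values, groups,
                             "mood_median", "degenerate_median_split"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  flags <- if (any(ct$expected < 1)) "low_expected_count" else character(0)
  group_test_result(ct$statistic, ct$parameter, ct$p.value, values, groups,
                    "mood_median", flags)
}

merge_features_covariates <- function(features, covariates, tissue,
                                      descriptor) {
  stopifnot(descriptor %in% DESCRIPTORS)
  f <- features[features$tissue == tissue, , drop = FALSE]
  if (nrow(f) == 0) stop("no feature rows for tissue ", tissue, call. = FALSE)
  merge(f, covariates, by = "patient_id")
}

assert_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("collinearity error: rank-deficient design, offending column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(X)
}

#' ANCOVA of post-contrast on pre-contrast texture
#'
#' Fits, for one tissue and descriptor, the covariance model
#' `post = X1 * pre + X2 * age + X3 * fazekas + X4 * bg_pvs +
#' X5 * hypertension` (with intercept) by least squares. Ordinal scores
#' enter as numeric linear terms; hypertension is 0/1.
#'
#' @param features Feature table from [cohort_features()] /
#'   [extract_features()] (one timepoint per row).
#' @param covariates Covariate table with `patient_id`, `age`, `fazekas`,
#'   `bg_pvs`, `hypertension`.
#' @param tissue Tissue name.
#' @param descriptor One of the six descriptor column names.
#' @return A list of class `ancova_result`: `coefficients` (data.frame
#'   with estimate, std_error, p_value), `residual_df`, `n`, plus the
#'   fitted `lm` object in `fit`.
#' @export
ancova_post_on_pre <- function(features, covariates, tissue, descriptor) {
  m <- merge_features_covariates(features, covariates, tissue, descriptor)
  pre <- m[m$timepoint == "pre", c("patient_id", descriptor)]
  post <- m[m$timepoint == "post", c("patient_id", descriptor, "age",
                                     "fazekas", "bg_pvs", "hypertension")]
  names(pre)[2] <- "pre_value"
  names(post)[2] <- "post_value"
  d <- merge(pre, post, by = "patient_id")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10)
    stop("need at least 10 complete records for the ANCOVA", call. = FALSE)
  X <- stats::model.matrix(~ pre_value + age + fazekas + bg_pvs + hypertension,
                           data = d)
  assert_full_rank(X)
  fit <- stats::lm(post_value ~ pre_value + age + fazekas + bg_pvs + hypertension,
                   data = d)
  s <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(s), estimate = s[, 1],
                              std_error = s[, 2], p_value = s[, 4],
                              row.names = NULL),
    residual_df = fit$df.residual, n = nrow(d), fit = fit
  ), class = "ancova_result")
}

#' Linear mixed model for paired pre/post-contrast texture
#'
#' Fits, for one tissue and descriptor, a REML random-intercept model with
#' two measurements (pre- and post-contrast) per patient:
#' `value ~ timepoint * fazekas + stroke_subtype + age + bg_pvs + cs_pvs +
#' map_mmHg + diabetes + (1 | patient)`, where `timepoint` is coded 0 =
#' pre, 1 = post, so the `timepoint:fazekas` interaction measures whether
#' the pre-to-post change grows with white matter disease burden.
#' Confidence intervals and p-values for fixed effects use the Wald normal
#' approximation.
#'
#' @param features Feature table with both timepoints per patient.
#' @param covariates Covariate table.
#' @param tissue Tissue name (the CSF pre/post model of interest uses
#'   `"CSF"`).
#' @param descriptor Descriptor column name.
#' @return A list of class `mixed_model_result`: `fixed_effects`
#'   (data.frame with estimate, std_error, ci_lo, ci_hi, p_value),
#'   `random_intercept_var`, `residual_var`, `boundary` flag, `n_patients`,
#'   and the `lmerMod` object in `fit` (NULL in the constant-response
#'   degenerate case).
#' @export
mixed_pre_post <- function(features, covariates, tissue, descriptor) {
  m <- merge_features_covariates(features, covariates, tissue, descriptor)
  d <- data.frame(
    patient_id = m$patient_id,
    value = m[[descriptor]],
    post = as.integer(m$timepoint == "post"),
    stroke_lacunar = as.integer(m$stroke_subtype == "lacunar"),
    age = m$age, bg_pvs = m$bg_pvs, cs_pvs = m$cs_pvs,
    fazekas = m$fazekas, map_mmHg = m$map_mmHg, diabetes = m$diabetes
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  tp_per_patient <- table(table(d$patient_id))
  if (!identical(names(tp_per_patient), "2"))
    stop("each patient must contribute exactly two rows (pre and post)",
         call. = FALSE)
  if (stats::var(d$value) == 0) {
    # constant response: both variance components on the 0 boundary and a
    # pure intercept fit
    fe <- data.frame(term = "(Intercept)", estimate = d$value[1],
                     std_error = 0, ci_lo = d$value[1], ci_hi = d$value[1],
                     p_value = NA_real_, row.names = NULL)
    return(structure(list(fixed_effects = fe, random_intercept_var = 0,
                          residual_var = 0, boundary = TRUE,
                          n_patients = length(unique(d$patient_id)),
                          fit = NULL),
                     class = "mixed_model_result"))
  }
  fit <- lme4::lmer(
    value ~ post * fazekas + stroke_lacunar + age + bg_pvs + cs_pvs +
      map_mmHg + diabetes + (1 | patient_id),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code < 0)
    stop("mixed-model non-convergence: ",
         paste(unlist(conv$messages), collapse = "; "), call. = FALSE)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "patient_id"]
  res_var <- vc$vcov[vc$grp == "Residual"]
  structure(list(
    fixed_effects = data.frame(
      term = names(est), estimate = unname(est), std_error = unname(se),
      ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
      p_value = unname(2 * stats::pnorm(-abs(z))), row.names = NULL),
    random_intercept_var = ri_var,
    residual_var = res_var,
    boundary = ri_var < 1e-8,
    n_patients = length(unique(d$patient_id)),
    fit = fit
  ), class = "mixed_model_result")
}

#' Battery of nonparametric group comparisons
#'
#' Runs the Kruskal-Wallis and Mood's median tests for every combination
#' of tissue, descriptor and timepoint in the feature table, grouping
#' patients by one clinical variable (hypertension, stroke subtype, basal
#' ganglia PVS score, or SVD score; ordinal scores form one group per
#' level). Groups with fewer than 2 patients are excluded with a warning.
#' No multiple-testing correction is applied to the reported `p`;
#' `p_adjusted` optionally adds a Benjamini-Hochberg-adjusted column
#' (within each test type) as a clearly separate extra.
#'
#' @param features Feature table.
#' @param covariates Covariate table containing the grouping column.
#' @param grouping One of `"hypertension"`, `"stroke_subtype"`,
#'   `"bg_pvs"`, `"svd_score"` (any covariate column is accepted).
#' @param tissues Optional subset of tissues.
#' @param timepoints Timepoints to include (default pre and post).
#' @param p_adjusted Add a BH-adjusted p-value column.
#' @return A tidy data.frame: tissue, descriptor, descriptor_class, test,
#'   grouping, timepoint, statistic, df, p, n_groups, n_total.
#' @export
run_comparison_battery <- function(features, covariates, grouping,
                                   tissues = NULL,
                                   timepoints = c("pre", "post"),
                                   p_adjusted = FALSE) {
  if (!grouping %in% names(covariates))
    stop("configuration error: grouping column '", grouping,
         "' not in covariates", call. = FALSE)
  g_all <- droplevels(as.factor(covariates[[grouping]]))
  keep_levels <- names(which(table(g_all) >= 2))
  if (length(keep_levels) < nlevels(g_all))
    warning("excluding group level(s) with < 2 patients: ",
            paste(setdiff(levels(g_all), keep_levels), collapse = ", "))
  if (length(keep_levels) < 2)
    stop("configuration error: fewer than 2 usable groups for '", grouping,
         "'", call. = FALSE)
  covs <- covariates[g_all %in% keep_levels, , drop = FALSE]
  if (is.null(tissues)) tissues <- unique(features$tissue)
  out <- list()
  for (tis in tissues) {
    f <- features[features$tissue == tis, , drop = FALSE]
    m <- merge(f, covs[, c("patient_id", grouping)], by = "patient_id")
    for (tp in timepoints) {
      mt <- m[m$timepoint == tp, , drop = FALSE]
      if (nrow(mt) == 0) next
      grp <- droplevels(as.factor(mt[[grouping]]))
      for (desc in DESCRIPTORS) {
        vals <- mt[[desc]]
        ok <- !is.na(vals)
        for (fun in list(kruskal_wallis, mood_median)) {
          res <- fun(vals[ok], grp[ok])
          out[[length(out) + 1L]] <- data.frame(
            tissue = tis, descriptor = desc,
            descriptor_class = descriptor_class(desc),
            test = res$test, grouping = grouping, timepoint = tp,
            statistic = res$statistic, df = res$df, p = res$p_value,
            n_groups = length(res$n_per_group),
            n_total = sum(res$n_per_group))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (p_adjusted) {
    res$p_bh <- NA_real_
    for (tt in unique(res$test)) {
      sel <- res$test == tt
      res$p_bh[sel] <- stats::p.adjust(res$p[sel], method = "BH")
    }
  }
  res
}
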