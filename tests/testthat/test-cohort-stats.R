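test_that("Kruskal-Wallis matches the rank formula on a tie-free example", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                        rep(c("a", "b", "c"), each = 3))
  expect_equal(res$statistic, 7.2)
  expect_identical(res$df, 2L)
  expect_equal(res$p_value, 1 - pchisq(7.2, 2))
})

test_that("identical groups give H = 0 and p = 1", {
  res <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- kruskal_wallis(rep(4, 8), rep(c("a", "b"), 4))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(41)
  v <- rnorm(60)
  g <- rep(1:3, each = 20)
  base <- kruskal_wallis(v, g)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) rank(x))) {
    tr <- kruskal_wallis(f(v), g)
    expect_equal(tr$statistic, base$statistic, tolerance = 1e-12)
    expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis type-I error sits at the nominal level", {
  set.seed(42)
  rej <- replicate(1000, {
    kruskal_wallis(rnorm(50), rep(1:2, each = 25))$p_value < 0.05
  })
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(mean(rej), ci[1])
  expect_lt(mean(rej), ci[2])
})

test_that("Mood's median test matches the 2x2 chi-square on split groups", {
  res <- mood_median(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 6.0)
  expect_identical(res$df, 1L)
  expect_equal(res$group_medians, c(a = 2, b = 8))
})

test_that("Mood's test degenerates gracefully", {
  # identical groups: no association with the median split
  res <- mood_median(c(1, 2, 3, 4, 1, 2, 3, 4), rep(c("a", "b"), each = 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # all values equal: nothing is above the grand median
  res2 <- mood_median(rep(2, 8), rep(c("a", "b"), each = 4))
  expect_true("degenerate_median_split" %in% res2$flags)
  expect_equal(res2$p_value, 1)
})

test_that("Mood's test is invariant under monotone transforms preserving the split", {
  set.seed(43)
  v <- rnorm(40)
  g <- rep(1:2, each = 20)
  base <- mood_median(v, g)
  tr <- mood_median(exp(v), g)
  expect_equal(tr$statistic, base$statistic, tolerance = 1e-12)
})

make_ancova_cohort <- function(n = 60, beta = c(2, 0.8, -0.05, 0.3, 0.12, 1.5),
                               noise = 0, seed = 44) {
  set.seed(seed)
  cov <- data.frame(patient_id = sprintf("P%03d", 1:n),
                    age = rnorm(n, 65, 10),
                    fazekas = sample(0:6, n, replace = TRUE),
                    bg_pvs = sample(0:4, n, replace = TRUE),
                    hypertension = rbinom(n, 1, 0.7))
  pre <- rnorm(n, 10, 2)
  post <- beta[1] + beta[2] * pre + beta[3] * cov$age + beta[4] * cov$fazekas +
    beta[5] * cov$bg_pvs + beta[6] * cov$hypertension + rnorm(n, 0, noise)
  feat <- rbind(
    data.frame(patient_id = cov$patient_id, tissue = "NAWM", timepoint = "pre",
               homogeneity = pre),
    data.frame(patient_id = cov$patient_id, tissue = "NAWM", timepoint = "post",
               homogeneity = post))
  list(features = feat, covariates = cov, beta = beta)
}

test_that("ANCOVA recovers noise-free coefficients exactly", {
  d <- make_ancova_cohort()
  # a perfect fit makes summary.lm grumble; that is the point of the test
  res <- suppressWarnings(
    ancova_post_on_pre(d$features, d$covariates, "NAWM", "homogeneity"))
  expect_equal(res$coefficients$estimate, d$beta, tolerance = 1e-8)
  expect_identical(res$residual_df, res$n - 6L)
})

test_that("a duplicated predictor raises a collinearity error naming it", {
  d <- make_ancova_cohort()
  d$covariates$bg_pvs <- d$covariates$age  # bg_pvs now aliases age
  expect_error(ancova_post_on_pre(d$features, d$covariates, "NAWM",
                                  "homogeneity"),
               "collinearity.*bg_pvs")
})

make_lmm_cohort <- function(n = 200, b_interaction = 0.4, ri_sd = 1,
                            res_sd = 0.5, seed = 45) {
  set.seed(seed)
  cov <- data.frame(patient_id = sprintf("P%03d", 1:n),
                    age = rnorm(n, 65, 10),
                    stroke_subtype = sample(c("lacunar", "cortical"), n, TRUE),
                    fazekas = sample(0:6, n, replace = TRUE),
                    bg_pvs = sample(0:4, n, replace = TRUE),
                    cs_pvs = sample(0:4, n, replace = TRUE),
                    map_mmHg = rnorm(n, 100, 12),
                    diabetes = rbinom(n, 1, 0.2))
  b <- c(intercept = 5, post = 1, fazekas = 0.2, lacunar = -0.3, age = 0.01,
         bg_pvs = 0.05, cs_pvs = -0.02, map = 0.005, diabetes = 0.1)
  ri <- rnorm(n, 0, ri_sd)
  val <- function(post) {
    b["intercept"] + b["post"] * post + b["fazekas"] * cov$fazekas +
      b_interaction * post * cov$fazekas +
      b["lacunar"] * (cov$stroke_subtype == "lacunar") + b["age"] * cov$age +
      b["bg_pvs"] * cov$bg_pvs + b["cs_pvs"] * cov$cs_pvs +
      b["map"] * cov$map_mmHg + b["diabetes"] * cov$diabetes +
      ri + rnorm(n, 0, res_sd)
  }
  feat <- rbind(
    data.frame(patient_id = cov$patient_id, tissue = "CSF", timepoint = "pre",
               contrast = val(0)),
    data.frame(patient_id = cov$patient_id, tissue = "CSF", timepoint = "post",
               contrast = val(1)))
  list(features = feat, covariates = cov, b_interaction = b_interaction)
}

test_that("with zero random-intercept variance the LMM collapses onto OLS", {
  d <- make_lmm_cohort(n = 120, ri_sd = 0, res_sd = 0.8, seed = 46)
  res <- mixed_pre_post(d$features, d$covariates, "CSF", "contrast")
  m <- merge(d$features, d$covariates, by = "patient_id")
  m$post <- as.integer(m$timepoint == "post")
  m$stroke_lacunar <- as.integer(m$stroke_subtype == "lacunar")
  ols <- lm(contrast ~ post * fazekas + stroke_lacunar + age + bg_pvs +
              cs_pvs + map_mmHg + diabetes, data = m)
  expect_equal(res$fixed_effects$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_true(res$boundary)
})

test_that("the interaction CI covers the truth at the nominal rate", {
  covered <- vapply(1:200, function(k) {
    d <- make_lmm_cohort(seed = 1000 + k)
    res <- mixed_pre_post(d$features, d$covariates, "CSF", "contrast")
    fe <- res$fixed_effects
    row <- fe[fe$term == "post:fazekas", ]
    row$ci_lo <= d$b_interaction && d$b_interaction <= row$ci_hi
  }, logical(1))
  ci <- 0.95 + c(-1, 1) * 1.96 * sqrt(0.95 * 0.05 / 200)
  expect_gt(mean(covered), ci[1])
  expect_lt(mean(covered), ci[2])
})

test_that("a constant response pins both variance components at zero", {
  d <- make_lmm_cohort(n = 30, seed = 47)
  d$features$contrast <- 3.5
  res <- mixed_pre_post(d$features, d$covariates, "CSF", "contrast")
  expect_true(res$boundary)
  expect_equal(res$random_intercept_var, 0)
  expect_equal(res$residual_var, 0)
  expect_equal(res$fixed_effects$estimate[1], 3.5)
})

test_that("the comparison battery is tidily shaped and classifies descriptors", {
  set.seed(48)
  coh <- generate_cohort(tiny_spec(n = 12, seed = 48))
  feat <- cohort_features(coh, n_levels = 16, tissues = c("NAWM", "CSF"))
  bat <- run_comparison_battery(feat, coh$covariates, "hypertension")
  # 2 tissues x 6 descriptors x 2 timepoints x 2 tests
  expect_identical(nrow(bat), 2L * 6L * 2L * 2L)
  expect_setequal(unique(bat$test), c("kruskal_wallis", "mood_median"))
  expect_identical(unique(bat$descriptor_class[bat$descriptor == "homogeneity"]),
                   "homogeneity")
  expect_identical(unique(bat$descriptor_class[bat$descriptor == "contrast"]),
                   "variability")
  expect_true(all(bat$p >= 0 & bat$p <= 1))
})

test_that("a single-level grouping is a configuration error", {
  set.seed(49)
  coh <- generate_cohort(tiny_spec(n = 8, seed = 49))
  feat <- cohort_features(coh, n_levels = 16, tissues = "NAWM")
  covs <- coh$covariates
  covs$hypertension <- 1L
  expect_error(run_comparison_battery(feat, covs, "hypertension"),
               "configuration")
})
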