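# flairtex

Masked-region GLCM texture analysis of paired pre- and post-contrast FLAIR
brain MRI, for studying cerebral small vessel disease (SVD) and subtle
blood–brain barrier leakage.

## What it does

In SVD, a slightly leaky blood–brain barrier lets intravenous gadolinium
seep into tissue and cerebrospinal fluid (CSF), where it raises the FLAIR
signal. Rather than pharmacokinetic modelling, this package characterizes
the *texture* of the FLAIR signal inside physiologically defined tissue
compartments — normal-appearing white matter (NAWM), deep gray matter
(DGM), white matter hyperintensities (WMH), CSF, and the index stroke
lesion — before and after contrast, and relates it to SVD severity markers
(Fazekas score, perivascular space ratings, SVD score, hypertension, age).

Per tissue and timepoint, in-mask intensities are normalized to the
volume's masked dynamic range, quantized into `N ∈ {8, 16, 32, 64}`
equally spaced gray levels (default 16), and summarized by six Haralick
descriptors of the symmetric, orientation-averaged gray-level
co-occurrence matrix at distance 1 (orientations 0°, 45°, 90°, 135°,
accumulated per axial slice and summed over the volume):

* homogeneity class: correlation, homogeneity `Σ P(i,j)/(1+(i−j)²)`,
  energy `Σ P(i,j)²`
* variability class: contrast `Σ (i−j)² P(i,j)`, GLCM variance
  `Σ (i−μ)² P(i,j)`, entropy `−Σ P log₂ P`

First-order statistics include the variance-to-mean ratio and its
pre/post difference (DVMR = VMR_post − VMR_pre). Cohort inference covers
Kruskal–Wallis and Mood's median group comparisons, ANCOVA of
post-contrast on pre-contrast texture (+ age, Fazekas, basal-ganglia PVS,
hypertension), and a random-intercept linear mixed model for the paired
pre/post measurements with a pre/post × Fazekas interaction.

A synthetic phantom module (`phantom_spec()`, `generate_cohort()`)
generates whole cohorts — volumes, disjoint tissue masks, covariates —
with known injected effects (texture smoothness increasing with SVD
score; heterogeneous CSF leakage increasing with Fazekas), so the entire
pipeline is validated against recoverable ground truth.

## Worked example

```r
library(flairtex)

spec <- phantom_spec(n_patients = 100, seed = 3)   # ~200-patient-cohort marginals
res  <- run_full_study(out_dir = "study_out", spec = spec)

subset(res$mixed_model, descriptor == "contrast" & term == "post:fazekas",
       select = c(term, estimate, ci_lo, ci_hi, p_value))
#>            term   estimate      ci_lo      ci_hi      p_value
#> 10 post:fazekas 0.06108776 0.05268415 0.06949137 4.633768e-46

subset(res$battery, tissue == "NAWM" & descriptor == "homogeneity" &
         grouping == "svd_score" & timepoint == "pre",
       select = c(test, statistic, df, p))
#>               test statistic df           p
#> 369 kruskal_wallis  17.01276  4 0.001921951
#> 370    mood_median  13.91834  4 0.007560289

aggregate(dvmr ~ tissue, data = res$dvmr, FUN = median)
#>   tissue      dvmr
#> 1    CSF -0.106765
#> 2    DGM  0.000000
#> 3   NAWM -0.001375
#> 4 stroke  0.000000
#> 5    WMH  0.007122
```

The mixed-model row says the pre-to-post change in CSF texture contrast
grows by ≈ 0.061 per Fazekas point (the injected leakage-with-disease
effect, recovered with a tight Wald CI). The battery rows say NAWM
homogeneity differs across SVD-score groups (both nonparametric tests) —
the injected smoothness gradient. The DVMR medians show the additive-shift
signature of leakage: CSF, whose mean rises most, drops its
variance-to-mean ratio; DGM and the stroke lesion receive no leakage and
sit at exactly zero; WMH, whose leakage is the most spatially
heterogeneous, rises slightly. `run_full_study()` also writes
`features.csv`, `mixed_model_csf.csv`, `ancova.csv`, `group_tests.csv`,
`dvmr.csv` and a run manifest into the output directory.

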