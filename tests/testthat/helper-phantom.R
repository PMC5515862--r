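# small cohort specs used across test files
tiny_spec <- function(n = 3, seed = 101, ...) {
  phantom_spec(n_patients = n, seed = seed, ...)
}

null_effect_spec <- function(n = 50, seed = 1, ...) {
  phantom_spec(n_patients = n, smoothness_slope_svd = 0,
               smoothness_slope_age = 0, leakage_csf_per_fazekas = 0,
               leakage_tissue = c(NAWM = 0, WMH = 0), seed = seed, ...)
}

# quantize a bare numeric array over a mask with an explicit range
quantize_array <- function(vol, mask = NULL, rng = NULL, n_levels = 8) {
  if (is.null(mask)) mask <- array(TRUE, dim(vol))
  if (is.null(rng)) rng <- range(vol[mask])
  quantize_region(vol, mask, rng, n_levels)
}
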