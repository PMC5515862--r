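#' First-order intensity statistics of a region
#'
#' Mean, sample variance (n - 1 denominator) and variance-to-mean ratio
#' (VMR) of the raw, un-quantized intensities of a masked region. The VMR
#' is flagged undefined (NA) when the mean magnitude falls below 1e-12.
#'
#' @param values Numeric vector of region intensities (a `masked_region`'s
#'   `values` element is also accepted).
#' @return A list of class `region_stats`: `mean`, `variance`, `vmr`,
#'   `n_voxels`.
#' @export
region_stats <- function(values) {
  if (inherits(values, "masked_region")) values <- values$values
  if (length(values) < 2)
    stop("insufficient-data error: need at least 2 voxels", call. = FALSE)
  m <- mean(values)
  v <- stats::var(values)
  vmr <- if (abs(m) < 1e-12) NA_real_ else v / m
  structure(list(mean = m, variance = v, vmr = vmr,
                 n_voxels = length(values)),
            class = "region_stats")
}

#' Pre/post-contrast difference in the variance-to-mean ratio (DVMR)
#'
#' `DVMR = VMR_post - VMR_pre`, computed on the raw FLAIR intensities of a
#' tissue region. Undefined (NA) if either VMR is undefined. Antisymmetric:
#' `dvmr(a, b) == -dvmr(b, a)`.
#'
#' @param pre_stats,post_stats `region_stats` of the same tissue at the two
#'   timepoints.
#' @return Signed scalar, or NA if undefined.
#' @export
dvmr <- function(pre_stats, post_stats) {
  stopifnot(inherits(pre_stats, "region_stats"),
            inherits(post_stats, "region_stats"))
  if (is.na(pre_stats$vmr) || is.na(post_stats$vmr)) return(NA_real_)
  post_stats$vmr - pre_stats$vmr
}
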