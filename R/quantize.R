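ALLOWED_LEVELS <- c(8L, 16L, 32L, 64L)

#' Normalize intensities to the unit interval
#'
#' Maps `v` to `clip((v - lo) / (hi - lo), 0, 1)`. Values outside
#' `[lo, hi]` are clipped rather than rejected, which makes the mapping
#' robust to mask-edge effects. A degenerate range (`hi == lo`) maps
#' everything to 0 and is flagged.
#'
#' @param values Numeric vector.
#' @param lo,hi Scaling range, `hi >= lo`.
#' @return Numeric vector in `[0, 1]` with attribute `degenerate_range`.
#' @export
normalize_intensities <- function(values, lo, hi) {
  stopifnot(is.finite(lo), is.finite(hi), hi >= lo)
  if (hi == lo) {
    warning("degenerate scaling range (hi == lo); all values mapped to 0")
    out <- rep(0, length(values))
    attr(out, "degenerate_range") <- TRUE
    return(out)
  }
  out <- pmin(pmax((values - lo) / (hi - lo), 0), 1)
  attr(out, "degenerate_range") <- FALSE
  out
}

#' Uniform quantization into N equally spaced gray levels
#'
#' `level = min(floor(v * N) + 1, N)` for normalized `v` in `[0, 1]`:
#' equal-width bins, 1-based levels, level N attained at `v = 1`.
#' Doubling N refines exactly (levels at N = 32 collapse pairwise onto
#' levels at N = 16).
#'
#' @param values Normalized values in `[0, 1]`.
#' @param n_levels One of 8, 16, 32, 64 (other values allowed only with
#'   `allow_nonstandard = TRUE`, with a warning).
#' @param allow_nonstandard Permit level counts outside the standard set.
#' @return Integer vector of levels in `1..n_levels`.
#' @export
quantize_uniform <- function(values, n_levels, allow_nonstandard = FALSE) {
  n_levels <- as.integer(n_levels)
  if (!(n_levels %in% ALLOWED_LEVELS)) {
    if (!allow_nonstandard)
      stop("configuration error: n_levels must be one of ",
           paste(ALLOWED_LEVELS, collapse = ", "), call. = FALSE)
    warning("nonstandard number of gray levels: ", n_levels)
  }
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("values must be normalized to [0, 1] before quantization", call. = FALSE)
  pmin(as.integer(floor(values * n_levels)) + 1L, n_levels)
}

#' Intensity scaling range over a set of masks
#'
#' Minimum and maximum intensity over the union of the given masks of one
#' volume; used as the per-volume normalization range so that every tissue
#' of a volume is quantized on a common scale.
#'
#' @param volume 3D numeric array.
#' @param masks List of logical arrays.
#' @return Numeric `c(lo, hi)`.
#' @export
intensity_range <- function(volume, masks) {
  u <- Reduce(`|`, masks)
  if (!any(u)) stop("empty-region error: mask union selects no voxels", call. = FALSE)
  range(volume[u])
}

#' Quantize a masked region of a volume
#'
#' Normalizes the in-mask intensities with [normalize_intensities()] and
#' quantizes them with [quantize_uniform()], returning the levels embedded
#' in the volume grid (NA outside the mask) so co-occurrence offsets can
#' be evaluated spatially.
#'
#' @param volume 3D numeric array.
#' @param mask 3D logical array.
#' @param range Numeric `c(lo, hi)` scaling range.
#' @param n_levels Number of gray levels.
#' @param allow_nonstandard Passed to [quantize_uniform()].
#' @return Object of class `quantized_region`: `levels` (3D integer array,
#'   NA outside mask), `n_levels`, `source_range`, `n_voxels`.
#' @export
quantize_region <- function(volume, mask, range, n_levels,
                            allow_nonstandard = FALSE) {
  region <- extract_region(volume, mask)
  norm <- normalize_intensities(region$values, range[1], range[2])
  lev <- quantize_uniform(norm, n_levels, allow_nonstandard)
  arr <- array(NA_integer_, region$dim)
  arr[mask] <- lev
  structure(list(levels = arr, n_levels = as.integer(n_levels),
                 source_range = c(range[1], range[2]),
                 n_voxels = length(lev)),
            class = "quantized_region")
}
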