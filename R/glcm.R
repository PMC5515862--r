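GLCM_ORIENTATIONS <- c(0L, 45L, 90L, 135L)

#' In-plane offset for a GLCM orientation
#'
#' Distance-1 displacement in (row, col) voxel indices: 0 deg -> (0, +1),
#' 45 deg -> (-1, +1), 90 deg -> (-1, 0), 135 deg -> (-1, -1).
#'
#' @param theta Orientation in degrees (0, 45, 90, 135).
#' @return Integer `c(drow, dcol)`.
#' @export
glcm_offset <- function(theta) {
  switch(as.character(theta),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("orientation must be one of 0, 45, 90, 135 degrees", call. = FALSE))
}

glcm_counts_nd <- function(levels, theta, n_levels) {
  off <- glcm_offset(theta)
  d <- dim(levels)
  r0 <- max(1L, 1L - off[1]); r1 <- min(d[1], d[1] - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(d[2], d[2] - off[2])
  if (r0 > r1 || c0 > c1) return(matrix(0L, n_levels, n_levels))
  rs <- seq.int(r0, r1)
  cs <- seq.int(c0, c1)
  if (length(d) == 2) {
    a <- levels[rs, cs, drop = FALSE]
    b <- levels[rs + off[1], cs + off[2], drop = FALSE]
  } else {
    a <- levels[rs, cs, , drop = FALSE]
    b <- levels[rs + off[1], cs + off[2], , drop = FALSE]
  }
  ok <- !is.na(a) & !is.na(b)
  m <- matrix(tabulate(a[ok] + (b[ok] - 1L) * n_levels, n_levels * n_levels),
              n_levels, n_levels)
  m + t(m)
}

#' Symmetric co-occurrence counts for one slice
#'
#' Counts level pairs at distance 1 in orientation `theta` over one axial
#' slice; both endpoints of a pair must lie inside the mask (levels are NA
#' outside), so no out-of-mask neighbor ever contributes. Accumulation is
#' symmetric: each pair increments both `(i, j)` and `(j, i)`.
#'
#' @param levels_slice 2D integer matrix of levels, NA outside the mask.
#' @param theta Orientation in degrees.
#' @param n_levels Number of gray levels N.
#' @return N x N integer count matrix (zero matrix if the slice has no
#'   valid pair).
#' @export
slice_glcm_counts <- function(levels_slice, theta, n_levels) {
  stopifnot(is.matrix(levels_slice))
  glcm_counts_nd(levels_slice, theta, as.integer(n_levels))
}

#' Global GLCM of a quantized region for one orientation
#'
#' Sums the per-slice co-occurrence counts over all axial slices of the
#' region and normalizes the total to a joint probability distribution.
#' An orientation with no valid pair is flagged empty (`total_pairs = 0`,
#' `P` all zero).
#'
#' @param region A `quantized_region` (or a 3D/2D integer level array with
#'   NA outside the mask, in which case `n_levels` must be given).
#' @param theta Orientation in degrees.
#' @param n_levels Number of gray levels (taken from `region` if it is a
#'   `quantized_region`).
#' @return Object of class `glcm`: `P` (N x N), `theta`, `d` (= 1),
#'   `total_pairs`.
#' @export
global_glcm <- function(region, theta, n_levels = NULL) {
  if (inherits(region, "quantized_region")) {
    levels <- region$levels
    n_levels <- region$n_levels
  } else {
    levels <- region
    if (is.null(n_levels)) stop("n_levels required for a bare level array",
                                call. = FALSE)
    n_levels <- as.integer(n_levels)
  }
  counts <- glcm_counts_nd(levels, theta, n_levels)
  total <- sum(counts)
  P <- if (total > 0) counts / total else matrix(0, n_levels, n_levels)
  structure(list(P = P, theta = as.integer(theta), d = 1L,
                 total_pairs = total),
            class = "glcm")
}

#' @rdname glcm_descriptors
#' @export
glcm_energy <- function(P) sum(P^2)

#' @rdname glcm_descriptors
#' @export
glcm_entropy <- function(P) {
  p <- P[P > 0]
  -sum(p * log2(p))
}

#' @rdname glcm_descriptors
#' @export
glcm_contrast <- function(P) {
  sum((row(P) - col(P))^2 * P)
}

#' @rdname glcm_descriptors
#' @export
glcm_homogeneity <- function(P) {
  sum(P / (1 + (row(P) - col(P))^2))
}

#' @rdname glcm_descriptors
#' @export
glcm_variance <- function(P) {
  px <- rowSums(P)
  mu <- sum(seq_along(px) * px)
  sum((row(P) - mu)^2 * P)
}

#' Haralick descriptors of a normalized GLCM
#'
#' Six second-order texture statistics of an N x N joint probability
#' matrix P with entries `P(i, j)` over gray levels `i, j = 1..N`:
#'
#' * energy: `sum P(i,j)^2` (uniformity; 1 for a single occupied cell);
#' * entropy: `-sum P log2 P` in bits, with `0 log 0 = 0` (randomness);
#' * contrast: `sum (i - j)^2 P(i,j)` (local intensity variation);
#' * homogeneity: `sum P(i,j) / (1 + (i - j)^2)` (inverse difference
#'   moment; 1 iff all mass is diagonal);
#' * GLCM variance (sum of squares): `sum (i - mu)^2 P(i,j)` with `mu`
#'   the mean of the row marginal (equal to the column marginal for the
#'   symmetric GLCMs built here);
#' * correlation: `(sum i j P(i,j) - mu_x mu_y) / (sigma_x sigma_y)`,
#'   returned as NA (undefined) when either marginal variance is zero.
#'
#' @param P Normalized, symmetric N x N GLCM.
#' @return A scalar; `glcm_correlation` returns `NA_real_` when undefined.
#' @name glcm_descriptors
#' @export
glcm_correlation <- function(P) {
  px <- rowSums(P)
  py <- colSums(P)
  i <- seq_along(px)
  mux <- sum(i * px)
  muy <- sum(i * py)
  sx2 <- sum((i - mux)^2 * px)
  sy2 <- sum((i - muy)^2 * py)
  if (sx2 <= 0 || sy2 <= 0) return(NA_real_)
  (sum(row(P) * col(P) * P) - mux * muy) / sqrt(sx2 * sy2)
}

#' Orientation-averaged texture descriptor vector
#'
#' Builds the four global GLCMs (0, 45, 90, 135 degrees, distance 1) of a
#' quantized region and averages each descriptor arithmetically over the
#' nonempty orientations, giving approximate rotation invariance. Empty
#' orientations (no valid voxel pair) are excluded from the average rather
#' than counted as zero; correlation is averaged only over orientations
#' where it is defined.
#'
#' @param region A `quantized_region`.
#' @return One-row data.frame: `contrast`, `glcm_variance`, `entropy`,
#'   `correlation`, `homogeneity`, `energy`, `orientations_used`,
#'   `total_pairs`, `correlation_defined`.
#' @export
texture_vector <- function(region) {
  stopifnot(inherits(region, "quantized_region"))
  glcms <- lapply(GLCM_ORIENTATIONS, function(th) global_glcm(region, th))
  nonempty <- vapply(glcms, function(g) g$total_pairs > 0, logical(1))
  if (!any(nonempty))
    stop("texture-undefined error: no valid voxel pair in any orientation",
         call. = FALSE)
  glcms <- glcms[nonempty]
  per <- vapply(glcms, function(g) c(
    contrast = glcm_contrast(g$P),
    glcm_variance = glcm_variance(g$P),
    entropy = glcm_entropy(g$P),
    correlation = glcm_correlation(g$P),
    homogeneity = glcm_homogeneity(g$P),
    energy = glcm_energy(g$P)
  ), numeric(6))
  corr <- per["correlation", ]
  corr_defined <- any(!is.na(corr))
  data.frame(
    contrast = mean(per["contrast", ]),
    glcm_variance = mean(per["glcm_variance", ]),
    entropy = mean(per["entropy", ]),
    correlation = if (corr_defined) mean(corr, na.rm = TRUE) else NA_real_,
    homogeneity = mean(per["homogeneity", ]),
    energy = mean(per["energy", ]),
    orientations_used = sum(nonempty),
    total_pairs = sum(vapply(glcms, `[[`, numeric(1), "total_pairs")),
    correlation_defined = corr_defined
  )
}
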