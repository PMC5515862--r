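#' Row-normalized Gaussian smoothing matrix
#'
#' Builds the n x n matrix that applies a truncated (3 sd) discrete Gaussian
#' kernel along one axis, with edge renormalization so every output is a
#' convex combination of inputs (no intensity drift at boundaries).
#'
#' @param n Axis length in voxels.
#' @param sd Kernel standard deviation in voxels; values below 1e-8 give the
#'   identity.
#' @return An n x n smoothing matrix with rows summing to 1.
#' @keywords internal
gaussian_smooth_matrix <- function(n, sd) {
  stopifnot(n >= 1, sd >= 0)
  if (sd < 1e-8) return(diag(n))
  half <- max(1L, as.integer(ceiling(3 * sd)))
  idx <- seq_len(n)
  D <- outer(idx, idx, "-")
  S <- exp(-(D^2) / (2 * sd^2))
  S[abs(D) > half] <- 0
  S / rowSums(S)
}

#' In-plane Gaussian smoothing of a 3D volume
#'
#' Smooths each axial slice (the last array axis indexes slices) with a
#' separable 2D Gaussian kernel. Through-plane smoothing is deliberately
#' absent: co-occurrence statistics are computed per slice, so only in-plane
#' spatial correlation matters.
#'
#' @param vol 3D numeric array.
#' @param sd Kernel standard deviation in voxels.
#' @return Smoothed array of the same dimension.
#' @export
smooth_volume_inplane <- function(vol, sd) {
  d <- dim(vol)
  stopifnot(length(d) == 3)
  if (sd < 1e-8) return(vol)
  Sr <- gaussian_smooth_matrix(d[1], sd)
  Sc <- gaussian_smooth_matrix(d[2], sd)
  m <- Sr %*% matrix(vol, d[1], d[2] * d[3])
  vol <- array(m, d)
  v2 <- aperm(vol, c(2L, 1L, 3L))
  m2 <- Sc %*% matrix(v2, d[2], d[1] * d[3])
  aperm(array(m2, c(d[2], d[1], d[3])), c(2L, 1L, 3L))
}

# canonical tissue order used throughout; also the overlap-resolution
# priority in reverse (stroke wins, NAWM loses)
TISSUES <- c("NAWM", "DGM", "WMH", "CSF", "stroke")
MASK_PRIORITY <- c("stroke", "WMH", "DGM", "CSF", "NAWM")

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.12g", x))
}
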