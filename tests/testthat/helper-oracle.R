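# Independent brute-force oracles for co-occurrence statistics.
# Deliberately naive (voxel-by-voxel loops, direct formula evaluation) and
# kept free of any package internals beyond the orientation convention.

oracle_offset <- function(theta) {
  switch(as.character(theta),
         "0" = c(0L, 1L), "45" = c(-1L, 1L),
         "90" = c(-1L, 0L), "135" = c(-1L, -1L))
}

oracle_glcm_counts <- function(levels, theta, n_levels) {
  if (length(dim(levels)) == 2) dim(levels) <- c(dim(levels), 1L)
  off <- oracle_offset(theta)
  d <- dim(levels)
  cnt <- matrix(0L, n_levels, n_levels)
  for (s in seq_len(d[3])) for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    a <- levels[r, cc, s]
    if (is.na(a)) next
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
    b <- levels[r2, c2, s]
    if (is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1L
    cnt[b, a] <- cnt[b, a] + 1L
  }
  cnt
}

oracle_descriptors <- function(P) {
  N <- nrow(P)
  energy <- 0; entropy <- 0; contrast <- 0; homog <- 0
  px <- numeric(N); py <- numeric(N); eij <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    p <- P[i, j]
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log2(p)
    contrast <- contrast + (i - j)^2 * p
    homog <- homog + p / (1 + (i - j)^2)
    px[i] <- px[i] + p
    py[j] <- py[j] + p
    eij <- eij + i * j * p
  }
  mux <- sum(seq_len(N) * px); muy <- sum(seq_len(N) * py)
  sx2 <- sum((seq_len(N) - mux)^2 * px); sy2 <- sum((seq_len(N) - muy)^2 * py)
  variance <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) variance <- variance + (i - mux)^2 * P[i, j]
  corr <- if (sx2 > 0 && sy2 > 0) (eij - mux * muy) / sqrt(sx2 * sy2) else NA_real_
  c(contrast = contrast, glcm_variance = variance, entropy = entropy,
    correlation = corr, homogeneity = homog, energy = energy)
}

oracle_texture_vector <- function(levels, n_levels) {
  per <- list()
  total <- 0
  for (th in c(0, 45, 90, 135)) {
    cnt <- oracle_glcm_counts(levels, th, n_levels)
    if (sum(cnt) == 0) next
    per[[length(per) + 1]] <- oracle_descriptors(cnt / sum(cnt))
    total <- total + sum(cnt)
  }
  stopifnot(length(per) > 0)
  m <- do.call(rbind, per)
  out <- colMeans(m)
  out["correlation"] <- mean(m[, "correlation"], na.rm = TRUE)
  attr(out, "total_pairs") <- total
  out
}

# random masked level region: dims up to max_dim, random mask coverage
random_level_region <- function(max_dim = c(32, 32, 4), n_levels = 8,
                                p_mask = 0.7) {
  d <- c(sample(4:max_dim[1], 1), sample(4:max_dim[2], 1),
         sample(1:max_dim[3], 1))
  mask <- array(stats::runif(prod(d)) < p_mask, d)
  if (!any(mask)) mask[1] <- TRUE
  lv <- array(NA_integer_, d)
  lv[mask] <- sample.int(n_levels, sum(mask), replace = TRUE)
  lv
}

# 90 degree counter-clockwise in-plane rotation of a 3D array
rotate90_inplane <- function(vol) {
  d <- dim(vol)
  out <- aperm(vol, c(2L, 1L, 3L))
  out[rev(seq_len(d[2])), , , drop = FALSE]
}
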