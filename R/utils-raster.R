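# Low-level raster helpers: FFT cross-correlation, separable Gaussian blur
# with reflective padding, bilinear resampling, and circular-angle utilities.
# These are internal; all carry the package-wide coordinate convention
# (see protobos-package.R).

# Wrap angles into [0, 2*pi).
ang_norm <- function(a) {
  a <- a %% (2 * pi)
  a[a < 0] <- a[a < 0] + 2 * pi
  a
}

# Absolute circular difference between two angles, in [0, pi].
circ_diff <- function(a, b) {
  d <- abs(ang_norm(a) - ang_norm(b))
  pmin(d, 2 * pi - d)
}

# FFT-friendly padded size (highly composite, >= n).
good_fft_size <- function(n) stats::nextn(n, c(2, 3, 5))

# Cross-correlation of raster A with kernel K (no kernel flip):
#   out[p] = sum_u K[u] * A[p + u],
# where u runs over kernel cells as (row, col) offsets relative to the kernel
# center (default: the middle cell), and A is taken as zero outside its
# support.  Output has the same shape as A.  Implements the correlation
# operator used for all receptive-field filtering in the model.
xcorr2 <- function(A, K, center = NULL) {
  stopifnot(is.matrix(A), is.matrix(K))
  na <- dim(A); nk <- dim(K)
  if (is.null(center)) center <- (nk + 1L) %/% 2L
  p1 <- good_fft_size(na[1] + nk[1] - 1L)
  p2 <- good_fft_size(na[2] + nk[2] - 1L)
  Ap <- matrix(0, p1, p2); Ap[seq_len(na[1]), seq_len(na[2])] <- A
  Kp <- matrix(0, p1, p2); Kp[seq_len(nk[1]), seq_len(nk[2])] <- K
  C <- Re(stats::fft(stats::fft(Ap) * Conj(stats::fft(Kp)), inverse = TRUE)) / (p1 * p2)
  ir <- ((seq_len(na[1]) - center[1]) %% p1) + 1L
  ic <- ((seq_len(na[2]) - center[2]) %% p2) + 1L
  C[ir, ic, drop = FALSE]
}

# Plan-based variant used by the recurrent core: kernel spectra are
# precomputed once per pyramid level, image spectra are computed once per
# map, and sums over channels happen in the frequency domain so a single
# inverse transform serves a whole orientation sum.
xcorr_plan <- function(img_dim, kernel_dim, center = NULL) {
  if (is.null(center)) center <- (kernel_dim + 1L) %/% 2L
  p1 <- good_fft_size(img_dim[1] + kernel_dim[1] - 1L)
  p2 <- good_fft_size(img_dim[2] + kernel_dim[2] - 1L)
  ir <- ((seq_len(img_dim[1]) - center[1]) %% p1) + 1L
  ic <- ((seq_len(img_dim[2]) - center[2]) %% p2) + 1L
  list(p = c(p1, p2), img_dim = img_dim, kernel_dim = kernel_dim,
       center = center, ir = ir, ic = ic)
}

plan_fft_kernel <- function(plan, K) {
  Kp <- matrix(0, plan$p[1], plan$p[2])
  Kp[seq_len(nrow(K)), seq_len(ncol(K))] <- K
  Conj(stats::fft(Kp))
}

plan_fft_image <- function(plan, A) {
  Ap <- matrix(0, plan$p[1], plan$p[2])
  Ap[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  stats::fft(Ap)
}

# Inverse transform of an accumulated frequency-domain product, cropped back
# to image coordinates.
plan_ifft <- function(plan, FX) {
  C <- Re(stats::fft(FX, inverse = TRUE)) / prod(plan$p)
  C[plan$ir, plan$ic, drop = FALSE]
}

# Reflect (mirror) pad indices for 1-d filtering.
reflect_idx <- function(n, pad) {
  idx <- seq.int(1L - pad, n + pad)
  idx[idx < 1L] <- 2L - idx[idx < 1L]
  idx[idx > n] <- 2L * n - idx[idx > n]
  # repeated reflection for pads larger than n
  while (any(idx < 1L | idx > n)) {
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
  }
  idx
}

# Separable Gaussian blur with reflective boundary handling.
gaussian_blur <- function(A, sigma) {
  if (sigma <= 0) return(A)
  rad <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq.int(-rad, rad))^2 / (2 * sigma^2))
  g <- g / sum(g)
  n <- nrow(A); m <- ncol(A)
  Ar <- A[reflect_idx(n, rad), , drop = FALSE]
  A1 <- apply(Ar, 2, function(col) as.numeric(stats::filter(col, g, sides = 2)))
  A1 <- A1[(rad + 1L):(rad + n), , drop = FALSE]
  Ac <- A1[, reflect_idx(m, rad), drop = FALSE]
  A2 <- t(apply(Ac, 1, function(row) as.numeric(stats::filter(row, g, sides = 2))))
  A2[, (rad + 1L):(rad + m), drop = FALSE]
}

# Bilinear resampling to an exact target shape, with pixel-center alignment.
# Used for cross-scale upsampling; constant rasters are preserved exactly.
bilinear_resize <- function(A, out_dim) {
  n <- nrow(A); m <- ncol(A)
  nr <- out_dim[1]; nc <- out_dim[2]
  if (nr == n && nc == m) return(A)
  src_r <- pmin(pmax((seq_len(nr) - 0.5) * n / nr - 0.5, 0), n - 1)
  src_c <- pmin(pmax((seq_len(nc) - 0.5) * m / nc - 0.5, 0), m - 1)
  r0 <- pmin(floor(src_r), n - 1); r1 <- pmin(r0 + 1, n - 1)
  c0 <- pmin(floor(src_c), m - 1); c1 <- pmin(c0 + 1, m - 1)
  fr <- src_r - r0; fc <- src_c - c0
  A00 <- A[r0 + 1, c0 + 1, drop = FALSE]
  A10 <- A[r1 + 1, c0 + 1, drop = FALSE]
  A01 <- A[r0 + 1, c1 + 1, drop = FALSE]
  A11 <- A[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  A00 * (1 - wr) * (1 - wc) + A10 * wr * (1 - wc) +
    A01 * (1 - wr) * wc + A11 * wr * wc
}

# Direction angles of the 16 directed border ownership channels.  Channel d
# (1..16) has border orientation theta_d = (d - 1) * pi / 8; channels d and
# d + 8 share the undirected orientation (d - 1) %% 8 but prefer opposite
# figure sides.
directed_angles <- function(n_orientations = 8L) {
  (seq_len(2L * n_orientations) - 1L) * pi / n_orientations
}

# Index of the opponent channel (theta + pi) in the directed indexing.
opponent_index <- function(d, n_orientations = 8L) {
  ((d - 1L + n_orientations) %% (2L * n_orientations)) + 1L
}

# Undirected orientation index (1..n_orientations) feeding directed channel d.
undirected_index <- function(d, n_orientations = 8L) {
  ((d - 1L) %% n_orientations) + 1L
}
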