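#' Annular grouping-cell kernel
#'
#' Spatial receptive-field profile of a grouping (G) cell lobe for directed
#' border orientation `theta`.  In polar coordinates `(r, phi)` around the
#' kernel center,
#'
#'   `v(r, phi) = exp[(r - R0) * cos(phi - theta + pi/2)] / (2 * pi * I0(r - R0))`
#'
#' where `I0` is the modified Bessel function of the first kind (order 0).
#' At each radius the angular profile is a von Mises density with
#' concentration `r - R0`: on the annulus `r = R0` the kernel is isotropic
#' with value `1 / (2 * pi)`, and away from the annulus it concentrates into
#' a lobe pointing in direction `theta - pi/2` (the `pi/2` offset aligns the
#' lobe with the figure side of the edge cells that drive the G cell).  The
#' kernel is evaluated on a truncated square support and divided by its
#' maximum, so the returned raster peaks at 1; `v` for `theta` and
#' `theta + pi` are related by a 180-degree rotation about the center.
#'
#' @param theta directed border orientation (radians).
#' @param R0 annulus radius in pixels (> 0); the model default is 2.
#' @param support_radius truncation radius in pixels (> R0).  Cells beyond
#'   this radius, and cells whose pre-normalization value falls below
#'   `trunc_tol` times the support maximum, are zeroed.
#' @param normalize divide by the maximum over all positions (default TRUE).
#' @param trunc_tol relative truncation tolerance.
#' @return A `(2 * support_radius + 1)` square matrix; the center cell is the
#'   kernel origin.
#' @export
grouping_kernel <- function(theta, R0 = 2, support_radius = 16,
                            normalize = TRUE, trunc_tol = 1e-4) {
  if (R0 <= 0) abort("`R0` must be positive.")
  if (support_radius <= R0) abort("`support_radius` must exceed `R0`.")
  n <- 2L * as.integer(ceiling(support_radius)) + 1L
  c0 <- (n + 1L) %/% 2L
  X <- matrix(seq_len(n) - c0, n, n, byrow = TRUE)
  Y <- -matrix(seq_len(n) - c0, n, n)
  r <- sqrt(X^2 + Y^2)
  phi <- atan2(Y, X)
  kappa <- r - R0
  # exp(kappa * cos) / (2 pi I0(kappa)), computed with exponent scaling so
  # large radii do not overflow: I0 is even in kappa.
  logv <- kappa * cos(phi - theta + pi / 2) - abs(kappa) -
    log(2 * pi * besselI(abs(kappa), 0, expon.scaled = TRUE))
  v <- exp(logv)
  # the angle is degenerate at the origin: use the angular average of the
  # von Mises profile there (1 / (2 pi)), which keeps the exact point
  # reflection between v_theta and v_theta+pi
  v[r == 0] <- 1 / (2 * pi)
  v[r > support_radius] <- 0
  mx <- max(v)
  v[v < trunc_tol * mx] <- 0
  if (normalize && mx > 0) v <- v / mx
  v
}

# Bank of grouping kernels for all directed orientations at one pyramid
# level, with precomputed frequency-domain representations for the
# correlation plan of that level.
kernel_bank_level <- function(img_dim, R0 = 2, n_orientations = 8L,
                              support_radius = NULL) {
  if (is.null(support_radius))
    support_radius <- min(8 * R0, ceiling(sqrt(sum(img_dim^2))))
  support_radius <- max(support_radius, R0 + 1)
  angles <- directed_angles(n_orientations)
  kernels <- lapply(angles, grouping_kernel, R0 = R0,
                    support_radius = support_radius)
  kd <- dim(kernels[[1]])
  plan <- xcorr_plan(img_dim, kd)
  fk <- lapply(kernels, function(K) plan_fft_kernel(plan, K))
  list(kernels = kernels, fk = fk, plan = plan, angles = angles,
       R0 = R0, support_radius = support_radius)
}

#' Grouping kernel bank across pyramid levels
#'
#' Builds, for every pyramid level, the 2 x `n_orientations` directed
#' grouping kernels together with precomputed FFT spectra sized for that
#' level.  The same `R0` (in pixels) is used at every level; because level
#' `k` is downsampled by `factor^k`, the effective grouping radius grows
#' with the level, which is what gives the model approximate scale
#' invariance.
#'
#' @param base_dim shape `c(nr, nc)` of the level-0 raster.
#' @param n_levels number of pyramid levels.
#' @param factor pyramid downsampling step.
#' @param R0 annulus radius in pixels.
#' @param n_orientations number of undirected orientations.
#' @param support_radius kernel truncation radius in pixels; default is each
#'   level's image diagonal.
#' @return List of class `kernel_bank`: per-level kernel sets.
#' @export
kernel_bank <- function(base_dim, n_levels = 5L, factor = 2, R0 = 2,
                        n_orientations = 8L, support_radius = NULL) {
  levels <- lapply(seq_len(n_levels) - 1L, function(k) {
    kernel_bank_level(level_shape(base_dim, k, factor), R0 = R0,
                      n_orientations = n_orientations,
                      support_radius = support_radius)
  })
  structure(list(levels = levels, base_dim = base_dim, factor = factor,
                 n_levels = n_levels, R0 = R0,
                 n_orientations = n_orientations),
            class = "kernel_bank")
}
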