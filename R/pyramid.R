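#' Multiscale image pyramid
#'
#' Builds the image pyramid over which all grouping computations run: level 0
#' is the input resolution and each subsequent level is an anti-alias blurred
#' and decimated copy of the previous one (Gaussian blur with
#' `sigma = factor / 2`, reflective padding, then decimation by `factor`).
#' Five levels with factor 2 span five octaves; factor `sqrt(2)` with ten
#' levels gives a half-octave pyramid.
#'
#' @param raster numeric matrix.
#' @param n_levels number of pyramid levels (>= 1).
#' @param factor downsampling step between levels.
#' @return List of class `pyramid` with elements `levels` (list of matrices),
#'   `factor`, `n_levels`.
#' @export
build_pyramid <- function(raster, n_levels = 5L, factor = 2) {
  stopifnot(is.matrix(raster), n_levels >= 1)
  min_size <- ceiling(factor^(n_levels - 1))
  if (nrow(raster) < min_size || ncol(raster) < min_size)
    abort(sprintf(
      "raster (%d x %d) too small for %d levels at factor %g: need at least %d x %d",
      nrow(raster), ncol(raster), n_levels, factor, min_size, min_size))
  levels <- vector("list", n_levels)
  levels[[1]] <- raster
  for (k in seq_len(n_levels - 1L)) {
    prev <- levels[[k]]
    target <- c(ceiling(nrow(raster) / factor^k), ceiling(ncol(raster) / factor^k))
    blurred <- gaussian_blur(prev, sigma = factor / 2)
    if (factor == round(factor)) {
      levels[[k + 1]] <- blurred[seq(1, nrow(prev), by = factor),
                                 seq(1, ncol(prev), by = factor), drop = FALSE]
    } else {
      levels[[k + 1]] <- bilinear_resize(blurred, target)
    }
  }
  structure(list(levels = levels, factor = factor, n_levels = n_levels),
            class = "pyramid")
}

#' Shape of a pyramid level
#'
#' Level `k` (0-based) of a pyramid over an `nr x nc` raster has shape
#' `ceiling(nr / factor^k) x ceiling(nc / factor^k)`.
#'
#' @param base_dim integer vector `c(nr, nc)` of the level-0 raster.
#' @param k 0-based level index.
#' @param factor downsampling step.
#' @return Integer vector `c(rows, cols)`.
#' @export
level_shape <- function(base_dim, k, factor = 2) {
  as.integer(ceiling(base_dim / factor^k))
}

#' Upsample a raster from a coarse pyramid level to a finer one
#'
#' Bilinear interpolation to the exact shape of the target level; used when
#' coarse-scale grouping activity is combined additively with finer scales.
#' `j = k` is the identity.
#'
#' @param raster matrix at level `j`.
#' @param j source level (0-based).
#' @param k target level (0-based), with `j >= k`.
#' @param base_dim shape `c(nr, nc)` of level 0.
#' @param factor pyramid downsampling step.
#' @return Matrix with the exact shape of level `k`.
#' @export
upsample_to <- function(raster, j, k, base_dim, factor = 2) {
  if (j < k) abort("`j` must be >= `k`: upsampling goes from coarse to fine.")
  if (j == k) return(raster)
  bilinear_resize(raster, level_shape(base_dim, k, factor))
}
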