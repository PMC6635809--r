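#' Decompose an image into luminance and color-opponent channels
#'
#' Converts an RGB (or grayscale) image into the three feature channels the
#' model operates on: intensity, red-green opponency and blue-yellow
#' opponency, following the broadly tuned opponency construction of classic
#' saliency models.  With `r`, `g`, `b` the color planes, intensity is the
#' plane mean, `rg = r - g`, and `by = b - (r + g) / 2`.  Grayscale input
#' yields zero color channels.
#'
#' @param image numeric matrix (grayscale) or row x col x 3 array (RGB),
#'   values in `[0, 1]`; an [annotated_image()] is also accepted.
#' @return A list of class `channel_set` with matrices `intensity`, `rg`,
#'   `by`.
#' @export
to_channels <- function(image) {
  if (inherits(image, "annotated_image")) image <- image$pixels
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    abort("image values must lie in [0, 1].")
  if (is.matrix(image)) {
    out <- list(intensity = image,
                rg = matrix(0, nrow(image), ncol(image)),
                by = matrix(0, nrow(image), ncol(image)))
  } else if (length(dim(image)) == 3 && dim(image)[3] == 3) {
    r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
    out <- list(intensity = (r + g + b) / 3,
                rg = r - g,
                by = b - (r + g) / 2)
  } else {
    abort("image must have 1 or 3 planes.")
  }
  structure(out, class = "channel_set")
}

#' Oriented odd-symmetric (Gabor) filter bank
#'
#' One odd-symmetric Gabor per undirected orientation.  The filter for
#' border orientation `theta` oscillates along the border normal
#' (`theta + pi/2`) and is elongated along the border tangent.  By the sign
#' convention used throughout the package, a positive response means the
#' lighter side of the edge lies in direction `theta + pi/2`.
#'
#' @param n_orientations number of undirected orientation bins on `[0, pi)`.
#' @param wavelength carrier wavelength in pixels.
#' @param aspect spatial aspect ratio `gamma` (< 1 elongates the envelope
#'   along the border tangent).
#' @param sigma Gaussian envelope s.d. in pixels; default `0.4 * wavelength`.
#' @return List of square odd-symmetric filter matrices (zero DC response),
#'   one per orientation `theta_i = (i - 1) * pi / n_orientations`.
#' @export
gabor_bank <- function(n_orientations = 8L, wavelength = 8, aspect = 0.5,
                       sigma = 0.4 * wavelength) {
  rad <- ceiling(3 * sigma)
  xs <- seq.int(-rad, rad)
  X <- matrix(xs, 2 * rad + 1, 2 * rad + 1, byrow = TRUE)   # x: column offset
  Y <- -matrix(xs, 2 * rad + 1, 2 * rad + 1)                # y: up is positive
  lapply(seq_len(n_orientations), function(i) {
    th <- (i - 1) * pi / n_orientations
    nrm <- X * cos(th + pi / 2) + Y * sin(th + pi / 2)      # along border normal
    tng <- X * cos(th) + Y * sin(th)                        # along border tangent
    k <- exp(-(nrm^2 + aspect^2 * tng^2) / (2 * sigma^2)) * sin(2 * pi * nrm / wavelength)
    k / sqrt(sum(k^2))
  })
}

#' Oriented, contrast-polarity-split edge responses (S cells)
#'
#' Filters a channel raster with the odd-symmetric oriented bank, keeps only
#' the maximal-magnitude orientation at each pixel (winner orientation; ties
#' broken toward the lowest orientation index), and splits the signed winner
#' response into two non-negative contrast-polarity maps: `L` (lighter side
#' toward `theta + pi/2`) and `D` (lighter side toward `theta - pi/2`).  For
#' color-opponent channels the two "polarities" are the two opponent signs.
#'
#' @param channel numeric matrix (one feature channel).
#' @param bank filter bank from [gabor_bank()]; built on the fly if `NULL`.
#' @param n_orientations number of undirected orientations (used when `bank`
#'   is `NULL`).
#' @return An array `row x col x n_orientations x 2` (polarity `L` = slice 1,
#'   `D` = slice 2), non-negative, with at most one nonzero orientation bin
#'   per pixel.
#' @export
oriented_edges <- function(channel, bank = NULL, n_orientations = 8L) {
  if (anyNA(channel) || any(!is.finite(channel))) abort("channel must be finite.")
  if (is.null(bank)) bank <- gabor_bank(n_orientations)
  signed <- oriented_responses(channel, bank)
  split_polarity(winner_orientation(signed))
}

# Signed responses of the oriented bank: row x col x n_orientations.
# The channel is reflect-padded by the filter radius so that a uniform
# raster gives exactly zero response up to the image border, and contrast
# inversion negates the responses exactly everywhere.
oriented_responses <- function(channel, bank) {
  n_or <- length(bank)
  rad <- (nrow(bank[[1]]) - 1L) %/% 2L
  padded <- channel[reflect_idx(nrow(channel), rad),
                    reflect_idx(ncol(channel), rad), drop = FALSE]
  out <- array(0, c(nrow(channel), ncol(channel), n_or))
  rows <- (rad + 1L):(rad + nrow(channel))
  cols <- (rad + 1L):(rad + ncol(channel))
  for (i in seq_len(n_or)) {
    out[, , i] <- xcorr2(padded, bank[[i]])[rows, cols]
  }
  out
}

# Keep only the maximal-|response| orientation per pixel; all other
# orientation bins are zeroed.  Ties are detected with a small relative
# tolerance (so that symmetric stimuli break ties identically despite
# floating-point filtering noise) and resolved toward the lowest
# orientation index.
winner_orientation <- function(signed, tie_tol = 1e-9) {
  n_or <- dim(signed)[3]
  absr <- abs(signed)
  mx <- absr[, , 1]
  for (i in seq_len(n_or)[-1]) mx <- pmax(mx, absr[, , i])
  out <- array(0, dim(signed))
  assigned <- matrix(FALSE, dim(signed)[1], dim(signed)[2])
  thr <- mx * (1 - tie_tol)
  for (i in seq_len(n_or)) {
    sel <- !assigned & absr[, , i] >= thr & mx > 0
    if (any(sel)) {
      oi <- out[, , i]; si <- signed[, , i]
      oi[sel] <- si[sel]
      out[, , i] <- oi
      assigned <- assigned | sel
    }
  }
  out
}

# Split signed orientation responses into the two polarity maps.
split_polarity <- function(signed) {
  d <- dim(signed)
  out <- array(0, c(d[1], d[2], d[3], 2))
  out[, , , 1] <- pmax(signed, 0)
  out[, , , 2] <- pmax(-signed, 0)
  out
}
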