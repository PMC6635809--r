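# Decoding: polarity combination, population-vector readout, per-image BOS
# normalization, channel fusion, and scene-point readout.

#' Combine contrast polarities of B (or G) activity
#'
#' Produces the contrast-polarity-invariant responses: per directed channel,
#' `B_theta = B_theta,L + B_theta,D` (and `G = G_L + G_D` for grouping
#' maps).  The opponent difference `B_theta - B_theta+pi` of the combined
#' responses is the border ownership signal (BOS) at that orientation: its
#' sign gives the assigned side, its magnitude the confidence.
#'
#' @param b either a `row x col x channels x 2` array (one pyramid level of a
#'   B volume) or a `row x col x 2` grouping array.
#' @return An array with the polarity axis summed out.
#' @export
combine_polarity <- function(b) {
  nd <- length(dim(b))
  if (nd == 4) {
    b[, , , 1] + b[, , , 2]
  } else if (nd == 3) {
    b[, , 1] + b[, , 2]
  } else {
    abort("`b` must be a 3- or 4-dimensional activity array.")
  }
}

#' Population-vector readout of the figure-ground field
#'
#' Sums the combined B-cell activity across directed channels as planar
#' vectors: channel `d` with border orientation `theta_d` contributes its
#' activity along the unit vector pointing to that channel's preferred
#' figure side, `theta_d + pi/2`.  The magnitude of the resultant at each
#' pixel is the BOS (used as contour strength) and its direction is a
#' continuous figure-ground orientation label.
#'
#' @param b_combined `row x col x 16` array of polarity-combined B activity
#'   at the finest pyramid level.
#' @return List of class `fg_field` with matrices `magnitude`, `angle`
#'   (radians in `[0, 2*pi)`), `vx`, `vy` and flag `normalized = FALSE`.
#' @export
population_vector <- function(b_combined) {
  nd <- dim(b_combined)[3]
  n_or <- nd %/% 2L
  ang <- directed_angles(n_or) + pi / 2   # preferred figure side per channel
  vx <- matrix(0, dim(b_combined)[1], dim(b_combined)[2])
  vy <- vx
  for (d in seq_len(nd)) {
    vx <- vx + b_combined[, , d] * cos(ang[d])
    vy <- vy + b_combined[, , d] * sin(ang[d])
  }
  new_fg_field(vx, vy, normalized = FALSE)
}

new_fg_field <- function(vx, vy, normalized = FALSE) {
  structure(list(magnitude = sqrt(vx^2 + vy^2),
                 angle = ang_norm(atan2(vy, vx)),
                 vx = vx, vy = vy, normalized = normalized),
            class = "fg_field")
}

#' @export
print.fg_field <- function(x, ...) {
  cat(sprintf("<fg_field> %d x %d, max magnitude %.4g%s\n",
              nrow(x$magnitude), ncol(x$magnitude), max(x$magnitude),
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Fuse per-channel figure-ground fields
#'
#' Weighted vector sum of the intensity, red-green and blue-yellow fields;
#' the defaults weight luminance 80% and each color channel 10%.  Weights
#' that do not sum to 1 are renormalized with a warning.
#'
#' @param fields list of three `fg_field`s (intensity, rg, by), co-registered.
#' @param weights numeric weights, one per field.
#' @return A fused `fg_field`.
#' @export
fuse_channels <- function(fields, weights = c(0.8, 0.1, 0.1)) {
  stopifnot(length(fields) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) {
    warn("channel weights do not sum to 1; renormalizing.")
    weights <- weights / sum(weights)
  }
  vx <- Reduce(`+`, Map(function(f, w) w * f$vx, fields, weights))
  vy <- Reduce(`+`, Map(function(f, w) w * f$vy, fields, weights))
  new_fg_field(vx, vy, normalized = FALSE)
}

#' Per-image normalized, signed scene-point BOS
#'
#' Normalizes BOS magnitudes by their maximum across the image, so signed
#' values are bounded between -1 and 1, and signs each scene point by the
#' +/- 90-degree rule: positive when the predicted figure direction is
#' within 90 degrees of the ground-truth figure side, negative when it is
#' more than 90 degrees away (i.e. the model assigns the border to the wrong
#' side), zero at exactly 90 degrees or where the field vanishes.
#'
#' @param field an `fg_field`.
#' @param truth tibble with columns `row`, `col` and either `true_side` or
#'   `angle` (ground-truth figure direction at each scene point);
#'   [annotated_image()] scene points or boundary tables both work.
#' @param window_radius disc radius (pixels) over which the readout is taken
#'   around each scene point (a receptive-field-sized window; 0 reads a
#'   single pixel).  The signed BOS is the disc average of the per-pixel
#'   signed normalized values; the predicted angle is the direction of the
#'   disc-averaged BOS vector (a local population-vector readout, robust to
#'   isolated cancellation pixels).
#' @return A tibble: one row per scene point with columns carried over from
#'   `truth` plus `bos` (signed, in `[-1, 1]`) and `pred_angle` (decoded
#'   figure direction at the scene point).
#' @export
normalize_bos <- function(field, truth, window_radius = 2) {
  truth <- as_tibble(truth)
  side <- if ("true_side" %in% names(truth)) truth$true_side else truth$angle
  if (is.null(side)) abort("`truth` needs a `true_side` or `angle` column.")
  mx <- max(field$magnitude)
  if (mx == 0) {
    warn("figure-ground field is identically zero; normalized BOS set to 0.")
    truth$bos <- 0
    truth$pred_angle <- NA_real_
    return(truth)
  }
  ro <- lapply(seq_len(nrow(truth)), function(i) {
    window_readout(field, truth$row[i], truth$col[i], side[i],
                   window_radius, mx)
  })
  truth$bos <- vapply(ro, `[[`, numeric(1), "bos")
  truth$pred_angle <- vapply(ro, `[[`, numeric(1), "pred_angle")
  truth
}

# Disc-window readout at one scene point: `bos` is the mean of the
# per-pixel signed normalized BOS values (sign = agreement of each pixel's
# decoded direction with the scene point's true side); `pred_angle` is the
# direction of the disc-averaged BOS vector.
window_readout <- function(field, row, col, true_side, window_radius, mx) {
  nr <- nrow(field$magnitude); nc <- ncol(field$magnitude)
  if (row < 1 || row > nr || col < 1 || col > nc)
    abort(sprintf("scene point (%d, %d) lies outside the %d x %d image.",
                  row, col, nr, nc))
  r <- max(0, window_radius)
  acc <- 0; n <- 0L; svx <- 0; svy <- 0
  eps <- 1e-12 * mx
  for (rr in max(1, row - ceiling(r)):min(nr, row + ceiling(r))) {
    for (cc in max(1, col - ceiling(r)):min(nc, col + ceiling(r))) {
      if ((rr - row)^2 + (cc - col)^2 > r^2 + 1e-9) next
      m <- field$magnitude[rr, cc]
      s <- if (m <= eps) 0 else sign(cos(field$angle[rr, cc] - true_side))
      acc <- acc + s * m / mx
      svx <- svx + field$vx[rr, cc]; svy <- svy + field$vy[rr, cc]
      n <- n + 1L
    }
  }
  pred <- if (sqrt(svx^2 + svy^2) <= eps) NA_real_ else ang_norm(atan2(svy, svx))
  list(bos = acc / n, pred_angle = pred)
}

#' Single scene-point BOS readout
#'
#' Signed normalized BOS averaged over a disc around one location (default
#' radius 2 px).  Convenience wrapper around [normalize_bos()].
#'
#' @param field an `fg_field`.
#' @param location `c(row, col)` pixel coordinates.
#' @param true_side ground-truth figure direction (radians).
#' @param window_radius disc radius in pixels (0 = single pixel).
#' @return A scalar in `[-1, 1]`.
#' @export
scene_point_bos <- function(field, location, true_side, window_radius = 2) {
  out <- normalize_bos(
    field,
    tibble(row = location[1], col = location[2], true_side = true_side),
    window_radius = window_radius)
  out$bos[1]
}
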