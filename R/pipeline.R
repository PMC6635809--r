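#' Run the full figure-ground model on an image
#'
#' End-to-end pipeline: channel decomposition, oriented polarity-split edge
#' responses over a multiscale pyramid, the recurrent B/G loop, and the
#' population-vector decode, with the per-channel fields fused by weighted
#' vector summation.  Color channels that are identically zero (grayscale
#' input) are skipped and contribute zero fields.
#'
#' @param image an [annotated_image()], a numeric matrix, or a 3-plane RGB
#'   array with values in `[0, 1]`.
#' @param n_iterations recurrent iterations (one feedforward + one feedback
#'   pass each).
#' @param n_levels,factor pyramid geometry (five octave-spaced levels by
#'   default).
#' @param n_orientations undirected orientation bins.
#' @param R0 grouping-cell annulus radius in pixels.
#' @param support_radius grouping kernel truncation radius; default is each
#'   level's image diagonal.
#' @param channel_weights fusion weights for (intensity, rg, by).
#' @param convergence_tol optional early-stopping tolerance (see
#'   [run_recurrence()]).
#' @param keep_trace record per-iteration decoded fields?
#' @return List of class `fg_result`: `field` (fused `fg_field`),
#'   `channel_fields`, `recurrence` (per-channel `recurrence_result`s),
#'   `grouping_map` (polarity-combined G activity summed over scales at the
#'   finest resolution), `scene_bos` (tibble of signed normalized BOS at the
#'   image's scene points, when annotations are present), `config`.
#' @export
fg_run <- function(image, n_iterations = 10L, n_levels = 5L, factor = 2,
                   n_orientations = 8L, R0 = 2, support_radius = NULL,
                   channel_weights = c(0.8, 0.1, 0.1),
                   convergence_tol = NULL, keep_trace = TRUE) {
  annot <- if (inherits(image, "annotated_image")) image else annotated_image(image)
  ch <- to_channels(annot$pixels)
  base_dim <- dim(ch$intensity)
  bank <- kernel_bank(base_dim, n_levels = n_levels, factor = factor, R0 = R0,
                      n_orientations = n_orientations,
                      support_radius = support_radius)
  gbank <- gabor_bank(n_orientations)

  run_channel <- function(raster) {
    if (max(abs(raster)) == 0) return(NULL)
    S <- edge_volume(raster, n_levels = n_levels, factor = factor,
                     bank = gbank, n_orientations = n_orientations)
    run_recurrence(S, bank = bank, n_iterations = n_iterations,
                   convergence_tol = convergence_tol, keep_trace = keep_trace)
  }
  recs <- list(intensity = run_channel(ch$intensity),
               rg = run_channel(ch$rg),
               by = run_channel(ch$by))

  zero_field <- new_fg_field(matrix(0, base_dim[1], base_dim[2]),
                             matrix(0, base_dim[1], base_dim[2]))
  fields <- lapply(recs, function(r) {
    if (is.null(r)) zero_field else
      population_vector(combine_polarity(r$B$levels[[1]]))
  })
  fused <- fuse_channels(fields, channel_weights)

  # Grouping map: polarity-combined G activity summed over scales at the
  # finest resolution, channel-fused with the same weights.
  gmap <- matrix(0, base_dim[1], base_dim[2])
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r)) next
    gsum <- matrix(0, base_dim[1], base_dim[2])
    for (k in seq_along(r$G$levels)) {
      gsum <- gsum + upsample_to(combine_polarity(r$G$levels[[k]]),
                                 k - 1L, 0L, base_dim, factor)
    }
    gmap <- gmap + channel_weights[i] * gsum
  }

  scene_bos <- NULL
  if (!is.null(annot$scene_points) && nrow(annot$scene_points) > 0 &&
      max(fused$magnitude) > 0) {
    scene_bos <- normalize_bos(fused, annot$scene_points)
  }

  structure(
    list(field = fused, channel_fields = fields, recurrence = recs,
         grouping_map = gmap, scene_bos = scene_bos, image = annot,
         config = list(n_iterations = n_iterations, n_levels = n_levels,
                       factor = factor, n_orientations = n_orientations,
                       R0 = R0, support_radius = support_radius,
                       channel_weights = channel_weights,
                       convergence_tol = convergence_tol)),
    class = "fg_result")
}

#' @export
print.fg_result <- function(x, ...) {
  d <- dim(x$field$magnitude)
  cat(sprintf("<fg_result> %d x %d image, %d iterations, %d levels\n",
              d[1], d[2], x$config$n_iterations, x$config$n_levels))
  if (!is.null(x$scene_bos))
    cat(sprintf("  scene points: %d, sign consistency %.3f\n",
                nrow(x$scene_bos), mean(x$scene_bos$bos > 0)))
  invisible(x)
}

#' Iteration at which decoded boundary signs stabilize
#'
#' Scans the per-iteration trace of a model run and returns the earliest
#' iteration from which the sign of the decoded BOS (agreement with the
#' ground-truth figure side, +/- 90-degree rule) at every scene point equals
#' its final value.  With one feedforward + feedback pass per iteration and
#' the standard ~10 ms per-pass latency assumption, iteration `i` maps to
#' `10 * i` milliseconds after response onset.
#'
#' @param result an `fg_result` from [fg_run()] with `keep_trace = TRUE`,
#'   run on an annotated image with scene points; alternatively a
#'   `recurrence_result` plus explicit `truth`.
#' @param truth optional scene-point tibble (`row`, `col`,
#'   `true_side`/`angle`), required when `result` is a `recurrence_result`.
#' @param channel which traced channel to use for an `fg_result`.
#' @return List with `iteration` (stabilization iteration), `latency_ms`
#'   (`10 * iteration`) and `signs` (iterations x scene points sign matrix).
#' @export
bos_sign_stabilization <- function(result, truth = NULL, channel = "intensity") {
  if (inherits(result, "fg_result")) {
    rec <- result$recurrence[[channel]]
    if (is.null(truth)) truth <- result$image$scene_points
  } else rec <- result
  if (is.null(rec$fields)) abort("run the model with `keep_trace = TRUE`.")
  if (is.null(truth)) abort("scene-point ground truth is required.")
  truth <- as_tibble(truth)
  side <- if ("true_side" %in% names(truth)) truth$true_side else truth$angle
  signs <- t(vapply(rec$fields, function(f) {
    m <- f$magnitude[cbind(truth$row, truth$col)]
    a <- f$angle[cbind(truth$row, truth$col)]
    s <- sign(cos(a - side))
    s[m == 0] <- 0
    s
  }, numeric(nrow(truth))))
  n_it <- nrow(signs)
  final <- signs[n_it, ]
  stable_from <- n_it
  for (i in rev(seq_len(n_it))) {
    if (all(signs[i, ] == final)) stable_from <- i else break
  }
  list(iteration = stable_from, latency_ms = 10 * stable_from, signs = signs)
}

#' @rdname fg_run
#' @param x an `fg_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.fg_result <- function(x, ...) {
  if (is.null(x$scene_bos)) {
    f <- x$field
    idx <- which(f$magnitude > 0, arr.ind = TRUE)
    return(tibble(row = idx[, 1], col = idx[, 2],
                  magnitude = f$magnitude[idx] / max(f$magnitude),
                  angle = f$angle[idx]))
  }
  x$scene_bos
}

#' @rdname fg_run
#' @exportS3Method generics::glance
glance.fg_result <- function(x, ...) {
  rec <- x$recurrence$intensity
  tibble(
    n_iterations = x$config$n_iterations,
    n_iterations_run = if (is.null(rec)) NA_integer_ else rec$n_iterations_run,
    max_bos = max(x$field$magnitude),
    consistency = if (is.null(x$scene_bos)) NA_real_ else mean(x$scene_bos$bos > 0),
    fg_accuracy = if (is.null(x$scene_bos)) NA_real_ else {
      ok <- !is.na(x$scene_bos$pred_angle)
      side <- if ("true_side" %in% names(x$scene_bos)) x$scene_bos$true_side else x$scene_bos$angle
      mean(circ_diff(x$scene_bos$pred_angle[ok], side[ok]) < pi / 2)
    }
  )
}
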