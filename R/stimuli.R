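#' Annotated image container
#'
#' Bundles an intensity raster with optional geometric ground truth: a binary
#' boundary mask, per-boundary-pixel figure-side orientations, and a table of
#' scene points.  A *scene point* is a specific boundary location in a
#' specific image at which a border ownership signal is measured, for the
#' model or for a recorded neuron; scene points always lie on an object
#' boundary.
#'
#' @param pixels numeric matrix (grayscale) or row x col x 3 array (RGB) with
#'   values in `[0, 1]`.
#' @param boundary tibble with columns `row`, `col`, `angle` giving boundary
#'   pixel locations and the ground-truth figure-side direction (radians,
#'   pointing from the boundary toward the figure interior), or `NULL`.
#' @param scene_points tibble with columns `scene_point_id`, `row`, `col`,
#'   `true_side`, or `NULL`.
#'
#' @return An object of class `annotated_image` with elements `pixels`,
#'   `boundary`, `boundary_mask` and `scene_points`.
#' @export
annotated_image <- function(pixels, boundary = NULL, scene_points = NULL) {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3)))
    abort("`pixels` must be a matrix or a 3-plane array.")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    abort("`pixels` must be finite and bounded in [0, 1].")
  nr <- dim(pixels)[1]; nc <- dim(pixels)[2]
  mask <- matrix(FALSE, nr, nc)
  if (!is.null(boundary)) {
    boundary <- as_tibble(boundary)
    stopifnot(all(c("row", "col", "angle") %in% names(boundary)))
    boundary$angle <- ang_norm(boundary$angle)
    mask[cbind(boundary$row, boundary$col)] <- TRUE
  }
  if (!is.null(scene_points)) {
    scene_points <- as_tibble(scene_points)
    stopifnot(all(c("scene_point_id", "row", "col", "true_side") %in% names(scene_points)))
    scene_points$true_side <- ang_norm(scene_points$true_side)
  }
  structure(
    list(pixels = pixels, boundary = boundary, boundary_mask = mask,
         scene_points = scene_points),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image> %d x %d%s, %d boundary px, %d scene points\n",
              d[1], d[2], if (length(d) == 3) " (RGB)" else "",
              if (is.null(x$boundary)) 0L else nrow(x$boundary),
              if (is.null(x$scene_points)) 0L else nrow(x$scene_points)))
  invisible(x)
}

#' Synthetic square stimulus with geometric ground truth
#'
#' Generates the standard test stimulus used to probe border ownership: a
#' uniform square on a uniform background.  The boundary mask marks the
#' square's perimeter pixels and the ground-truth figure-side orientation at
#' each perimeter pixel is the inward normal of the perimeter segment (corner
#' pixels take the diagonal inward direction).  Default gray levels are 0.25
#' (background) and 0.75 (figure), symmetric around 0.5, so that contrast
#' inversion is the exact pixel map `1 - p`.
#'
#' @param image_size image side length in pixels (square image), at least 16.
#' @param square_side side of the square in pixels.
#' @param center integer `c(row, col)` center of the square; default image
#'   center.
#' @param polarity `"light-on-dark"` or `"dark-on-light"`.
#' @param scene_point_spacing spacing (pixels) between consecutive scene
#'   points sampled along each square edge; corners are excluded so scene
#'   points sit on straight boundary segments, as in physiological testing.
#' @param bg,fg background and figure gray levels.
#'
#' @return An [annotated_image()].
#' @export
make_square_stimulus <- function(image_size, square_side,
                                 center = NULL,
                                 polarity = c("light-on-dark", "dark-on-light"),
                                 scene_point_spacing = 4L,
                                 bg = 0.25, fg = 0.75) {
  polarity <- match.arg(polarity)
  if (image_size < 16) abort("`image_size` must be at least 16 pixels.")
  if (is.null(center)) center <- rep((image_size + 1L) %/% 2L, 2L)
  half_lo <- (square_side - 1L) %/% 2L
  half_hi <- square_side - 1L - half_lo
  r0 <- center[1] - half_lo; r1 <- center[1] + half_hi
  c0 <- center[2] - half_lo; c1 <- center[2] + half_hi
  if (r0 < 1 || c0 < 1 || r1 > image_size || c1 > image_size)
    abort(sprintf(
      "square of side %d centered at (%d, %d) extends outside the %d x %d image",
      square_side, center[1], center[2], image_size, image_size))

  if (polarity == "dark-on-light") { tmp <- bg; bg <- fg; fg <- tmp }
  px <- matrix(bg, image_size, image_size)
  px[r0:r1, c0:c1] <- fg

  # Perimeter pixels with inward-normal ground truth.  Angle convention:
  # 0 = rightward, pi/2 = upward (decreasing row).
  rows <- integer(0); cols <- integer(0); angs <- numeric(0)
  add <- function(r, c, a) {
    rows <<- c(rows, r); cols <<- c(cols, c); angs <<- c(angs, a)
  }
  if (square_side == 1L) {
    add(r0, c0, 0)  # degenerate single-pixel "square": direction arbitrary
  } else {
    for (cc in c0:c1) {
      a_top <- 3 * pi / 2          # top edge: inward is downward
      a_bot <- pi / 2              # bottom edge: inward is upward
      if (cc == c0) { a_top <- 7 * pi / 4; a_bot <- pi / 4 }       # left corners
      if (cc == c1) { a_top <- 5 * pi / 4; a_bot <- 3 * pi / 4 }   # right corners
      add(r0, cc, a_top); add(r1, cc, a_bot)
    }
    for (rr in setdiff(r0:r1, c(r0, r1))) {
      add(rr, c0, 0)               # left edge: inward is rightward
      add(rr, c1, pi)              # right edge: inward is leftward
    }
  }
  boundary <- tibble(row = rows, col = cols, angle = ang_norm(angs))

  # Scene points: subsample straight-edge boundary pixels (corners excluded).
  sp <- boundary[!(boundary$row %in% c(r0, r1) & boundary$col %in% c(c0, c1)), ]
  keep <- logical(nrow(sp))
  on_edge_pos <- ifelse(sp$row %in% c(r0, r1), sp$col - c0, sp$row - r0)
  keep <- (on_edge_pos %% scene_point_spacing) == (scene_point_spacing %/% 2)
  sp <- sp[keep, ]
  scene_points <- tibble(
    scene_point_id = sprintf("sp%03d", seq_len(nrow(sp))),
    row = sp$row, col = sp$col, true_side = sp$angle
  )

  annotated_image(px, boundary, scene_points)
}

#' Simulate noisy border ownership cell responses at scene points
#'
#' Stand-in generator for recorded border ownership data: each simulated cell
#' responds at every scene point with `gain` times a reference BOS plus
#' i.i.d. Gaussian noise, independently for each stimulus repeat.  The noise
#' model matches the variance decomposition used by the explainable-variance
#' statistic (a repeatable response component plus trial-to-trial noise).
#'
#' @param scene_points data frame with columns `scene_point_id` and `bos`
#'   (the reference BOS per scene point, e.g. the model's signed BOS).
#' @param gain multiplicative response gain of the simulated cell.
#' @param noise_sd standard deviation of the per-repeat Gaussian noise
#'   (must be `>= 0`).
#' @param n_repeats number of stimulus repeats per scene point (at least 2,
#'   so that the noise variance is estimable).
#' @param seed integer seed; fixed seeds give bit-identical output.
#'
#' @return A tibble with columns `scene_point_id`, `repeat_index`, `bos`.
#' @export
simulate_cell_responses <- function(scene_points, gain = 1, noise_sd = 0.1,
                                    n_repeats = 10L, seed) {
  scene_points <- as_tibble(scene_points)
  stopifnot(all(c("scene_point_id", "bos") %in% names(scene_points)))
  if (n_repeats < 2) abort("`n_repeats` must be >= 2: noise variance is undefined otherwise.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  n <- nrow(scene_points)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- tidyr::expand_grid(
    scene_point_id = scene_points$scene_point_id,
    repeat_index = seq_len(n_repeats)
  )
  ref <- rep(gain * scene_points$bos, each = n_repeats)
  out$bos <- ref + stats::rnorm(n * n_repeats, mean = 0, sd = noise_sd)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read a raster image as an annotated image
#'
#' Reads PNG, JPEG or TIFF rasters, rescales pixel values to `[0, 1]`, and
#' returns an [annotated_image()] with empty annotations.  Grayscale images
#' are carried as a single plane; color images as a 3-plane array.
#'
#' @param path path to an image file.
#' @return An [annotated_image()] with no boundary or scene-point metadata.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file does not exist: %s", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) abort(sprintf("cannot read image '%s': %s",
                                                    path, conditionMessage(e))))
  px <- EBImage::imageData(img)
  # EBImage stores (x = column, y = row); transpose to row-major.
  if (length(dim(px)) == 2) {
    px <- t(px)
  } else {
    px <- px[, , seq_len(min(3L, dim(px)[3])), drop = FALSE]
    if (dim(px)[3] == 1L) px <- t(px[, , 1]) else px <- aperm(px, c(2, 1, 3))
  }
  px[px < 0] <- 0; px[px > 1] <- 1
  annotated_image(px)
}

#' Write / read boundary annotations as delimited text
#'
#' Plain-text fixture format: one row per boundary pixel with columns
#' `row`, `col`, `angle_radians`.
#'
#' @param boundary tibble with columns `row`, `col`, `angle`.
#' @param path file path.
#' @return `read_boundary_annotation()` returns a tibble with columns `row`,
#'   `col`, `angle`; `write_boundary_annotation()` returns `path` invisibly.
#' @export
write_boundary_annotation <- function(boundary, path) {
  df <- data.frame(row = boundary$row, col = boundary$col,
                   angle_radians = boundary$angle)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boundary_annotation
#' @export
read_boundary_annotation <- function(path) {
  df <- utils::read.delim(path)
  tibble(row = df$row, col = df$col, angle = ang_norm(df$angle_radians))
}

#' Write / read scene-point response tables
#'
#' CSV with columns `scene_point_id`, `row`, `col`, `true_side`,
#' `repeat_index`, `bos` (for per-repeat cell responses) or the subset of
#' columns present.
#'
#' @param responses data frame of scene-point responses.
#' @param path file path.
#' @return `read_scene_points()` returns a tibble; `write_scene_points()`
#'   returns `path` invisibly.
#' @export
write_scene_points <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scene_points
#' @export
read_scene_points <- function(path) {
  as_tibble(utils::read.csv(path))
}
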