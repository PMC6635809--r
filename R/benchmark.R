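# Contour-detection and figure-ground benchmarking: boundary matching,
# precision-recall sweeps (ODS / OIS / AP), and the +/- 90-degree
# figure-ground accuracy.

#' Match predicted boundary pixels to ground truth
#'
#' Greedy nearest-neighbor one-to-one matching within a distance tolerance
#' (a documented approximation of the assignment solver used by standard
#' contour benchmarks).  Unmatched predictions count against precision,
#' unmatched ground-truth pixels against recall.
#'
#' @param pred two-column matrix or data frame of predicted boundary pixels
#'   (`row`, `col`).
#' @param truth two-column matrix or data frame of true boundary pixels.
#' @param tolerance maximum matching distance in pixels (>= 0).
#' @return List with `n_matched`, `n_pred`, `n_true`, `precision`, `recall`,
#'   `f` (harmonic mean, 0 when precision + recall is 0), and the matched
#'   index pairs.
#' @export
boundary_match <- function(pred, truth, tolerance) {
  stopifnot(tolerance >= 0)
  pred <- as.matrix(pred)[, 1:2, drop = FALSE]
  truth <- as.matrix(truth)[, 1:2, drop = FALSE]
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) {
    p <- if (np == 0) 0 else 0
    r <- if (nt == 0) 1 else 0
    if (np == 0 && nt == 0) { p <- 1; r <- 1 }
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    return(list(n_matched = 0L, n_pred = np, n_true = nt,
                precision = p, recall = r, f = f,
                pairs = matrix(integer(0), 0, 2)))
  }
  # candidate pairs within tolerance, via a coarse grid bucket pass
  cand_i <- integer(0); cand_j <- integer(0); cand_d <- numeric(0)
  tol2 <- tolerance^2
  # bucket truth pixels by grid cell of size ceiling(tolerance)+1
  cell <- max(1, ceiling(tolerance))
  key <- function(r, c) paste(r %/% cell, c %/% cell)
  buckets <- split(seq_len(nt), key(truth[, 1], truth[, 2]))
  for (i in seq_len(np)) {
    kr <- pred[i, 1] %/% cell; kc <- pred[i, 2] %/% cell
    for (dr in -1:1) for (dc in -1:1) {
      js <- buckets[[paste(kr + dr, kc + dc)]]
      if (is.null(js)) next
      d2 <- (truth[js, 1] - pred[i, 1])^2 + (truth[js, 2] - pred[i, 2])^2
      ok <- d2 <= tol2
      if (any(ok)) {
        cand_i <- c(cand_i, rep.int(i, sum(ok)))
        cand_j <- c(cand_j, js[ok])
        cand_d <- c(cand_d, d2[ok])
      }
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  if (length(cand_i)) {
    ord <- order(cand_d, cand_i, cand_j)
    used_p <- logical(np); used_t <- logical(nt)
    keep_i <- integer(0); keep_j <- integer(0)
    for (idx in ord) {
      i <- cand_i[idx]; j <- cand_j[idx]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      keep_i <- c(keep_i, i); keep_j <- c(keep_j, j)
    }
    pairs <- cbind(keep_i, keep_j)
  }
  m <- nrow(pairs)
  p <- m / np; r <- m / nt
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(n_matched = m, n_pred = np, n_true = nt,
       precision = p, recall = r, f = f, pairs = pairs)
}

# Non-maximum suppression of a magnitude map along the local BOS-angle
# normal: a pixel survives if it is at least as large as its two neighbors
# across the boundary (i.e. along the decoded figure direction).
nms_thin <- function(magnitude, angle) {
  nr <- nrow(magnitude); nc <- ncol(magnitude)
  # step across the boundary: the decoded angle points toward the figure,
  # i.e. along the boundary normal
  dr <- -round(sin(angle)); dc <- round(cos(angle))
  out <- matrix(0, nr, nc)
  idx <- which(magnitude > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  r <- idx[, 1]; c <- idx[, 2]
  lin <- function(rr, cc) {
    rr <- pmin(pmax(rr, 1L), nr); cc <- pmin(pmax(cc, 1L), nc)
    cbind(rr, cc)
  }
  s <- cbind(dr[idx], dc[idx])
  m0 <- magnitude[idx]
  m1 <- magnitude[lin(r + s[, 1], c + s[, 2])]
  m2 <- magnitude[lin(r - s[, 1], c - s[, 2])]
  keep <- m0 >= m1 & m0 >= m2
  out[idx[keep, , drop = FALSE]] <- m0[keep]
  out
}

#' Precision-recall sweep over BOS magnitude thresholds
#'
#' Thins the magnitude field by non-maximum suppression along the decoded
#' figure direction, thresholds it at `n_thresholds` levels, matches each
#' binarized prediction against the true boundary pixels, and summarizes the
#' curve by the best F-score (the single-image ODS component), the same
#' value as `ois_f` for a single image, and the area under the
#' precision-recall curve (AP, trapezoidal over recall).
#'
#' @param field an `fg_field` (or a list with `magnitude` and `angle`
#'   matrices); magnitudes are normalized to `[0, 1]` internally.
#' @param truth_mask logical matrix of true boundary pixels, or a `row`/
#'   `col` table.
#' @param n_thresholds number of threshold levels.
#' @param tolerance matching tolerance in pixels; default
#'   `0.0075 * image diagonal`.
#' @param thin apply non-maximum suppression before matching?
#' @return List of class `pr_curve`: tibble `curve` (threshold, counts,
#'   precision, recall, f), `best_f`, `ap`, `best_threshold`, `tolerance`.
#' @export
pr_sweep <- function(field, truth_mask, n_thresholds = 99, tolerance = NULL,
                     thin = TRUE) {
  mag <- field$magnitude
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  if (!is.matrix(truth_mask)) {
    tm <- matrix(FALSE, nrow(mag), ncol(mag))
    tm[cbind(truth_mask$row, truth_mask$col)] <- TRUE
    truth_mask <- tm
  }
  if (is.null(tolerance))
    tolerance <- 0.0075 * sqrt(nrow(mag)^2 + ncol(mag)^2)
  if (thin) mag <- nms_thin(mag, field$angle)
  truth_px <- which(truth_mask, arr.ind = TRUE)
  thr <- seq_len(n_thresholds) / (n_thresholds + 1)
  rows <- lapply(thr, function(t) {
    pred_px <- which(mag >= t, arr.ind = TRUE)
    m <- boundary_match(pred_px, truth_px, tolerance)
    tibble(threshold = t, n_matched = m$n_matched, n_pred = m$n_pred,
           n_true = m$n_true, precision = m$precision, recall = m$recall,
           f = m$f)
  })
  curve <- dplyr::bind_rows(rows)
  structure(list(curve = curve,
                 best_f = max(curve$f),
                 best_threshold = curve$threshold[which.max(curve$f)],
                 ap = pr_area(curve$precision, curve$recall),
                 tolerance = tolerance),
            class = "pr_curve")
}

# Area under the PR curve, trapezoidal over recall (recall is non-increasing
# in threshold, so reverse into increasing order first).
pr_area <- function(precision, recall) {
  o <- order(recall)
  r <- recall[o]; p <- precision[o]
  if (length(r) < 2) return(0)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Aggregate precision-recall curves across images
#'
#' Pools per-threshold match counts over a set of images: ODS is the best
#' F-score at a single dataset-wide threshold, OIS is the mean of the
#' per-image best F-scores, and AP is the area under the pooled
#' precision-recall curve.
#'
#' @param curves list of `pr_curve` objects sharing the same thresholds.
#' @return A tibble with one row: `ods_f`, `ois_f`, `ap`.
#' @export
pr_aggregate <- function(curves) {
  stopifnot(length(curves) >= 1)
  pooled <- dplyr::bind_rows(lapply(curves, function(cv) cv$curve)) |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(n_matched = sum(.data$n_matched),
                     n_pred = sum(.data$n_pred),
                     n_true = sum(.data$n_true), .groups = "drop") |>
    dplyr::mutate(
      precision = ifelse(.data$n_pred == 0, 0, .data$n_matched / .data$n_pred),
      recall = ifelse(.data$n_true == 0, 0, .data$n_matched / .data$n_true),
      f = ifelse(.data$precision + .data$recall == 0, 0,
                 2 * .data$precision * .data$recall /
                   (.data$precision + .data$recall)))
  tibble(ods_f = max(pooled$f),
         ois_f = mean(vapply(curves, function(cv) cv$best_f, numeric(1))),
         ap = pr_area(pooled$precision, pooled$recall))
}

#' Figure-ground assignment accuracy
#'
#' Fraction of labeled boundary points whose predicted figure direction
#' falls strictly within 90 degrees (circular difference) of the true
#' figure-ground label.
#'
#' @param pred_angles predicted figure directions (radians).
#' @param true_angles ground-truth figure directions (radians), co-located.
#' @return Fraction correct in `[0, 1]`.
#' @export
fg_accuracy <- function(pred_angles, true_angles) {
  if (length(pred_angles) == 0) abort("no labeled boundary points supplied.")
  stopifnot(length(pred_angles) == length(true_angles))
  mean(circ_diff(pred_angles, true_angles) < pi / 2)
}
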