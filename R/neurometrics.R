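# Model-vs-cell comparison statistics: sign consistency, cosine similarity,
# Fisher-z averaging, bootstrap difference tests, TOST equivalence tests,
# and noise-corrected explainable-variance R^2.

#' Border ownership sign consistency
#'
#' Fraction of scene points with a strictly positive signed BOS, i.e. the
#' ratio of scene points assigned to the correct figure side to the total
#' number tested.  Zero values count as inconsistent (conservative
#' convention).
#'
#' @param bos data frame with a `bos` column, or a numeric vector of signed
#'   BOS values.
#' @return Fraction in `[0, 1]`.
#' @export
consistency <- function(bos) {
  v <- if (is.data.frame(bos)) bos$bos else bos
  if (length(v) == 0) abort("consistency of an empty BOS vector is undefined.")
  if (anyNA(v)) abort("BOS values must be finite.")
  mean(v > 0)
}

#' Select highly consistent response vectors
#'
#' Generic threshold filter used to pick cells whose border ownership sign
#' agrees with the ground truth on more than a given fraction of their scene
#' points (the physiological convention is > 80%).
#'
#' @param responses data frame with columns `cell_id` and `bos` (signed, one
#'   row per cell x scene point, repeats already averaged).
#' @param threshold minimum consistency (exclusive).
#' @return Tibble of `cell_id` and `consistency` for cells passing the
#'   threshold.
#' @export
consistent_cells <- function(responses, threshold = 0.8) {
  as_tibble(responses) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(consistency = mean(.data$bos > 0), .groups = "drop") |>
    dplyr::filter(.data$consistency > threshold)
}

#' Cosine similarity between two BOS vectors
#'
#' Treats all BOS responses of a cell (or of the model) as one vector with a
#' coordinate per scene point and computes the scalar product normalized by
#' the vector lengths.  Identical vectors give 1, exactly opposite vectors
#' -1, orthogonal vectors 0.  When the inputs are data frames the vectors
#' are aligned on their shared `scene_point_id`s first.
#'
#' @param a,b numeric vectors of equal length, or data frames with columns
#'   `scene_point_id` and `bos`.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (is.data.frame(a) || is.data.frame(b)) {
    a <- as_tibble(a); b <- as_tibble(b)
    shared <- intersect(a$scene_point_id, b$scene_point_id)
    if (length(shared) < 2) abort("need at least 2 shared scene points.")
    a <- a$bos[match(shared, a$scene_point_id)]
    b <- b$bos[match(shared, b$scene_point_id)]
  }
  stopifnot(length(a) == length(b))
  if (length(a) < 2) abort("need at least 2 shared scene points.")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity is undefined for a zero vector.")
  # guard against rounding a hair past +/-1 (which would break Fisher z)
  min(max(sum(a * b) / (na * nb), -1), 1)
}

# Fisher z-transform with clamping away from +/-1 (atanh diverges there).
fisher_z <- function(r, clamp = 1 - 1e-6) {
  if (any(abs(r) >= 1)) {
    warn("similarities at +/-1 clamped before Fisher z-transform.")
    r <- pmin(pmax(r, -clamp), clamp)
  }
  atanh(r)
}

# Mean of correlations through the Fisher z-domain (variance-stabilized).
fisher_mean <- function(r) tanh(mean(fisher_z(r)))

#' Bootstrap test for a difference in mean similarity
#'
#' Two-sided bootstrap test of the difference between the Fisher-z means of
#' two groups of cosine similarities (e.g. cell-cell vs model-cell), under
#' the pooled null hypothesis that both groups come from the same
#' distribution: group-sized resamples are drawn with replacement from the
#' pooled values and the observed mean difference is referred to the
#' resampled distribution.
#'
#' @param group1,group2 numeric vectors of similarities in `(-1, 1)` (values
#'   at +/-1 are clamped with a warning).
#' @param n_samples bootstrap resamples (the headline analysis uses 10,000).
#' @param seed integer seed, required for reproducibility.
#' @return List with `p_value`, `observed_difference` (difference of
#'   Fisher-z back-transformed means), `n_samples`.
#' @export
bootstrap_mean_difference <- function(group1, group2, n_samples = 10000L, seed) {
  if (length(group1) == 0 || length(group2) == 0) abort("both groups must be nonempty.")
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  z1 <- fisher_z(group1); z2 <- fisher_z(group2)
  obs <- mean(z1) - mean(z2)
  pooled <- c(z1, z2)
  n1 <- length(z1); n2 <- length(z2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  i1 <- matrix(sample.int(n1 + n2, n1 * n_samples, replace = TRUE), n_samples)
  i2 <- matrix(sample.int(n1 + n2, n2 * n_samples, replace = TRUE), n_samples)
  diffs <- rowMeans(matrix(pooled[i1], n_samples)) -
    rowMeans(matrix(pooled[i2], n_samples))
  p <- (1 + sum(abs(diffs) >= abs(obs))) / (n_samples + 1)
  list(p_value = p, observed_difference = tanh(mean(z1)) - tanh(mean(z2)),
       n_samples = n_samples)
}

#' TOST equivalence test
#'
#' Two one-sided Welch t tests against the bounds of a pre-declared zone of
#' indifference for the difference in group means (default `[-0.25, 0.25]`).
#' The null hypothesis is that the mean difference lies outside the zone;
#' equivalence is declared when both one-sided nulls are rejected at
#' `alpha`, and the reported p-value is the larger of the two.
#'
#' @param group1,group2 numeric vectors (each of length >= 2).
#' @param zone numeric `c(lower, upper)` equivalence bounds on the mean
#'   difference.
#' @param alpha significance level for the equivalence decision.
#' @return List with `p_value` (max of the two one-sided p's), `equivalent`
#'   (logical), `mean_difference`, `p_lower`, `p_upper`.
#' @export
tost_equivalence <- function(group1, group2, zone = c(-0.25, 0.25),
                             alpha = 0.05) {
  stopifnot(length(group1) >= 2, length(group2) >= 2, length(zone) == 2,
            zone[1] <= zone[2])
  d <- mean(group1) - mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (v1 == 0 && v2 == 0) {
    # degenerate data: decide purely on whether the difference is inside
    inside <- d > zone[1] && d < zone[2]
    return(list(p_value = if (inside) 0 else 1, equivalent = inside,
                mean_difference = d, p_lower = NA_real_, p_upper = NA_real_,
                degenerate = TRUE))
  }
  se <- sqrt(v1 / length(group1) + v2 / length(group2))
  df <- (v1 / length(group1) + v2 / length(group2))^2 /
    (v1^2 / (length(group1)^2 * (length(group1) - 1)) +
       v2^2 / (length(group2)^2 * (length(group2) - 1)))
  # H0_lower: d <= zone[1]  vs  H1: d > zone[1]
  p_lower <- stats::pt((d - zone[1]) / se, df, lower.tail = FALSE)
  # H0_upper: d >= zone[2]  vs  H1: d < zone[2]
  p_upper <- stats::pt((d - zone[2]) / se, df, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  list(p_value = p, equivalent = p < alpha, mean_difference = d,
       p_lower = p_lower, p_upper = p_upper, degenerate = FALSE)
}

#' Noise-corrected explainable-variance goodness of fit
#'
#' Fits a single scale factor from the model BOS to each cell's mean
#' response by least squares and reports the fraction of the cell's
#' *explainable* variance captured by the scaled model:
#'
#'   `R^2 = (sigma_predicted^2 - sigma_noise^2 / Ns) / (sigma_response^2 - sigma_noise^2)`
#'
#' where `sigma_response^2` is the across-scene-point variance of the cell's
#' trial-averaged responses, `sigma_noise^2` is the trial-to-trial noise
#' variance of those averages (within-point repeat variance averaged over
#' points, divided by the number of repeats), and `sigma_predicted^2` is the
#' variance of the scaled model prediction.  The `1/Ns` numerator correction
#' removes the share of noise variance absorbed by fitting the scale factor
#' (one fitted degree of freedom over `Ns` scene points).
#'
#' @param cell_repeats data frame with columns `scene_point_id`,
#'   `repeat_index`, `bos`: per-repeat responses of one cell (>= 2 repeats
#'   per scene point, >= 3 scene points).
#' @param model_bos data frame with columns `scene_point_id` and `bos`: the
#'   model's signed BOS at the same scene points.
#' @return Object of class `fg_fit`: list with `scale`, `r2`,
#'   `sigma_response2`, `sigma_noise2`, `sigma_predicted2`,
#'   `n_scene_points`, `n_repeats`, `r2_defined`.
#' @export
explainable_variance_r2 <- function(cell_repeats, model_bos) {
  cr <- as_tibble(cell_repeats)
  mb <- as_tibble(model_bos)
  stopifnot(all(c("scene_point_id", "repeat_index", "bos") %in% names(cr)),
            all(c("scene_point_id", "bos") %in% names(mb)))
  per_point <- cr |>
    dplyr::group_by(.data$scene_point_id) |>
    dplyr::summarise(mean_bos = mean(.data$bos), var_bos = stats::var(.data$bos),
                     n_rep = dplyr::n(), .groups = "drop")
  if (any(per_point$n_rep < 2)) abort("every scene point needs >= 2 repeats.")
  shared <- intersect(per_point$scene_point_id, mb$scene_point_id)
  ns <- length(shared)
  if (ns < 3) abort("need at least 3 shared scene points.")
  y <- per_point$mean_bos[match(shared, per_point$scene_point_id)]
  vnoise_rep <- per_point$var_bos[match(shared, per_point$scene_point_id)]
  nrep <- per_point$n_rep[match(shared, per_point$scene_point_id)]
  m <- mb$bos[match(shared, mb$scene_point_id)]
  a <- sum(m * y) / sum(m^2)            # least-squares scale, no intercept
  sigma_noise2 <- mean(vnoise_rep / nrep)  # noise variance of the averaged response
  sigma_response2 <- stats::var(y)
  sigma_predicted2 <- stats::var(a * m)
  denom <- sigma_response2 - sigma_noise2
  r2_defined <- denom > 0
  r2 <- if (r2_defined) (sigma_predicted2 - sigma_noise2 / ns) / denom else NA_real_
  structure(list(scale = a, r2 = r2, sigma_response2 = sigma_response2,
                 sigma_noise2 = sigma_noise2,
                 sigma_predicted2 = sigma_predicted2,
                 n_scene_points = ns, n_repeats = mean(nrep),
                 r2_defined = r2_defined),
            class = "fg_fit")
}

#' @export
print.fg_fit <- function(x, ...) {
  cat(sprintf("<fg_fit> scale %.4g, R2 %.3f over %d scene points%s\n",
              x$scale, if (x$r2_defined) x$r2 else NA, x$n_scene_points,
              if (x$r2_defined) "" else " (R2 undefined: response variance <= noise variance)"))
  invisible(x)
}

#' @rdname explainable_variance_r2
#' @param x an `fg_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.fg_fit <- function(x, ...) {
  tibble(term = c("scale", "r2"), estimate = c(x$scale, x$r2))
}

#' @rdname explainable_variance_r2
#' @exportS3Method generics::glance
glance.fg_fit <- function(x, ...) {
  tibble(r2 = x$r2, scale = x$scale,
         sigma_response2 = x$sigma_response2,
         sigma_noise2 = x$sigma_noise2,
         sigma_predicted2 = x$sigma_predicted2,
         n_scene_points = x$n_scene_points,
         r2_defined = x$r2_defined)
}

#' Per-cell comparison report
#'
#' Convenience wrapper producing, for each cell in a per-repeat response
#' table, the consistency, model-cell cosine similarity and
#' explainable-variance R^2.
#'
#' @param responses data frame with columns `cell_id`, `scene_point_id`,
#'   `repeat_index`, `bos`.
#' @param model_bos data frame with `scene_point_id`, `bos`.
#' @return Tibble with one row per cell: `cell_id`, `n_scene_points`,
#'   `consistency`, `cosine_sim`, `r2`.
#' @export
compare_cells_to_model <- function(responses, model_bos) {
  responses <- as_tibble(responses)
  cells <- unique(responses$cell_id)
  purrr::map_dfr(cells, function(cid) {
    cr <- responses[responses$cell_id == cid, ]
    means <- cr |>
      dplyr::group_by(.data$scene_point_id) |>
      dplyr::summarise(bos = mean(.data$bos), .groups = "drop")
    fit <- explainable_variance_r2(cr, model_bos)
    tibble(cell_id = cid,
           n_scene_points = nrow(means),
           consistency = consistency(means$bos),
           cosine_sim = cosine_similarity(means, as_tibble(model_bos)),
           r2 = fit$r2)
  })
}
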