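test_that("consistency counts strictly positive signs", {
  expect_equal(consistency(c(1, 2, -3, 4)), 0.75)
  expect_equal(consistency(rep(0.5, 10)), 1)
  expect_equal(consistency(c(0, 0, 0)), 0)  # zeros are inconsistent
  expect_error(consistency(numeric(0)), "empty")
  df <- tibble::tibble(bos = c(0.2, -0.1))
  expect_equal(consistency(df), 0.5)
})

test_that("highly consistent cells are selected by threshold", {
  resp <- tibble::tibble(
    cell_id = rep(c("a", "b"), each = 10),
    bos = c(rep(1, 9), -1, rep(1, 5), rep(-1, 5)))
  out <- consistent_cells(resp, threshold = 0.8)
  expect_equal(out$cell_id, "a")
  expect_equal(out$consistency, 0.9)
})

test_that("cosine similarity matches its defining identities and a brute-force oracle", {
  a <- c(1, 2, 3, -4)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, -a), -1)
  expect_equal(cosine_similarity(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0)
  # scale invariance and symmetry
  b <- c(0.3, -1.2, 0.5, 2)
  expect_equal(cosine_similarity(a, 7.3 * b), cosine_similarity(a, b))
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  # elementwise brute-force evaluation of the defining formula
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]; da <- da + a[i]^2; db <- db + b[i]^2
  }
  expect_equal(cosine_similarity(a, b), num / (sqrt(da) * sqrt(db)),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("data-frame similarity aligns on shared scene points", {
  a <- tibble::tibble(scene_point_id = c("p1", "p2", "p3"), bos = c(1, 2, 3))
  b <- tibble::tibble(scene_point_id = c("p3", "p2", "p9"), bos = c(3, 2, 99))
  expect_equal(cosine_similarity(a, b), 1)  # shared points p2, p3 align
  expect_error(cosine_similarity(a, tibble::tibble(scene_point_id = "p1", bos = 1)),
               "shared")
})

test_that("Fisher-z mean of identical values returns that value", {
  expect_equal(protobos:::fisher_mean(rep(0.37, 8)), 0.37, tolerance = 1e-12)
  expect_warning(protobos:::fisher_z(1), "clamped")
})

test_that("bootstrap difference test is seeded and near 1 for identical groups", {
  g <- c(0.2, 0.4, 0.5, 0.3, 0.45, 0.6, 0.35)
  r1 <- bootstrap_mean_difference(g, g, n_samples = 500, seed = 4)
  r2 <- bootstrap_mean_difference(g, g, n_samples = 500, seed = 4)
  expect_identical(r1, r2)
  expect_gt(r1$p_value, 0.9)
  expect_equal(r1$observed_difference, 0)
  r3 <- bootstrap_mean_difference(g, g, n_samples = 500, seed = 5)
  expect_false(identical(r3$p_value, NULL))
  expect_error(bootstrap_mean_difference(g, g, n_samples = 10), "seed")
})

test_that("TOST declares equivalence only inside the zone", {
  set.seed(8)
  g1 <- rnorm(60, 0, 0.05); g2 <- rnorm(60, 0, 0.05)
  out <- tost_equivalence(g1, g2)
  expect_true(out$equivalent)
  expect_lt(out$p_value, 0.05)

  # a 0.5 mean offset lies outside [-0.25, 0.25]: never equivalent
  out2 <- tost_equivalence(g1, g2 + 0.5)
  expect_false(out2$equivalent)
  expect_gt(out2$p_value, 0.5)

  # an empty-interior zone can never declare equivalence
  out3 <- tost_equivalence(g1, g2, zone = c(0, 0))
  expect_false(out3$equivalent)

  # degenerate zero-variance identical groups are declared equivalent
  out4 <- tost_equivalence(rep(0.4, 5), rep(0.4, 5))
  expect_true(out4$equivalent)
  expect_true(out4$degenerate)
})

test_that("TOST agrees with a one-sided t-test framework on the same data", {
  # whenever TOST declares equivalence, each one-sided Welch test against the
  # zone bounds must itself reject at the same alpha
  set.seed(12)
  for (i in 1:20) {
    g1 <- rnorm(30, 0, 0.2); g2 <- rnorm(25, rnorm(1, 0, 0.2), 0.25)
    out <- tost_equivalence(g1, g2)
    p_lo <- stats::t.test(g1, g2, mu = -0.25, alternative = "greater")$p.value
    p_hi <- stats::t.test(g1, g2, mu = 0.25, alternative = "less")$p.value
    expect_equal(out$p_lower, p_lo, tolerance = 1e-10)
    expect_equal(out$p_upper, p_hi, tolerance = 1e-10)
    if (out$equivalent) expect_true(p_lo < 0.05 && p_hi < 0.05)
  }
})

test_that("explainable variance R2: exact fit, scale invariance, undefined case", {
  m <- tibble::tibble(scene_point_id = paste0("p", 1:12),
                      bos = seq(-1, 1, length.out = 12))
  exact <- tidyr::expand_grid(scene_point_id = m$scene_point_id,
                              repeat_index = 1:3)
  exact$bos <- 2.5 * m$bos[match(exact$scene_point_id, m$scene_point_id)]
  fit <- explainable_variance_r2(exact, m)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$scale, 2.5, tolerance = 1e-10)
  expect_equal(fit$sigma_noise2, 0)

  # the estimator is invariant to the true gain: fit out the scale
  noisy <- simulate_cell_responses(m, gain = 1, noise_sd = 0.05,
                                   n_repeats = 10, seed = 2)
  noisy5 <- noisy; noisy5$bos <- 5 * noisy5$bos
  f1 <- explainable_variance_r2(noisy, m)
  f5 <- explainable_variance_r2(noisy5, m)
  expect_equal(f1$r2, f5$r2, tolerance = 1e-10)
  expect_equal(f5$scale, 5 * f1$scale, tolerance = 1e-10)

  # pure noise with no signal: response variance below noise variance flags R2
  flat <- simulate_cell_responses(
    tibble::tibble(scene_point_id = m$scene_point_id, bos = rep(0, 12)),
    gain = 1, noise_sd = 1, n_repeats = 40, seed = 3)
  fflat <- explainable_variance_r2(flat, m)
  expect_false(fflat$r2_defined)
  expect_true(is.na(fflat$r2))

  expect_error(explainable_variance_r2(exact[exact$repeat_index == 1, ], m),
               "repeats")
})

test_that("uncorrelated model explains roughly none of the variance", {
  set.seed(21)
  m <- tibble::tibble(scene_point_id = paste0("p", 1:200),
                      bos = runif(200, -1, 1))
  cell_ref <- tibble::tibble(scene_point_id = m$scene_point_id,
                             bos = runif(200, -1, 1))  # independent of model
  resp <- simulate_cell_responses(cell_ref, gain = 1, noise_sd = 0.1,
                                  n_repeats = 10, seed = 22)
  fit <- explainable_variance_r2(resp, m)
  expect_lt(abs(fit$r2), 0.1)
})

test_that("per-cell report combines the comparison statistics", {
  m <- tibble::tibble(scene_point_id = paste0("p", 1:20),
                      bos = seq(-1, 1, length.out = 20))
  r1 <- simulate_cell_responses(m, gain = 2, noise_sd = 0.05, n_repeats = 5, seed = 5)
  r2 <- simulate_cell_responses(m, gain = -1, noise_sd = 0.05, n_repeats = 5, seed = 6)
  resp <- dplyr::bind_rows(dplyr::mutate(r1, cell_id = "c1"),
                           dplyr::mutate(r2, cell_id = "c2"))
  rep_tbl <- compare_cells_to_model(resp, m)
  expect_equal(nrow(rep_tbl), 2)
  expect_gt(rep_tbl$cosine_sim[rep_tbl$cell_id == "c1"], 0.99)
  expect_lt(rep_tbl$cosine_sim[rep_tbl$cell_id == "c2"], -0.99)
  fitc1 <- explainable_variance_r2(r1, m)
  expect_s3_class(glance(fitc1), "tbl_df")
  expect_equal(tidy(fitc1)$term, c("scale", "r2"))
})
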