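test_that("polarity combination is additive and contrast invariant", {
  b <- array(0, c(4, 4, 16, 2))
  b[2, 2, 3, 1] <- 0.7
  comb <- combine_polarity(b)
  expect_equal(comb[2, 2, 3], 0.7)
  expect_equal(sum(comb), 0.7)

  # combined B maps coincide for a stimulus and its contrast inversion
  B1 <- combine_polarity(square64_run()$recurrence$intensity$B$levels[[1]])
  B2 <- combine_polarity(square64_dark_run()$recurrence$intensity$B$levels[[1]])
  expect_equal(B1, B2, tolerance = 1e-9)
})

test_that("population vector follows planar vector addition", {
  nd <- 16
  b <- array(0, c(3, 3, nd))
  b[2, 2, 1] <- 0.6                      # theta = 0, preferred side pi/2
  f <- population_vector(b)
  expect_equal(f$magnitude[2, 2], 0.6)
  expect_equal(f$angle[2, 2], pi / 2)

  # equal opponent activity cancels
  b[2, 2, 9] <- 0.6                      # theta = pi, preferred side 3 pi/2
  f2 <- population_vector(b)
  expect_equal(f2$magnitude[2, 2], 0, tolerance = 1e-12)

  # orthogonal unit responses add to sqrt(2) along the bisector
  b3 <- array(0, c(3, 3, nd))
  b3[1, 1, 1] <- 1                       # side pi/2
  b3[1, 1, 5] <- 1                       # theta = pi/2, side pi
  f3 <- population_vector(b3)
  expect_equal(f3$magnitude[1, 1], sqrt(2), tolerance = 1e-12)
  expect_equal(f3$angle[1, 1], 3 * pi / 4, tolerance = 1e-12)
})

test_that("normalized BOS is bounded by 1 with equality at the argmax pixel", {
  res <- square64_run()
  f <- res$field
  amax <- which(f$magnitude == max(f$magnitude), arr.ind = TRUE)[1, ]
  truth <- tibble::tibble(row = c(amax[1], res$image$scene_points$row),
                          col = c(amax[2], res$image$scene_points$col),
                          true_side = c(f$angle[amax[1], amax[2]],
                                        res$image$scene_points$true_side))
  nb <- normalize_bos(f, truth, window_radius = 0)
  expect_true(all(abs(nb$bos) <= 1 + 1e-12))
  expect_equal(nb$bos[1], 1)
  # opposite true side at the argmax pixel gives exactly -1
  flipped <- truth[1, ]; flipped$true_side <- ang_norm(flipped$true_side + pi)
  expect_equal(normalize_bos(f, flipped, window_radius = 0)$bos, -1)
})

test_that("an all-zero field normalizes to zero with a warning", {
  zf <- population_vector(array(0, c(5, 5, 16)))
  expect_warning(
    nb <- normalize_bos(zf, tibble::tibble(row = 3, col = 3, true_side = 0)),
    "zero")
  expect_equal(nb$bos, 0)
})

test_that("channel fusion is a weighted vector sum", {
  mk <- function(vx, vy) protobos:::new_fg_field(matrix(vx, 2, 2), matrix(vy, 2, 2))
  fa <- mk(1, 0); fb <- mk(0, 1); fz <- mk(0, 0)
  fused <- fuse_channels(list(fa, fz, fz), weights = c(0.8, 0.1, 0.1))
  expect_equal(fused$vx, 0.8 * fa$vx)
  # identical fields with weights summing to one reproduce the field
  fused2 <- fuse_channels(list(fa, fa, fa))
  expect_equal(fused2$vx, fa$vx, tolerance = 1e-12)
  # degenerate weights collapse to one channel
  fused3 <- fuse_channels(list(fa, fb, fz), weights = c(1, 0, 0))
  expect_equal(fused3$vy, fz$vy)
  # permutation invariance with matching weights
  fused4 <- fuse_channels(list(fb, fa, fz), weights = c(0.1, 0.8, 0.1))
  expect_equal(fused4$vx, fused$vx + 0.1 * fb$vx)
  expect_warning(fuse_channels(list(fa, fb, fz), weights = c(2, 1, 1)), "renormaliz")
})

test_that("scene-point readout averages over its disc and validates bounds", {
  mk_const <- function(vx, vy, n = 11) protobos:::new_fg_field(
    matrix(vx, n, n), matrix(vy, n, n))
  f <- mk_const(0.5, 0)
  # constant field: windowed readout equals the constant (normalized to 1)
  expect_equal(scene_point_bos(f, c(6, 6), true_side = 0), 1)
  expect_equal(scene_point_bos(f, c(6, 6), true_side = pi), -1)
  expect_equal(scene_point_bos(f, c(6, 6), true_side = 0, window_radius = 0), 1)
  expect_error(scene_point_bos(f, c(50, 6), true_side = 0), "outside")
})
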